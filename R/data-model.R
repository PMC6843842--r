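#' Declare categorical covariates for a multilevel dataset
#'
#' A schema names every categorical covariate, its admissible category
#' labels, and the reference category dropped during dummy coding.
#' Individual-level covariates describe persons (e.g. smoking status);
#' area-level covariates describe neighbourhoods and are constant within an
#' area (typically tertiles `T1`/`T2`/`T3` of a built-environment metric,
#' with `T1` as reference so odds ratios are oriented against the lowest
#' tertile).
#'
#' @param individual named list; each element is a list with `levels`
#'   (character vector of admissible labels) and optionally `reference`
#'   (defaults to the first level).
#' @param area named list in the same format for area-level covariates.
#'   Defaults for tertiled metrics are `levels = c("T1","T2","T3")`,
#'   `reference = "T1"`.
#' @return An object of class `covariate_schema`.
#' @examples
#' covariate_schema(
#'   individual = list(smoking = list(levels = c("never", "former", "current"))),
#'   area = list(dist_pa = list(levels = c("T1", "T2", "T3"), reference = "T1"))
#' )
#' @export
covariate_schema <- function(individual = list(), area = list()) {
  norm <- function(defs, what) {
    if (length(defs) == 0L) return(list())
    if (is.null(names(defs)) || any(names(defs) == ""))
      stop(what, " covariates must be a named list", call. = FALSE)
    lapply(defs, function(d) {
      if (is.character(d)) d <- list(levels = d)
      if (is.null(d$levels) || length(d$levels) < 2L)
        stop("each covariate needs >= 2 declared levels", call. = FALSE)
      if (anyDuplicated(d$levels))
        stop("duplicated level labels", call. = FALSE)
      if (is.null(d$reference)) d$reference <- d$levels[1L]
      if (!d$reference %in% d$levels)
        stop("reference level not among declared levels", call. = FALSE)
      list(levels = as.character(d$levels), reference = as.character(d$reference))
    })
  }
  structure(list(individual = norm(individual, "individual"),
                 area = norm(area, "area")),
            class = "covariate_schema")
}

#' Read a covariate schema from a JSON or YAML config file
#'
#' The config holds two top-level maps, `individual` and `area`, each mapping
#' a covariate name to `{levels: [...], reference: ...}`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `covariate_schema`.
#' @export
read_schema <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML schemas", call. = FALSE)
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  covariate_schema(individual = cfg$individual %||% list(),
                   area = cfg$area %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a multilevel dataset of individuals nested in areas
#'
#' The central container: one row per individual with a binary outcome
#' (1 = obese, BMI >= 25 kg/m^2), the id of the area the individual lives
#' in, and categorical covariates validated against a [covariate_schema()].
#' Area ordering is the sorted id order, fixed here once, so that every
#' downstream matrix (design, adjacency, CAR precision) indexes areas
#' identically.
#'
#' @param records data.frame with columns `area_id`, `outcome` and one
#'   column per declared individual covariate (character labels).
#' @param schema a [covariate_schema()].
#' @param areas optional character vector of all area ids (areas with no
#'   sampled individuals are allowed); defaults to the ids observed in
#'   `records`.
#' @param area_covariates optional data.frame with column `area_id` plus one
#'   column per declared area covariate (labels) and/or raw metric columns.
#' @return An object of class `multilevel_dataset` with elements `areas`
#'   (sorted ids), `records`, `area_covariates`, `schema`.
#' @export
multilevel_dataset <- function(records, schema, areas = NULL,
                               area_covariates = NULL) {
  stopifnot(inherits(schema, "covariate_schema"), is.data.frame(records))
  need <- c("area_id", "outcome", names(schema$individual))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  records$area_id <- as.character(records$area_id)

  out <- suppressWarnings(as.numeric(records$outcome))
  bad <- which(is.na(out) | !out %in% c(0, 1))
  if (length(bad))
    stop("outcome must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  records$outcome <- as.integer(out)

  # drop records with missing covariate values (no imputation), then
  # validate every label against the declared category set
  drop <- rep(FALSE, nrow(records))
  for (cv in names(schema$individual)) {
    val <- as.character(records[[cv]])
    records[[cv]] <- val
    drop <- drop | is.na(val) | val == ""
  }
  if (any(drop)) {
    warning(sum(drop), " record(s) with missing covariate values dropped",
            call. = FALSE)
    records <- records[!drop, , drop = FALSE]
  }
  for (cv in names(schema$individual)) {
    bad <- which(!records[[cv]] %in% schema$individual[[cv]]$levels)
    if (length(bad))
      stop("unknown label '", records[[cv]][bad[1L]], "' in column '", cv,
           "' at row ", bad[1L], call. = FALSE)
  }

  areas <- sort(unique(as.character(areas %||% records$area_id)))
  unknown <- setdiff(records$area_id, areas)
  if (length(unknown))
    stop("record area id(s) not in area list: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)

  if (!is.null(area_covariates)) {
    stopifnot(is.data.frame(area_covariates), "area_id" %in% names(area_covariates))
    area_covariates$area_id <- as.character(area_covariates$area_id)
    for (cv in names(schema$area)) {
      if (!cv %in% names(area_covariates)) next
      lab <- as.character(area_covariates[[cv]])
      bad <- which(!is.na(lab) & !lab %in% schema$area[[cv]]$levels)
      if (length(bad))
        stop("unknown label '", lab[bad[1L]], "' in area column '", cv, "'",
             call. = FALSE)
      area_covariates[[cv]] <- lab
    }
    area_covariates <-
      area_covariates[match(areas, area_covariates$area_id), , drop = FALSE]
    rownames(area_covariates) <- NULL
  }

  rownames(records) <- NULL
  structure(list(areas = areas, records = records,
                 area_covariates = area_covariates, schema = schema),
            class = "multilevel_dataset")
}

#' @export
print.multilevel_dataset <- function(x, ...) {
  cat("<multilevel_dataset> ", nrow(x$records), " individuals in ",
      length(x$areas), " areas\n", sep = "")
  cat("  outcome prevalence: ",
      formatC(mean(x$records$outcome), digits = 3, format = "f"), "\n", sep = "")
  cat("  individual covariates: ",
      paste(names(x$schema$individual), collapse = ", "), "\n", sep = "")
  if (length(x$schema$area))
    cat("  area covariates: ",
        paste(names(x$schema$area), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-area individual counts
#'
#' @param ds a [multilevel_dataset()].
#' @return Integer vector n_i, named by area id, in the fixed area order.
#' @export
area_sizes <- function(ds) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  n <- table(factor(ds$records$area_id, levels = ds$areas))
  stats::setNames(as.integer(n), ds$areas)
}

#' Read individual records from CSV
#'
#' Expects a header row with at least `area_id`, `outcome`, and one column
#' per covariate declared in `schema`. Unknown category labels and
#' unparseable outcomes are rejected with the offending row named; records
#' with missing covariate values are dropped with a warning.
#'
#' @param path CSV file path.
#' @param schema a [covariate_schema()].
#' @param areas,area_covariates passed to [multilevel_dataset()].
#' @return A `multilevel_dataset`.
#' @export
read_individuals <- function(path, schema, areas = NULL, area_covariates = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = c("NA", ""))
  multilevel_dataset(df, schema, areas = areas,
                     area_covariates = area_covariates)
}

#' Write individual records to CSV
#'
#' Inverse of [read_individuals()]: `read_individuals(write_individuals(ds))`
#' reproduces the records exactly.
#'
#' @param ds a [multilevel_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(ds, path) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read area-level covariates from CSV
#'
#' One row per area: an `area_id` column plus raw metric columns (numeric)
#' and/or precomputed tertile label columns.
#'
#' @param path CSV file path.
#' @return data.frame with `area_id` as character.
#' @export
read_areas <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""))
  if (!"area_id" %in% names(df)) stop("areas file needs an area_id column",
                                      call. = FALSE)
  df$area_id <- as.character(df$area_id)
  df
}

#' Dichotomize body mass index at the obesity cut-off
#'
#' BMI = weight(kg) / height(m)^2; obesity is BMI >= 25.0 kg/m^2 (the
#' inclusive Asian-population cut-off), coded 1.
#'
#' @param height_m height in meters, > 0.
#' @param weight_kg weight in kilograms, > 0.
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize_bmi(1.75, 76.6) # BMI 25.01 -> 1
#' dichotomize_bmi(1.75, 76.5) # BMI 24.98 -> 0
#' @export
dichotomize_bmi <- function(height_m, weight_kg) {
  if (any(!is.finite(height_m)) || any(!is.finite(weight_kg)) ||
      any(height_m <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  as.integer(weight_kg / height_m^2 >= 25.0)
}

#' Build dummy-coded design matrices
#'
#' Encodes the individual covariates into X (one row per individual) and the
#' area covariates into W (area-level labels expanded to individual rows),
#' dropping each covariate's reference category so that a covariate with K
#' levels contributes exactly K-1 indicator columns. Column names are
#' `covariate:level`.
#'
#' @param ds a [multilevel_dataset()].
#' @param spec a [model_spec()]; only covariates named there are encoded.
#' @return A list of class `design_matrices` with elements `y` (integer
#'   outcomes), `X`, `W` (0/1 matrices, possibly zero columns), `area_index`
#'   (row -> position of the row's area in `ds$areas`), `x_names`,
#'   `w_names`, `areas`, `W_area` (the area-level W, one row per area).
#' @export
encode_design <- function(ds, spec) {
  stopifnot(inherits(ds, "multilevel_dataset"), inherits(spec, "model_spec"))
  rec <- ds$records
  n <- nrow(rec)
  area_index <- match(rec$area_id, ds$areas)

  dummy_block <- function(labels, def, name) {
    obs <- unique(labels)
    if (length(obs) < 2L)
      stop("covariate '", name, "' has a single observed level; design is degenerate",
           call. = FALSE)
    keep <- setdiff(def$levels, def$reference)
    m <- vapply(keep, function(lv) as.numeric(labels == lv), numeric(length(labels)))
    m <- matrix(m, ncol = length(keep),
                dimnames = list(NULL, paste0(name, ":", keep)))
    m
  }

  X <- matrix(0, n, 0)
  for (cv in spec$individual_covariates) {
    def <- ds$schema$individual[[cv]]
    if (is.null(def)) stop("individual covariate '", cv, "' not declared in schema",
                           call. = FALSE)
    X <- cbind(X, dummy_block(rec[[cv]], def, cv))
  }

  W_area <- matrix(0, length(ds$areas), 0)
  for (cv in spec$area_covariates) {
    def <- ds$schema$area[[cv]]
    if (is.null(def)) stop("area covariate '", cv, "' not declared in schema",
                           call. = FALSE)
    if (is.null(ds$area_covariates) || !cv %in% names(ds$area_covariates))
      stop("area covariate '", cv, "' missing from area_covariates", call. = FALSE)
    lab <- ds$area_covariates[[cv]]
    if (anyNA(lab)) stop("area covariate '", cv, "' has missing labels", call. = FALSE)
    W_area <- cbind(W_area, dummy_block(lab, def, cv))
  }
  W <- W_area[area_index, , drop = FALSE]

  structure(list(y = rec$outcome, X = X, W = W, W_area = W_area,
                 area_index = area_index,
                 x_names = colnames(X), w_names = colnames(W_area),
                 areas = ds$areas),
            class = "design_matrices")
}

#' Recover category labels from a dummy-coded block
#'
#' Utility inverse of the coding used by [encode_design()]: a row of all
#' zeros maps to the reference category, a single 1 maps to that column's
#' level.
#'
#' @param block 0/1 matrix whose columns are `covariate:level`.
#' @param def list with `levels` and `reference` as in a schema entry.
#' @return Character vector of labels.
#' @export
decode_dummies <- function(block, def) {
  keep <- sub("^[^:]*:", "", colnames(block))
  hit <- block %*% seq_along(keep)
  lab <- rep(def$reference, nrow(block))
  nz <- hit > 0
  lab[nz] <- keep[hit[nz]]
  lab
}
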