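#' Descriptive table by outcome group
#'
#' For every covariate level, counts and column percentages within the
#' nonobese (outcome 0) and obese (outcome 1) groups, the classic
#' "Table 1" of an epidemiological report.
#'
#' @param ds a [multilevel_dataset()].
#' @param covariates covariate names; defaults to every declared individual
#'   covariate.
#' @return data.frame of class `descriptive_table`: `covariate`, `level`,
#'   `n_nonobese`, `pct_nonobese`, `n_obese`, `pct_obese`, and formatted
#'   `nonobese` / `obese` strings `"n (p)"` with one decimal.
#' @export
describe_outcome <- function(ds, covariates = NULL) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  if (nrow(ds$records) == 0L) stop("empty dataset", call. = FALSE)
  covariates <- covariates %||% names(ds$schema$individual)
  y <- ds$records$outcome
  rows <- lapply(covariates, function(cv) {
    lev <- ds$schema$individual[[cv]]$levels
    x <- factor(ds$records[[cv]], levels = lev)
    n0 <- as.integer(table(x[y == 0]))
    n1 <- as.integer(table(x[y == 1]))
    data.frame(covariate = cv, level = lev, n_nonobese = n0, n_obese = n1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  add_percents(out)
}

#' Percentages for a printed count table
#'
#' Turns per-level counts within the nonobese and obese groups (for example
#' the published marginal counts of a survey report) into column
#' percentages and the overall outcome prevalence, without access to the
#' microdata.
#'
#' @param counts data.frame with columns `covariate`, `level`,
#'   `n_nonobese`, `n_obese`.
#' @return The input with `pct_nonobese`, `pct_obese` (column percents
#'   within each covariate) and formatted strings appended; attribute
#'   `"prevalence_pct"` holds the overall percent obese computed from the
#'   first covariate's group totals.
#' @export
add_percents <- function(counts) {
  stopifnot(all(c("covariate", "level", "n_nonobese", "n_obese") %in%
                  names(counts)))
  out <- counts
  out$pct_nonobese <- NA_real_; out$pct_obese <- NA_real_
  for (cv in unique(out$covariate)) {
    i <- out$covariate == cv
    out$pct_nonobese[i] <- 100 * out$n_nonobese[i] / sum(out$n_nonobese[i])
    out$pct_obese[i] <- 100 * out$n_obese[i] / sum(out$n_obese[i])
  }
  fmt <- function(n, p) sprintf("%d (%.1f)", n, p)
  out$nonobese <- fmt(out$n_nonobese, out$pct_nonobese)
  out$obese <- fmt(out$n_obese, out$pct_obese)
  i <- counts$covariate == counts$covariate[1L]
  attr(out, "prevalence_pct") <-
    100 * sum(counts$n_obese[i]) / sum(counts$n_obese[i] + counts$n_nonobese[i])
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' Published marginal counts of the 2013-2014 KCHS Gyeonggi obesity survey
#'
#' The per-level participant counts within the nonobese (N = 58,232) and
#' obese (N = 19,782) groups, as printed in the survey's descriptive table:
#' sociodemographic factors, health behaviours, health status, and the
#' tertiled neighbourhood-environment metrics. These public summary counts
#' let the descriptive stage run without the (non-public) microdata.
#'
#' @return data.frame with `covariate`, `level`, `n_nonobese`, `n_obese`.
#' @seealso [add_percents()] to derive the column percentages.
#' @export
kchs_counts <- function() {
  utils::read.csv(system.file("extdata", "kchs_gyeonggi_2013_counts.csv",
                              package = "bymlogit"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Univariate logistic regression by Newton-Raphson
#'
#' Maximum-likelihood fit of `logit P(y=1) = b0 + sum_k b_k 1[x = level_k]`
#' for a single categorical covariate, by iteratively reweighted least
#' squares (Newton-Raphson on the log-likelihood). Levels exhibiting
#' complete separation (all-0 or all-1 outcomes) are flagged and excluded
#' from the Wald test.
#'
#' @param y 0/1 outcomes.
#' @param x categorical covariate (character or factor), same length.
#' @param reference reference level (default: first factor level).
#' @param max_iter,tol Newton iteration controls.
#' @return list of class `uni_logit`: `coef` (named, intercept first),
#'   `se`, `z`, `p` (per-level Wald), `wald_p` (joint Wald chi-square
#'   p-value over non-separated levels), `or` (per-level odds ratios),
#'   `separated` (flagged levels), `converged`, `loglik`.
#' @export
fit_univariate_logistic <- function(y, x, reference = NULL,
                                    max_iter = 50L, tol = 1e-10) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(x) == length(y))
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  x <- as.factor(x)
  x <- droplevels(x)
  if (nlevels(x) < 2L)
    stop("covariate has fewer than 2 observed levels; degenerate fit",
         call. = FALSE)
  if (!is.null(reference)) x <- stats::relevel(x, ref = reference)

  sep_lev <- levels(x)[vapply(levels(x), function(lv) {
    yy <- y[x == lv]; length(yy) > 0 && (all(yy == 0) || all(yy == 1))
  }, TRUE)]
  if (length(sep_lev))
    warning("complete separation in level(s): ",
            paste(sep_lev, collapse = ", "), "; excluded from the Wald test",
            call. = FALSE)

  X <- cbind(`(Intercept)` = 1,
             vapply(levels(x)[-1L], function(lv) as.numeric(x == lv),
                    numeric(length(x))))
  b <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # dampen huge steps (separation drives coefficients to +-Inf)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    b <- b + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% b)
  mu <- inv_logit(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  names(b) <- names(se) <- names(z) <- names(p) <- colnames(X)

  keep <- setdiff(colnames(X)[-1L], sep_lev)
  wald_p <- if (length(keep)) {
    bk <- b[keep]
    Vk <- V[keep, keep, drop = FALSE]
    W <- tryCatch(drop(t(bk) %*% solve(Vk, bk)), error = function(e) NA_real_)
    stats::pchisq(W, df = length(keep), lower.tail = FALSE)
  } else NA_real_

  structure(list(coef = b, se = se, z = z, p = p, wald_p = wald_p,
                 or = exp(b[-1L]), separated = sep_lev,
                 converged = converged,
                 loglik = sum(y * eta - log1pexp(eta))),
            class = "uni_logit")
}

#' Stratified univariate screening of covariates
#'
#' The pre-modelling stage: within each stratum (by default the six
#' gender x age-group cells), each candidate covariate is tested against
#' the outcome with a univariate logistic regression, and covariates with
#' joint Wald p below the threshold are selected for the multilevel model
#' of that stratum.
#'
#' @param ds a [multilevel_dataset()].
#' @param covariates candidate covariate names (individual and/or area
#'   covariates; area labels are joined to individuals through their area).
#' @param strata_vars record columns defining strata (default
#'   `c("gender", "age_group")` when present, else a single overall
#'   stratum).
#' @param threshold significance threshold on the Wald p-value (default
#'   0.05).
#' @return data.frame of class `screen_result`: `stratum`, `covariate`,
#'   `p`, `selected`. Strata where a fit is degenerate get `NA` p and are
#'   not selected; empty strata are skipped with a warning.
#' @export
screen_covariates <- function(ds, covariates = NULL, strata_vars = NULL,
                              threshold = 0.05) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  covariates <- covariates %||% c(names(ds$schema$individual),
                                  names(ds$schema$area))
  default_sv <- intersect(c("gender", "age_group"), names(ds$records))
  strata_vars <- strata_vars %||% default_sv
  rec <- ds$records
  # join area-level labels onto individual rows
  for (cv in intersect(covariates, names(ds$schema$area))) {
    if (is.null(ds$area_covariates) || !cv %in% names(ds$area_covariates))
      stop("area covariate '", cv, "' not available", call. = FALSE)
    rec[[cv]] <- ds$area_covariates[[cv]][match(rec$area_id,
                                                ds$area_covariates$area_id)]
  }
  strat <- if (length(strata_vars))
    interaction(rec[strata_vars], drop = FALSE, sep = " x ") else
      factor(rep("all", nrow(rec)))
  covariates <- setdiff(covariates, strata_vars)

  rows <- list()
  for (s in levels(strat)) {
    idx <- which(strat == s)
    if (!length(idx)) { warning("empty stratum '", s, "' skipped",
                                call. = FALSE); next }
    for (cv in covariates) {
      p <- tryCatch(
        suppressWarnings(
          fit_univariate_logistic(rec$outcome[idx], rec[[cv]][idx])$wald_p),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = s, covariate = cv, p = p,
                   selected = isTRUE(p < threshold), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Covariates selected by screening, per stratum
#'
#' @param screen a `screen_result` from [screen_covariates()].
#' @param stratum stratum label.
#' @return Character vector of selected covariate names.
#' @export
selected_covariates <- function(screen, stratum) {
  screen$covariate[screen$stratum == stratum & screen$selected]
}
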