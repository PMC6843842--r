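#' Configuration for the nested-cohort generator
#'
#' The defaults emulate the study population the package is designed for:
#' 546 districts with on average ~143 surveyed adults each, ~25% outcome
#' prevalence, a male share of 46.3% with higher obesity odds, and three
#' age bands. Covariate effects are on the log-odds scale; the reference
#' level of every covariate has effect 0.
#'
#' @param n_areas number of areas; the default adjacency is a rook lattice
#'   with dimensions as near square as `n_areas` factors allow.
#' @param graph optional [area_graph()] overriding the lattice.
#' @param mean_individuals mean persons sampled per area.
#' @param nb_size negative-binomial size (dispersion) of per-area counts;
#'   smaller is more dispersed; `Inf` gives exactly `mean_individuals`
#'   per area.
#' @param alpha intercept on the logit scale.
#' @param individual named list of individual covariate definitions, each
#'   `list(levels, probs, effects)` with `effects` named by non-reference
#'   level (the first level is the reference).
#' @param area named list of area covariate definitions in the same format
#'   (labels are drawn per area).
#' @param sigma_u2 conditional variance of the intrinsic CAR spatial effect.
#' @param sigma_v2 variance of the independent area effect.
#' @param seed master seed; every random stream of the generator derives
#'   from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_areas = 546L,
                       graph = NULL,
                       mean_individuals = 143,
                       nb_size = 8,
                       alpha = -1.68,
                       individual = list(
                         gender = list(levels = c("female", "male"),
                                       probs = c(0.537, 0.463),
                                       effects = c(male = 0.66)),
                         age_group = list(levels = c("19-39", "40-59", "60+"),
                                          probs = c(0.347, 0.429, 0.224),
                                          effects = c("40-59" = 0.32,
                                                      "60+" = 0.32))),
                       area = list(),
                       sigma_u2 = 0.1,
                       sigma_v2 = 0.1,
                       seed = 1L) {
  norm_def <- function(d) {
    stopifnot(length(d$levels) >= 2L)
    d$probs <- d$probs %||% rep(1 / length(d$levels), length(d$levels))
    stopifnot(length(d$probs) == length(d$levels), all(d$probs >= 0))
    d$probs <- d$probs / sum(d$probs)
    eff <- stats::setNames(numeric(length(d$levels)), d$levels)
    if (!is.null(d$effects)) {
      stopifnot(all(names(d$effects) %in% d$levels))
      eff[names(d$effects)] <- d$effects
    }
    d$effects <- eff
    d
  }
  stopifnot(n_areas >= 1, mean_individuals > 0, nb_size > 0,
            sigma_u2 >= 0, sigma_v2 >= 0)
  structure(list(n_areas = as.integer(n_areas), graph = graph,
                 mean_individuals = mean_individuals, nb_size = nb_size,
                 alpha = alpha,
                 individual = lapply(individual, norm_def),
                 area = lapply(area, norm_def),
                 sigma_u2 = sigma_u2, sigma_v2 = sigma_v2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# near-square lattice dimensions whose product is exactly n
near_square_dims <- function(n) {
  nr <- floor(sqrt(n))
  while (nr > 1L && n %% nr != 0L) nr <- nr - 1L
  c(nr, n %/% nr)
}

#' Simulate a nested cohort with known ground truth
#'
#' Runs the model forward: spatial effects u from the sum-to-zero
#' constrained intrinsic CAR on the area graph, independent effects
#' v ~ N(0, sigma_v2), categorical covariates from their declared level
#' probabilities, and outcomes y ~ Bernoulli(logit^-1(lambda)) with
#' lambda = alpha + X'beta + W'gamma + u + v. Identical seeds reproduce
#' the dataset bit for bit.
#'
#' @param cfg a [sim_config()].
#' @return list of class `simulated_cohort`: `ds` (a
#'   [multilevel_dataset()]), `graph` (the [area_graph()]), `truth`
#'   (realized `u`, `v`, per-individual `p`, the `cfg`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  graph <- cfg$graph
  if (is.null(graph)) {
    dims <- near_square_dims(cfg$n_areas)
    graph <- lattice_graph(dims[1L], dims[2L])
  }
  stopifnot(graph$n == cfg$n_areas)
  N <- graph$n

  u <- if (cfg$sigma_u2 > 0) sample_car(graph, cfg$sigma_u2) else numeric(N)
  v <- stats::rnorm(N, 0, sqrt(cfg$sigma_v2))

  n_i <- if (is.infinite(cfg$nb_size)) rep(round(cfg$mean_individuals), N) else
    stats::rnbinom(N, size = cfg$nb_size, mu = cfg$mean_individuals)
  n <- sum(n_i)
  if (n == 0L) stop("simulated cohort is empty; increase mean_individuals",
                    call. = FALSE)
  area_index <- rep(seq_len(N), n_i)

  eta <- rep(cfg$alpha, n) + (u + v)[area_index]
  rec <- data.frame(area_id = graph$areas[area_index],
                    stringsAsFactors = FALSE)
  for (cv in names(cfg$individual)) {
    d <- cfg$individual[[cv]]
    lab <- sample(d$levels, n, replace = TRUE, prob = d$probs)
    rec[[cv]] <- lab
    eta <- eta + d$effects[lab]
  }
  area_lab <- list()
  for (cv in names(cfg$area)) {
    d <- cfg$area[[cv]]
    lab <- sample(d$levels, N, replace = TRUE, prob = d$probs)
    area_lab[[cv]] <- lab
    eta <- eta + d$effects[lab[area_index]]
  }
  p <- inv_logit(eta)
  rec$outcome <- stats::rbinom(n, 1L, p)
  rec <- rec[, c("area_id", "outcome",
                 names(cfg$individual)), drop = FALSE]

  schema <- covariate_schema(
    individual = lapply(cfg$individual, function(d)
      list(levels = d$levels, reference = d$levels[1L])),
    area = lapply(cfg$area, function(d)
      list(levels = d$levels, reference = d$levels[1L])))
  area_cov <- if (length(area_lab))
    do.call(data.frame, c(list(area_id = graph$areas, stringsAsFactors = FALSE),
                          area_lab)) else NULL
  ds <- multilevel_dataset(rec, schema, areas = graph$areas,
                           area_covariates = area_cov)

  structure(list(ds = ds, graph = graph,
                 truth = list(u = u, v = v, p = p, eta = eta, cfg = cfg)),
            class = "simulated_cohort")
}

#' Implied marginal outcome prevalence of a configuration
#'
#' Monte-Carlo estimate of E[logit^-1(lambda)] under the generator, useful
#' to check that a configuration emulates the intended prevalence before
#' committing to a large simulation.
#'
#' @param cfg a [sim_config()].
#' @param nsim Monte-Carlo sample size.
#' @return Scalar prevalence estimate.
#' @export
implied_prevalence <- function(cfg, nsim = 20000L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 77L)
  # area effects: approximate the marginal CAR variance by its average
  # diagonal on a small lattice of the same degree structure
  eta <- rep(cfg$alpha, nsim)
  if (cfg$sigma_u2 > 0) {
    g <- lattice_graph(5L, 5L)
    mvar <- mean(diag(car_covariance(g, cfg$sigma_u2)))
    eta <- eta + stats::rnorm(nsim, 0, sqrt(mvar))
  }
  eta <- eta + stats::rnorm(nsim, 0, sqrt(cfg$sigma_v2))
  for (d in c(cfg$individual, cfg$area)) {
    lab <- sample(d$levels, nsim, replace = TRUE, prob = d$probs)
    eta <- eta + d$effects[lab]
  }
  mean(inv_logit(eta))
}

#' Write a simulated cohort to disk
#'
#' Emits the flat-file interface consumed by the readers:
#' `individuals.csv`, `areas.csv` (when area covariates exist),
#' `edges.csv`, and `truth.json` holding the realized random effects and
#' the configuration scalars.
#'
#' @param sim a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_individuals(sim$ds, file.path(dir, "individuals.csv"))
  if (!is.null(sim$ds$area_covariates))
    utils::write.csv(sim$ds$area_covariates, file.path(dir, "areas.csv"),
                     row.names = FALSE, quote = FALSE)
  ed <- sim$graph$edges
  utils::write.csv(data.frame(area_id_a = sim$graph$areas[ed[, 1L]],
                              area_id_b = sim$graph$areas[ed[, 2L]]),
                   file.path(dir, "edges.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(u = tr$u, v = tr$v,
         alpha = tr$cfg$alpha, sigma_u2 = tr$cfg$sigma_u2,
         sigma_v2 = tr$cfg$sigma_v2, seed = tr$cfg$seed),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Simulate a synthetic landscape for the built-environment metrics
#'
#' Each area is a rectangular block of 100 m x 100 m urbanized cells placed
#' in its own tile of a square tiling; destination points of each class
#' (physical-activity facility, park, transit stop) follow a homogeneous
#' Poisson process over the whole landscape; intersection counts and
#' population follow the calibration scales of published district tables
#' (population densities spanning roughly 4-8000 persons/km^2,
#' intersection densities 0-3 per km^2); floor areas of the three land-use
#' classes are Dirichlet-distributed so the land-use-mix entropy spans
#' (0, 1).
#'
#' @param n_areas number of areas.
#' @param dest_per_tile named expected destination counts per 3 km x 3 km
#'   tile, classes `pa_facility`, `park`, `transit`. Sparse classes give
#'   long nearest distances.
#' @param cells_range min and max urbanized cells per area.
#' @param floor_concentration Dirichlet concentration of the three land-use
#'   floor-area proportions (large values push LUM towards 1).
#' @param seed integer seed.
#' @return Object of class `landscape` (see [landscape_metrics()]).
#' @export
simulate_landscape <- function(n_areas = 100L,
                               dest_per_tile = c(pa_facility = 2, park = 25,
                                                 transit = 45),
                               cells_range = c(20L, 100L),
                               floor_concentration = 2,
                               seed = 1L) {
  stopifnot(n_areas >= 1, all(dest_per_tile > 0), floor_concentration > 0)
  set.seed(seed)
  tile <- 3000 # m
  ag <- ceiling(sqrt(n_areas))
  ids <- sprintf("L%0*d", nchar(n_areas), seq_len(n_areas))
  areas <- vector("list", n_areas)
  for (i in seq_len(n_areas)) {
    tr <- (i - 1L) %/% ag; tc <- (i - 1L) %% ag
    ncell <- sample(cells_range[1L]:cells_range[2L], 1L)
    wc <- ceiling(sqrt(ncell)); hc <- ceiling(ncell / wc)
    ox <- tc * tile + stats::runif(1L, 0, max(tile - wc * 100, 1))
    oy <- tr * tile + stats::runif(1L, 0, max(tile - hc * 100, 1))
    grid <- expand.grid(x = seq_len(wc), y = seq_len(hc))[seq_len(ncell), ]
    centers <- cbind(ox + (grid$x - 0.5) * 100, oy + (grid$y - 0.5) * 100)
    area_km2 <- ncell * 0.01
    pop_dens <- stats::rlnorm(1L, log(150), 1.3)
    int_dens <- stats::rlnorm(1L, log(0.15), 1)
    fa <- stats::rgamma(3L, shape = floor_concentration)
    areas[[i]] <- list(area_id = ids[i], cell_centers = centers,
                       urban_area_km2 = area_km2,
                       population = round(pop_dens * area_km2),
                       n_intersections = stats::rpois(1L, int_dens * area_km2),
                       floor_areas = 1e4 * fa / sum(fa))
  }
  ext <- ag * tile
  # destination intensity varies across tiles (log-normal multipliers with
  # unit mean), emulating the urban/rural contrast of a real province:
  # dense tiles give near-zero distances, empty stretches give the long
  # right tail seen in published district tables
  dest <- lapply(dest_per_tile, function(lam) {
    pts <- matrix(numeric(0), 0, 2)
    for (t in seq_len(ag^2) - 1L) {
      mult <- stats::rlnorm(1L, -1.125, 1.5)
      m <- stats::rpois(1L, lam * mult)
      if (m > 0L)
        pts <- rbind(pts, cbind(
          (t %% ag) * tile + stats::runif(m, 0, tile),
          (t %/% ag) * tile + stats::runif(m, 0, tile)))
    }
    if (nrow(pts) == 0L)
      pts <- cbind(stats::runif(1L, 0, ext), stats::runif(1L, 0, ext))
    pts
  })
  structure(list(areas = areas, destinations = dest, extent_m = ext),
            class = "landscape")
}
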