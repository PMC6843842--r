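#' Deviance information criterion
#'
#' DIC = Dbar + pD, where Dbar is the posterior mean of the deviance
#' D(theta) = -2 log p(y | theta) and pD = Dbar - D(theta_hat) with
#' theta_hat the componentwise posterior mean of all parameters, including
#' the area random effects u and v (the deviance conditions on the random
#' effects). Smaller DIC indicates better fit, penalized for effective
#' complexity.
#'
#' @param fit a `posterior_draws` object from [fit_bym()].
#' @return list(dic, dbar, pd).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (nrow(fit$draws) < 3L) stop("too few draws for DIC", call. = FALSE)
  dbar <- mean(fit$draws[, "deviance"])
  eta_hat <- plugin_eta(fit)
  dhat <- -2 * log_likelihood_bern(fit$design$y, eta_hat)
  pd <- dbar - dhat
  if (pd < 0)
    warning("negative pD (", formatC(pd, digits = 3, format = "f"),
            "): a known DIC pathology under poor mixing or a skewed posterior",
            call. = FALSE)
  list(dic = dbar + pd, dbar = dbar, pd = pd)
}

# linear predictor at the componentwise posterior mean state
plugin_eta <- function(fit) {
  cm <- colMeans(fit$draws)
  design <- fit$design
  spec <- fit$spec
  N <- length(design$areas)
  state <- parameter_state(
    spec, design,
    alpha = cm[["alpha"]],
    beta = if (has_component(spec, "beta") && length(design$x_names))
      unname(cm[paste0("beta.", design$x_names)]) else NULL,
    gamma = if (has_component(spec, "gamma") && length(design$w_names))
      unname(cm[paste0("gamma.", design$w_names)]) else NULL,
    u = if (has_component(spec, "u"))
      unname(cm[paste0("u.", design$areas)]) else NULL,
    v = unname(cm[paste0("v.", design$areas)]),
    sigma_u2 = if (has_component(spec, "u")) cm[["sigma_u2"]] else 1,
    sigma_v2 = cm[["sigma_v2"]])
  linear_predictor(state, design, spec)
}

#' Spatial fraction of unexplained area-level variance
#'
#' SF = sigma_u2 / (sigma_u2 + sigma_v2): the share of residual area-level
#' variation attributed to the spatially structured component. Values near
#' 1 indicate dominant spatial dependence; near 0, unstructured
#' heterogeneity. Uses the raw variance parameters (the CAR sigma_u2 is a
#' conditional variance; see the package vignette for the caveat).
#'
#' @param sigma_u2,sigma_v2 non-negative variances, not both zero. Vectors
#'   are accepted (e.g. posterior draws).
#' @return SF in `[0, 1]`.
#' @examples
#' spatial_fraction(1, 1)      # 0.5
#' spatial_fraction(0.991, 0.009) # 0.991
#' @export
spatial_fraction <- function(sigma_u2, sigma_v2) {
  if (any(sigma_u2 < 0) || any(sigma_v2 < 0))
    stop("variances must be non-negative", call. = FALSE)
  tot <- sigma_u2 + sigma_v2
  if (any(tot == 0)) stop("spatial fraction undefined when both variances are 0",
                          call. = FALSE)
  sigma_u2 / tot
}

#' Posterior spatial fraction of a fitted M4 model
#'
#' Applies [spatial_fraction()] drawwise and reports the posterior mean
#' (plus the drawwise quantiles).
#'
#' @param fit an M4 `posterior_draws` object.
#' @return list(mean, cri_low, cri_high).
#' @export
posterior_sf <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (fit$spec$variant != "M4")
    stop("the spatial fraction is defined for variant M4 only", call. = FALSE)
  sf <- spatial_fraction(fit$draws[, "sigma_u2"], fit$draws[, "sigma_v2"])
  q <- unname(stats::quantile(sf, c(0.025, 0.975)))
  list(mean = mean(sf), cri_low = q[1L], cri_high = q[2L])
}

#' Fit and compare the nested model variants
#'
#' Fits each requested variant on the same data with the same seed policy
#' and tabulates Dbar, pD, DIC, and (for M4) the posterior-mean spatial
#' fraction. The variant with the smallest DIC is flagged.
#'
#' @param ds a [multilevel_dataset()].
#' @param graph an [area_graph()].
#' @param specs list of [model_spec()] objects (one per variant).
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed shared across variants.
#' @return list of class `fit_comparison`: `table` (data.frame with one row
#'   per variant), `best_variant`, `fits` (the `posterior_draws` objects).
#' @export
compare_models <- function(ds, graph, specs, mcmc = mcmc_control(), seed) {
  stopifnot(is.list(specs), length(specs) >= 1)
  fits <- lapply(specs, function(sp) fit_bym(ds, graph, sp, mcmc, seed = seed))
  rows <- lapply(fits, function(f) {
    d <- dic(f)
    data.frame(variant = f$spec$variant, dbar = d$dbar, pd = d$pd,
               dic = d$dic,
               sf = if (f$spec$variant == "M4") posterior_sf(f)$mean else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- tab$variant[which.min(tab$dic)]
  structure(list(table = tab, best_variant = best, fits = fits),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("<fit_comparison>\n")
  print(transform(x$table, dbar = round(dbar, 2), pd = round(pd, 2),
                  dic = round(dic, 2), sf = round(sf, 3)))
  cat("best variant by DIC: ", x$best_variant, "\n", sep = "")
  invisible(x)
}

#' Write a model-comparison table to CSV
#'
#' Columns: variant, dbar, pd, dic, sf.
#'
#' @param cmp a `fit_comparison`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  utils::write.csv(cmp$table, path, row.names = FALSE)
  invisible(path)
}
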