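#' Specify one of the four nested model variants
#'
#' The linear predictor for individual j in area i is, by variant:
#' \describe{
#'   \item{M1}{`alpha + v_i` (intercept + independent area heterogeneity)}
#'   \item{M2}{`alpha + X_ij' beta + v_i` (adds individual covariates)}
#'   \item{M3}{`alpha + X_ij' beta + W_i' gamma + v_i` (adds area covariates)}
#'   \item{M4}{`alpha + X_ij' beta + W_i' gamma + u_i + v_i` (adds the CAR
#'     spatial effect: the BYM convolution)}
#' }
#' with `y_ij ~ Bernoulli(logit^-1(lambda_ij))`. Priors: N(0, 10000) on the
#' intercept and every fixed coefficient; Gamma(shape, rate) on each random
#' effect precision 1/sigma^2 (equivalently logGamma on the log precision),
#' with the vague default Gamma(1, 0.0005). A sensitivity analysis uses
#' Gamma(1, 1).
#'
#' @param variant one of "M1", "M2", "M3", "M4".
#' @param individual_covariates covariate names entering X (ignored for M1).
#' @param area_covariates covariate names entering W (M3/M4 only).
#' @param prior_fixed_variance variance of the normal prior on alpha, beta,
#'   gamma (default 10000).
#' @param prior_logprec_shape,prior_logprec_rate shape and rate of the
#'   Gamma prior on precisions (defaults 1 and 0.0005); set the rate to 1
#'   for the sensitivity prior.
#' @param prior_scale_parameterization if TRUE interpret
#'   `prior_logprec_rate` as a scale instead of a rate.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(variant = c("M4", "M1", "M2", "M3"),
                       individual_covariates = character(0),
                       area_covariates = character(0),
                       prior_fixed_variance = 1e4,
                       prior_logprec_shape = 1,
                       prior_logprec_rate = 5e-4,
                       prior_scale_parameterization = FALSE) {
  variant <- match.arg(variant)
  if (variant == "M1") individual_covariates <- character(0)
  if (variant %in% c("M1", "M2")) area_covariates <- character(0)
  stopifnot(prior_fixed_variance > 0, prior_logprec_shape > 0,
            prior_logprec_rate > 0)
  rate <- if (prior_scale_parameterization) 1 / prior_logprec_rate else
    prior_logprec_rate
  structure(list(variant = variant,
                 individual_covariates = as.character(individual_covariates),
                 area_covariates = as.character(area_covariates),
                 prior_fixed_variance = prior_fixed_variance,
                 prior_logprec_shape = prior_logprec_shape,
                 prior_logprec_rate = rate),
            class = "model_spec")
}

#' Does a variant include a model component?
#' @param spec a [model_spec()].
#' @param what one of "beta", "gamma", "u".
#' @return Logical.
#' @export
has_component <- function(spec, what = c("beta", "gamma", "u")) {
  what <- match.arg(what)
  switch(what,
         beta  = spec$variant %in% c("M2", "M3", "M4"),
         gamma = spec$variant %in% c("M3", "M4"),
         u     = spec$variant == "M4")
}

#' Construct a full parameter state
#'
#' Holds every parameter of the model at one point: intercept, fixed
#' effects, the two area random-effect vectors and their variances.
#' Components absent from the variant are pinned at zero.
#'
#' @param spec a [model_spec()].
#' @param design a [encode_design()] result (fixes dimensions).
#' @param alpha,beta,gamma,u,v,sigma_u2,sigma_v2 parameter values; defaults
#'   are zeros and unit variances.
#' @return Object of class `parameter_state`.
#' @export
parameter_state <- function(spec, design, alpha = 0,
                            beta = NULL, gamma = NULL, u = NULL, v = NULL,
                            sigma_u2 = 1, sigma_v2 = 1) {
  N <- length(design$areas)
  p <- ncol(design$X); q <- ncol(design$W)
  beta <- beta %||% numeric(p)
  gamma <- gamma %||% numeric(q)
  u <- u %||% numeric(N)
  v <- v %||% numeric(N)
  if (!has_component(spec, "beta")) beta <- numeric(p) * 0
  if (!has_component(spec, "gamma")) gamma <- numeric(q) * 0
  if (!has_component(spec, "u")) u <- numeric(N)
  stopifnot(length(beta) == p, length(gamma) == q,
            length(u) == N, length(v) == N,
            sigma_v2 > 0, sigma_u2 > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, u = u, v = v,
                 sigma_u2 = sigma_u2, sigma_v2 = sigma_v2),
            class = "parameter_state")
}

#' Linear predictor over individuals
#'
#' lambda_ij = alpha + X_ij' beta + W_i' gamma + u_i + v_i, with terms
#' absent from the variant contributing zero.
#'
#' @param state a [parameter_state()].
#' @param design a [encode_design()] result.
#' @param spec a [model_spec()].
#' @return Numeric vector, one element per individual.
#' @export
linear_predictor <- function(state, design, spec) {
  eta <- rep(state$alpha, length(design$y))
  if (has_component(spec, "beta") && ncol(design$X) > 0) {
    if (length(state$beta) != ncol(design$X))
      stop("beta length does not match X", call. = FALSE)
    eta <- eta + drop(design$X %*% state$beta)
  }
  if (has_component(spec, "gamma") && ncol(design$W) > 0) {
    if (length(state$gamma) != ncol(design$W))
      stop("gamma length does not match W", call. = FALSE)
    eta <- eta + drop(design$W_area %*% state$gamma)[design$area_index]
  }
  if (has_component(spec, "u")) eta <- eta + state$u[design$area_index]
  eta + state$v[design$area_index]
}

# log(1 + exp(x)) without overflow for |x| up to ~700
log1pexp <- function(x) {
  out <- x
  small <- x <= 37
  out[small] <- log1p(exp(x[small]))
  big <- x > 37 & x <= 709
  out[big] <- x[big] + log1p(exp(-x[big]))
  out
}

#' Bernoulli log-likelihood on the logit scale
#'
#' sum(y * lambda - log(1 + exp(lambda))), computed overflow-safely.
#'
#' @param y 0/1 outcomes.
#' @param eta linear predictor, same length.
#' @return Scalar log-likelihood.
#' @export
log_likelihood_bern <- function(y, eta) {
  if (length(y) != length(eta)) stop("length mismatch", call. = FALSE)
  sum(y * eta - log1pexp(eta))
}

#' Inverse logit with clipping
#'
#' @param eta linear predictor; clipped at +-35 before exponentiation (the
#'   probability is already within 1e-15 of 0/1 there).
#' @return Probabilities in (0, 1).
#' @export
inv_logit <- function(eta) stats::plogis(pmin(pmax(eta, -35), 35))

#' Log prior density of a parameter state
#'
#' Normal(0, prior_fixed_variance) on alpha and each beta/gamma coefficient;
#' Gamma(shape, rate) on the precisions 1/sigma_v2 (and 1/sigma_u2 for M4),
#' including the Jacobian-free evaluation on the precision scale;
#' Normal(0, sigma_v2) on each v_i; and for M4 the improper intrinsic CAR
#' generalized density
#' -(rank(Q)/2) log(sigma_u2) - u' Q u / (2 sigma_u2)
#' on u (its normalizing constant over the constrained subspace is a fixed
#' number independent of parameters and is omitted).
#'
#' @param state a [parameter_state()].
#' @param spec a [model_spec()].
#' @param graph an [area_graph()] (needed for M4).
#' @return Scalar log prior (up to the constant CAR normalizer).
#' @export
log_prior <- function(state, spec, graph = NULL) {
  if (state$sigma_v2 <= 0 || state$sigma_u2 <= 0)
    stop("variances must be positive", call. = FALSE)
  sdf <- sqrt(spec$prior_fixed_variance)
  lp <- stats::dnorm(state$alpha, 0, sdf, log = TRUE)
  if (has_component(spec, "beta") && length(state$beta))
    lp <- lp + sum(stats::dnorm(state$beta, 0, sdf, log = TRUE))
  if (has_component(spec, "gamma") && length(state$gamma))
    lp <- lp + sum(stats::dnorm(state$gamma, 0, sdf, log = TRUE))
  lp <- lp + sum(stats::dnorm(state$v, 0, sqrt(state$sigma_v2), log = TRUE))
  lp <- lp + stats::dgamma(1 / state$sigma_v2, shape = spec$prior_logprec_shape,
                           rate = spec$prior_logprec_rate, log = TRUE)
  if (has_component(spec, "u")) {
    if (is.null(graph)) stop("M4 requires the area graph", call. = FALSE)
    qf <- car_quadform(graph, state$u)
    lp <- lp - (car_rank(graph) / 2) * log(state$sigma_u2) -
      qf / (2 * state$sigma_u2)
    lp <- lp + stats::dgamma(1 / state$sigma_u2, shape = spec$prior_logprec_shape,
                             rate = spec$prior_logprec_rate, log = TRUE)
  }
  lp
}

#' CAR quadratic form u' Q u
#'
#' Computed edgewise as the sum of squared differences across adjacent
#' pairs, avoiding the N x N matrix.
#'
#' @param graph an [area_graph()].
#' @param u effect vector.
#' @return Scalar.
#' @export
car_quadform <- function(graph, u) {
  if (!nrow(graph$edges)) return(0)
  sum((u[graph$edges[, 1L]] - u[graph$edges[, 2L]])^2)
}

#' Log posterior (likelihood + prior)
#'
#' @param state a [parameter_state()].
#' @param design a [encode_design()] result.
#' @param spec a [model_spec()].
#' @param graph an [area_graph()] for M4.
#' @return Scalar log posterior up to an additive constant.
#' @export
log_posterior <- function(state, design, spec, graph = NULL) {
  log_likelihood_bern(design$y, linear_predictor(state, design, spec)) +
    log_prior(state, spec, graph)
}
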