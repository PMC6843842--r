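#' MCMC settings
#'
#' @param chains number of independent chains.
#' @param iter total iterations per chain (including burn-in).
#' @param burn_in iterations discarded per chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param adapt adapt random-walk scales during burn-in towards ~0.44
#'   acceptance (Roberts-Rosenthal optimal scalar rate); scales are frozen
#'   after burn-in so the retained chain is a genuine Markov chain.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4L, iter = 10000L, burn_in = 5000L,
                         thin = 5L, adapt = TRUE) {
  stopifnot(chains >= 1, iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 adapt = isTRUE(adapt)),
            class = "mcmc_control")
}

#' Fit a Bayesian spatial multilevel logistic model by MCMC
#'
#' Metropolis-within-Gibbs: adaptive random-walk Metropolis updates for the
#' intercept and each fixed coefficient; blocked random-walk updates for the
#' independent area effects v (all areas in parallel, valid because their
#' full conditionals are mutually independent) and for the CAR effects u
#' (areas of one graph colour in parallel, valid because non-adjacent CAR
#' conditionals are mutually independent); conjugate Gibbs draws for the
#' precisions 1/sigma_v2 and 1/sigma_u2, which have Gamma full conditionals
#' under the Gamma(shape, rate) prior. After every sweep u is re-centred to
#' mean zero with the subtracted mean absorbed into the intercept, which
#' leaves the linear predictor unchanged and resolves the intrinsic CAR's
#' level non-identifiability.
#'
#' @param ds a [multilevel_dataset()].
#' @param graph an [area_graph()] over `ds$areas` (required for M4; for
#'   other variants it may be NULL).
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed; the fit is bit-reproducible given the seed
#'   (chain c uses seed + c - 1).
#' @param init optional [parameter_state()] used as the starting state.
#' @return Object of class `posterior_draws`: `draws` (matrix, one row per
#'   retained draw across all chains), `chain` (chain id per row), `meta`
#'   (settings, acceptance rates, Gelman-Rubin R-hat), `spec`, `design`,
#'   `graph`.
#' @export
fit_bym <- function(ds, graph = NULL, spec, mcmc = mcmc_control(),
                    seed, init = NULL) {
  stopifnot(inherits(ds, "multilevel_dataset"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_control"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  if (has_component(spec, "u")) {
    if (is.null(graph)) stop("variant M4 requires an area graph", call. = FALSE)
    if (!identical(graph$areas, ds$areas))
      stop("graph areas do not match dataset areas", call. = FALSE)
  }
  design <- encode_design(ds, spec)

  chains <- lapply(seq_len(mcmc$chains), function(ch)
    run_chain(design, graph, spec, mcmc, seed = seed + ch - 1L, init = init))
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(mcmc$chains), each = nrow(chains[[1L]]$draws))

  acc <- Reduce(`+`, lapply(chains, `[[`, "accept")) / mcmc$chains
  scalar_cols <- attr(chains[[1L]]$draws, "scalar_cols")
  rhat <- gelman_rubin(lapply(chains, function(ch)
    ch$draws[, scalar_cols, drop = FALSE]))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("Gelman-Rubin R-hat > 1.05 for: ",
            paste(names(rhat)[which(rhat > 1.05)], collapse = ", "),
            "; consider more iterations", call. = FALSE)
  bad_acc <- acc < 0.1 | acc > 0.6
  if (any(bad_acc))
    warning("post-adaptation acceptance outside [0.1, 0.6] for: ",
            paste(names(acc)[bad_acc], collapse = ", "), call. = FALSE)

  structure(list(draws = draws, chain = chain_id,
                 meta = list(chains = mcmc$chains, iter = mcmc$iter,
                             burn_in = mcmc$burn_in, thin = mcmc$thin,
                             seed = seed, accept = acc, rhat = rhat),
                 spec = spec, design = design, graph = graph),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> variant ", x$spec$variant, ": ", nrow(x$draws),
      " retained draws (", x$meta$chains, " chain(s))\n", sep = "")
  cat("  max R-hat: ", formatC(max(x$meta$rhat, na.rm = TRUE), digits = 3,
                               format = "f"), "\n", sep = "")
  invisible(x)
}

# one chain of the Metropolis-within-Gibbs sampler
run_chain <- function(design, graph, spec, mcmc, seed, init = NULL) {
  set.seed(seed)
  y <- design$y
  n <- length(y)
  N <- length(design$areas)
  ai <- design$area_index
  p <- if (has_component(spec, "beta")) ncol(design$X) else 0L
  q <- if (has_component(spec, "gamma")) ncol(design$W) else 0L
  use_u <- has_component(spec, "u")
  tau_shape <- spec$prior_logprec_shape
  tau_rate <- spec$prior_logprec_rate
  prec_fixed <- 1 / spec$prior_fixed_variance

  # state
  alpha <- init$alpha %||% stats::qlogis(max(min(mean(y), 0.99), 0.01))
  beta <- init$beta %||% numeric(p)
  gamma <- init$gamma %||% numeric(q)
  v <- init$v %||% numeric(N)
  u <- if (use_u) (init$u %||% numeric(N)) else numeric(N)
  sigma_v2 <- init$sigma_v2 %||% 0.1
  sigma_u2 <- init$sigma_u2 %||% 0.1

  # per-coefficient row index sets (rows where the indicator is 1)
  brows <- if (p) lapply(seq_len(p), function(j) which(design$X[, j] == 1)) else list()
  grows <- if (q) lapply(seq_len(q), function(j) which(design$W[, j] == 1)) else list()

  # colour classes for parallel CAR updates; neighbour sums for conditionals
  if (use_u) {
    col <- graph_coloring(graph)
    classes <- split(seq_len(N), col)
    class_rows <- lapply(classes, function(cl) which(ai %in% cl))
    e1 <- graph$edges[, 1L]; e2 <- graph$edges[, 2L]
    wplus <- pmax(graph$w_plus, 1L) # islands never updated, avoid 0-div
    islands <- which(graph$w_plus == 0L)
    qrank <- car_rank(graph)
    Q <- car_precision(graph)
    # one-off eigendecomposition of Q for the marginalized variance move
    eg <- eigen(Q, symmetric = TRUE)
    ev_pos <- eg$values > max(eg$values) * 1e-10
    lam <- eg$values[ev_pos]
    Vb <- eg$vectors
    n_null <- N - sum(ev_pos)
    s_var <- 0.8 # scale of the joint (log sigma_u2, log sigma_v2) proposal
  }

  # log target of (sigma_u2, sigma_v2) given b = u + v with u integrated
  # out: in the eigenbasis of Q the coordinates of b are independent with
  # variance sigma_u2/lambda_k + sigma_v2 (sigma_v2 alone on the null
  # space); precision priors enter with the Jacobian to the log-variance
  # scale.
  var_marginal_lp <- function(su2, sv2, bt2) {
    vk <- c(su2 / lam + sv2, rep(sv2, n_null))
    -0.5 * sum(bt2 / vk + log(vk)) +
      stats::dgamma(1 / su2, tau_shape, rate = tau_rate, log = TRUE) - log(su2) +
      stats::dgamma(1 / sv2, tau_shape, rate = tau_rate, log = TRUE) - log(sv2)
  }

  eta_fixed <- rep(alpha, n)
  if (p) eta_fixed <- eta_fixed + drop(design$X %*% beta)
  if (q) eta_fixed <- eta_fixed + drop(design$W %*% gamma)
  eta <- eta_fixed + (u + v)[ai]
  ll_row <- y * eta - log1pexp(eta) # per-row log-likelihood, kept current

  # adaptive scales
  s_alpha <- 0.1
  s_beta <- rep(0.1, p); s_gamma <- rep(0.2, q)
  s_v <- rep(0.5, N); s_u <- rep(0.5, N)
  n_scalar_acc <- stats::setNames(numeric(1 + p + q),
                                  c("alpha",
                                    if (p) paste0("beta.", design$x_names),
                                    if (q) paste0("gamma.", design$w_names)))
  n_v_acc <- 0; n_u_acc <- 0
  post_acc <- n_scalar_acc; post_v_acc <- 0; post_u_acc <- 0; n_post <- 0

  n_keep <- (mcmc$iter - mcmc$burn_in) %/% mcmc$thin
  cn <- c("alpha",
          if (p) paste0("beta.", design$x_names),
          if (q) paste0("gamma.", design$w_names),
          "sigma_v2", if (use_u) "sigma_u2",
          paste0("v.", design$areas), if (use_u) paste0("u.", design$areas),
          "deviance")
  out <- matrix(NA_real_, n_keep, length(cn), dimnames = list(NULL, cn))
  kept <- 0L

  gain <- function(t) min(0.25, 5 / sqrt(t + 10))

  for (t in seq_len(mcmc$iter)) {
    adapting <- mcmc$adapt && t <= mcmc$burn_in
    g <- gain(t)

    ## --- intercept ---
    d <- stats::rnorm(1L, 0, s_alpha)
    eta_new <- eta + d
    llr_new <- y * eta_new - log1pexp(eta_new)
    dll <- sum(llr_new) - sum(ll_row)
    dlp <- -0.5 * prec_fixed * ((alpha + d)^2 - alpha^2)
    if (log(stats::runif(1L)) < dll + dlp) {
      alpha <- alpha + d; eta <- eta_new; ll_row <- llr_new
      n_scalar_acc["alpha"] <- n_scalar_acc["alpha"] + 1
      if (!adapting) post_acc["alpha"] <- post_acc["alpha"] + 1
      if (adapting) s_alpha <- s_alpha * exp(g * 0.56)
    } else if (adapting) s_alpha <- s_alpha * exp(-g * 0.44)

    ## --- individual-level coefficients ---
    if (p) for (j in seq_len(p)) {
      r <- brows[[j]]
      d <- stats::rnorm(1L, 0, s_beta[j])
      en <- eta[r] + d
      lln <- y[r] * en - log1pexp(en)
      dll <- sum(lln) - sum(ll_row[r])
      dlp <- -0.5 * prec_fixed * ((beta[j] + d)^2 - beta[j]^2)
      nm <- paste0("beta.", design$x_names[j])
      if (log(stats::runif(1L)) < dll + dlp) {
        beta[j] <- beta[j] + d; eta[r] <- en; ll_row[r] <- lln
        n_scalar_acc[nm] <- n_scalar_acc[nm] + 1
        if (!adapting) post_acc[nm] <- post_acc[nm] + 1
        if (adapting) s_beta[j] <- s_beta[j] * exp(g * 0.56)
      } else if (adapting) s_beta[j] <- s_beta[j] * exp(-g * 0.44)
    }

    ## --- area-level coefficients ---
    if (q) for (j in seq_len(q)) {
      r <- grows[[j]]
      d <- stats::rnorm(1L, 0, s_gamma[j])
      en <- eta[r] + d
      lln <- y[r] * en - log1pexp(en)
      dll <- sum(lln) - sum(ll_row[r])
      dlp <- -0.5 * prec_fixed * ((gamma[j] + d)^2 - gamma[j]^2)
      nm <- paste0("gamma.", design$w_names[j])
      if (log(stats::runif(1L)) < dll + dlp) {
        gamma[j] <- gamma[j] + d; eta[r] <- en; ll_row[r] <- lln
        n_scalar_acc[nm] <- n_scalar_acc[nm] + 1
        if (!adapting) post_acc[nm] <- post_acc[nm] + 1
        if (adapting) s_gamma[j] <- s_gamma[j] * exp(g * 0.56)
      } else if (adapting) s_gamma[j] <- s_gamma[j] * exp(-g * 0.44)
    }

    ## --- independent heterogeneity effects v (all areas in parallel) ---
    d <- stats::rnorm(N, 0, s_v)
    en <- eta + d[ai]
    lln <- y * en - log1pexp(en)
    dll_area <- rowsum_vec(lln - ll_row, ai, N)
    dlp_area <- -0.5 * ((v + d)^2 - v^2) / sigma_v2
    acc <- log(stats::runif(N)) < dll_area + dlp_area
    if (any(acc)) {
      v[acc] <- v[acc] + d[acc]
      racc <- acc[ai]
      eta[racc] <- en[racc]; ll_row[racc] <- lln[racc]
    }
    n_v_acc <- n_v_acc + mean(acc)
    if (!adapting) post_v_acc <- post_v_acc + mean(acc)
    if (adapting) s_v <- s_v * exp(g * ifelse(acc, 0.56, -0.44))

    ## --- CAR effects u, one colour class at a time ---
    if (use_u) {
      nbsum <- numeric(N) # sum of neighbours' u
      nbsum <- nbsum + rowsum_vec(u[e2], e1, N) + rowsum_vec(u[e1], e2, N)
      for (ci in seq_along(classes)) {
        cl <- classes[[ci]]
        cl <- setdiff(cl, islands)
        if (!length(cl)) next
        r <- class_rows[[ci]]
        d_area <- numeric(N)
        d_area[cl] <- stats::rnorm(length(cl), 0, s_u[cl])
        en <- eta[r] + d_area[ai[r]]
        lln <- y[r] * en - log1pexp(en)
        dll_area <- rowsum_vec(lln - ll_row[r], ai[r], N)
        # CAR full-conditional prior: N(nbsum/w+, sigma_u2/w+)
        m <- nbsum[cl] / wplus[cl]
        dlp_cl <- -0.5 * wplus[cl] *
          ((u[cl] + d_area[cl] - m)^2 - (u[cl] - m)^2) / sigma_u2
        acc_cl <- log(stats::runif(length(cl))) < dll_area[cl] + dlp_cl
        moved <- cl[acc_cl]
        if (length(moved)) {
          u[moved] <- u[moved] + d_area[moved]
          racc <- ai[r] %in% moved
          idx <- r[racc]
          eta[idx] <- en[racc]; ll_row[idx] <- lln[racc]
          # refresh neighbour sums touched by moved areas
          nbsum <- rowsum_vec(u[e2], e1, N) + rowsum_vec(u[e1], e2, N)
        }
        n_u_acc <- n_u_acc + sum(acc_cl) / (N - length(islands))
        if (!adapting) post_u_acc <- post_u_acc + sum(acc_cl) / (N - length(islands))
        if (adapting) s_u[cl] <- s_u[cl] * exp(g * ifelse(acc_cl, 0.56, -0.44))
      }
      # identifiability: absorb the mean level of u into the intercept
      # (eta unchanged). With several components the residual per-component
      # means are also removed (WinBUGS car.normal convention), which
      # requires refreshing eta.
      ub <- mean(u)
      if (ub != 0) { u <- u - ub; alpha <- alpha + ub }
      if (graph$n_components > 1L) {
        cm <- stats::ave(u, graph$component)
        if (any(cm != 0)) {
          u <- u - cm
          eta <- eta - cm[ai]
          ll_row <- y * eta - log1pexp(eta)
        }
      }
    }

    ## --- marginalized variance move ---
    # random-walk Metropolis on (log sigma_u2, log sigma_v2) against the
    # marginal of b = u + v, so the variance partition moves without
    # dragging the current u/v split along (the partition otherwise mixes
    # pathologically slowly).
    if (use_u) {
      b <- u + v
      bt2 <- drop(crossprod(Vb, b))^2
      cur_lp <- var_marginal_lp(sigma_u2, sigma_v2, bt2)
      for (rep in 1:8) {
        prop_u <- sigma_u2 * exp(stats::rnorm(1L, 0, s_var))
        prop_v <- sigma_v2 * exp(stats::rnorm(1L, 0, s_var))
        prop_lp <- var_marginal_lp(prop_u, prop_v, bt2)
        if (log(stats::runif(1L)) < prop_lp - cur_lp) {
          sigma_u2 <- prop_u; sigma_v2 <- prop_v; cur_lp <- prop_lp
        }
      }
    }

    ## --- joint redistribution of the convolution u + v ---
    # the likelihood sees only b = u + v; given b and the variances, u is
    # exactly Gaussian with precision Q/sigma_u2 + I/sigma_v2, so the u/v
    # split (and hence the variance partition) can be redrawn by Gibbs.
    # Without this move the split mixes pathologically slowly.
    if (use_u) {
      b <- u + v
      P <- Q / sigma_u2
      diag(P) <- diag(P) + 1 / sigma_v2
      ch <- chol(P)
      m <- backsolve(ch, forwardsolve(ch, b / sigma_v2, upper.tri = TRUE,
                                      transpose = TRUE))
      u <- drop(m + backsolve(ch, stats::rnorm(N)))
      if (length(islands)) u[islands] <- 0
      v <- b - u
      ub <- mean(u) # absorb the level into the intercept, eta unchanged
      if (ub != 0) { u <- u - ub; alpha <- alpha + ub }
    }

    ## --- level transfer between intercept and v ---
    # alpha and the mean of v are identified only through their sum; this
    # move shifts level between them along the likelihood-invariant
    # direction (eta unchanged); the conditional of the shift is Gaussian
    # in the priors alone, so this is an exact Gibbs draw.
    prec_d <- N / sigma_v2 + prec_fixed
    mean_d <- (N * mean(v) / sigma_v2 - alpha * prec_fixed) / prec_d
    d <- stats::rnorm(1L, mean_d, sqrt(1 / prec_d))
    alpha <- alpha + d; v <- v - d

    ## --- variance Gibbs updates (Gamma full conditionals on precisions) ---
    tau_v <- stats::rgamma(1L, shape = tau_shape + N / 2,
                           rate = tau_rate + sum(v^2) / 2)
    sigma_v2 <- 1 / tau_v
    if (use_u) {
      tau_u <- stats::rgamma(1L, shape = tau_shape + qrank / 2,
                             rate = tau_rate + car_quadform(graph, u) / 2)
      sigma_u2 <- 1 / tau_u
    }

    if (!adapting) n_post <- n_post + 1

    ## --- record ---
    if (t > mcmc$burn_in && (t - mcmc$burn_in) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- c(alpha, if (p) beta, if (q) gamma,
                       sigma_v2, if (use_u) sigma_u2,
                       v, if (use_u) u,
                       -2 * sum(ll_row))
    }
  }

  scalar_cols <- c("alpha",
                   if (p) paste0("beta.", design$x_names),
                   if (q) paste0("gamma.", design$w_names),
                   "sigma_v2", if (use_u) "sigma_u2")
  attr(out, "scalar_cols") <- scalar_cols
  acc_rates <- c(post_acc / max(n_post, 1),
                 v = post_v_acc / max(n_post, 1),
                 if (use_u) c(u = post_u_acc / max(n_post, 1)))
  list(draws = out, accept = acc_rates)
}

# fast grouped sum of a vector into n bins (groups are integer indices)
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic between/within-chain R-hat. With a single chain the chain is
#' split in half and the halves compared.
#'
#' @param chain_list list of draw matrices with identical column names.
#' @return Named vector of R-hat values.
#' @export
gelman_rubin <- function(chain_list) {
  if (length(chain_list) == 1L) {
    m <- chain_list[[1L]]
    h <- nrow(m) %/% 2L
    chain_list <- list(m[seq_len(h), , drop = FALSE],
                       m[(h + 1L):(2L * h), , drop = FALSE])
  }
  M <- length(chain_list)
  nit <- nrow(chain_list[[1L]])
  vapply(colnames(chain_list[[1L]]), function(cl) {
    means <- vapply(chain_list, function(ch) mean(ch[, cl]), 0)
    vars <- vapply(chain_list, function(ch) stats::var(ch[, cl]), 0)
    W <- mean(vars)
    B <- nit * stats::var(means)
    if (!is.finite(W) || !is.finite(B) || W <= 0) return(NA_real_)
    sqrt(((nit - 1) / nit * W + B / nit) / W)
  }, 0)
}

#' Posterior draws of one parameter
#'
#' @param fit a `posterior_draws` object.
#' @param name column name, e.g. `"alpha"`, `"sigma_u2"`,
#'   `"beta.smoking:current"`.
#' @return Numeric vector of draws.
#' @export
param_draws <- function(fit, name) {
  if (!name %in% colnames(fit$draws)) stop("no parameter named '", name, "'",
                                           call. = FALSE)
  fit$draws[, name]
}

#' Summarize fixed effects as odds ratios with credible intervals
#'
#' One row per coefficient: posterior mean on the log-odds scale, the odds
#' ratio exp(mean), and the equal-tailed 95% credible interval of
#' exp(coefficient) (2.5th and 97.5th percentiles). `significant` flags
#' intervals excluding 1 (the criterion used to bold effects in reports).
#'
#' @param fit a `posterior_draws` object.
#' @param level credible level (default 0.95).
#' @param include_intercept include a row for alpha (on the OR scale this is
#'   the baseline odds).
#' @return data.frame of class `effect_summary`.
#' @export
summarize_effects <- function(fit, level = 0.95, include_intercept = FALSE) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (nrow(fit$draws) < 200L)
    stop("need at least 200 retained draws to summarize", call. = FALSE)
  cols <- grep("^(beta|gamma)\\.", colnames(fit$draws), value = TRUE)
  if (include_intercept) cols <- c("alpha", cols)
  a <- (1 - level) / 2
  rows <- lapply(cols, function(cl) {
    b <- fit$draws[, cl]
    ci <- unname(stats::quantile(exp(b), c(a, 1 - a)))
    data.frame(name = sub("^(beta|gamma)\\.", "", cl),
               group = if (startsWith(cl, "gamma.")) "area" else
                 if (startsWith(cl, "beta.")) "individual" else "intercept",
               posterior_mean = mean(b), or = exp(mean(b)),
               cri_low = ci[1L], cri_high = ci[2L],
               significant = ci[1L] > 1 | ci[2L] < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Write retained draws and metadata to disk
#'
#' Draws go to a flat CSV (one row per retained draw, one column per
#' parameter); chain settings, seed, acceptance rates and R-hat go to a
#' JSON sidecar `<path>.meta.json`.
#'
#' @param fit a `posterior_draws` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  meta <- fit$meta
  meta$accept <- as.list(meta$accept)
  meta$rhat <- as.list(meta$rhat)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
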