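# small simulated fixtures keep the sampler tests inside a few minutes

test_that("identical seeds give bit-identical draws; settings are honoured", {
  sim <- simulate_cohort(sim_config(n_areas = 9L, mean_individuals = 25,
                                    individual = list(), area = list(),
                                    sigma_u2 = 0.2, sigma_v2 = 0.1,
                                    seed = 5L))
  sp <- model_spec("M4")
  ctl <- mcmc_control(chains = 2L, iter = 400L, burn_in = 200L, thin = 2L)
  f1 <- suppressWarnings(fit_bym(sim$ds, sim$graph, sp, ctl, seed = 3L))
  f2 <- suppressWarnings(fit_bym(sim$ds, sim$graph, sp, ctl, seed = 3L))
  expect_identical(f1$draws, f2$draws)
  # chains x (iter - burn_in)/thin retained draws
  expect_equal(nrow(f1$draws), 2L * (400L - 200L) %/% 2L)
  f3 <- suppressWarnings(fit_bym(sim$ds, sim$graph, sp, ctl, seed = 4L))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("M1 recovers the intercept on data with pure area heterogeneity", {
  cfg <- sim_config(n_areas = 100L, mean_individuals = 100, nb_size = Inf,
                    alpha = -1.1, individual = list(), area = list(),
                    sigma_u2 = 0, sigma_v2 = 0.09, seed = 61L)
  sim <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_bym(sim$ds, sim$graph, model_spec("M1"),
            mcmc_control(chains = 1L, iter = 2000L, burn_in = 1000L,
                         thin = 2L), seed = 62L))
  ci <- quantile(param_draws(fit, "alpha"), c(0.025, 0.975))
  expect_lt(ci[1L], -1.1)
  expect_gt(ci[2L], -1.1)
  # v standard deviation estimated in the right range
  expect_lt(abs(sqrt(mean(param_draws(fit, "sigma_v2"))) - 0.3), 0.2)
})

test_that("zero spatial signal concentrates sigma_u2 near zero relative to sigma_v2", {
  cfg <- sim_config(n_areas = 64L, mean_individuals = 60, nb_size = Inf,
                    alpha = -1, individual = list(), area = list(),
                    sigma_u2 = 0, sigma_v2 = 0.5, seed = 71L)
  sim <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_bym(sim$ds, sim$graph, model_spec("M4"),
            mcmc_control(chains = 1L, iter = 2500L, burn_in = 1200L,
                         thin = 2L), seed = 72L))
  sf <- posterior_sf(fit)
  expect_lt(sf$mean, 0.5)
})

test_that("summaries transform coefficient draws exactly", {
  sim <- simulate_cohort(sim_config(n_areas = 9L, mean_individuals = 30,
                                    individual = list(
                                      x = list(levels = c("a", "b"),
                                               probs = c(0.5, 0.5),
                                               effects = c(b = 0.3))),
                                    area = list(), sigma_u2 = 0.1,
                                    sigma_v2 = 0.1, seed = 9L))
  fit <- suppressWarnings(
    fit_bym(sim$ds, sim$graph, model_spec("M4", "x"),
            mcmc_control(chains = 1L, iter = 700L, burn_in = 200L,
                         thin = 1L), seed = 10L))
  # constant draws: OR = exp(value), CrI degenerate
  fit$draws[, "beta.x:b"] <- log(2)
  s <- summarize_effects(fit)
  expect_equal(s$or[s$name == "x:b"], 2)
  expect_equal(s$cri_low[s$name == "x:b"], 2)
  expect_equal(s$cri_high[s$name == "x:b"], 2)
  expect_false(s$significant[s$name == "x:b"] == FALSE) # CrI excludes 1

  fit$draws[, "beta.x:b"] <- 0
  s0 <- summarize_effects(fit)
  expect_equal(s0$or[1L], 1)
  expect_false(s0$significant[1L])

  # percentile CrI equals the sorted-array oracle
  set.seed(11)
  z <- rnorm(1000L, 0.2, 0.4)
  fit$draws <- fit$draws[rep(seq_len(nrow(fit$draws)), length.out = 1000L), ]
  fit$draws[, "beta.x:b"] <- z
  s2 <- summarize_effects(fit)
  sorted <- sort(exp(z))
  # type-7 interpolation at p = 0.025, 0.975 on n = 1000
  orac <- function(p) {
    h <- (1000 - 1) * p + 1
    sorted[floor(h)] + (h - floor(h)) * (sorted[floor(h) + 1] - sorted[floor(h)])
  }
  expect_equal(s2$cri_low[1L], orac(0.025), tolerance = 1e-12)
  expect_equal(s2$cri_high[1L], orac(0.975), tolerance = 1e-12)
})

test_that("too few draws are refused by summarize_effects", {
  sim <- simulate_cohort(sim_config(n_areas = 4L, mean_individuals = 20,
                                    individual = list(), area = list(),
                                    sigma_u2 = 0.1, sigma_v2 = 0.1,
                                    seed = 13L))
  fit <- suppressWarnings(
    fit_bym(sim$ds, sim$graph, model_spec("M4"),
            mcmc_control(chains = 1L, iter = 150L, burn_in = 50L, thin = 1L),
            seed = 14L))
  expect_error(summarize_effects(fit), "at least 200")
})

test_that("M2 posterior means agree with Newton maximum likelihood", {
  # near-flat priors and a tiny v variance make the Bayesian fit collapse
  # onto ordinary logistic regression; the screening module's Newton
  # fitter is the independent oracle
  set.seed(15)
  n <- 2000L
  x <- sample(c("a", "b", "c"), n, TRUE)
  eta <- -0.8 + 0.5 * (x == "b") - 0.4 * (x == "c")
  y <- rbinom(n, 1L, plogis(eta))
  rec <- data.frame(area_id = "Z1", outcome = y, x = x,
                    stringsAsFactors = FALSE)
  schema <- covariate_schema(individual = list(
    x = list(levels = c("a", "b", "c"), reference = "a")))
  ds <- multilevel_dataset(rec, schema)
  g1 <- suppressWarnings(area_graph(NULL, "Z1")) # single area: island by design

  ml <- fit_univariate_logistic(y, x, reference = "a")

  spec <- model_spec("M2", "x")
  fit <- suppressWarnings(
    fit_bym(ds, g1, spec,
            mcmc_control(chains = 1L, iter = 4000L, burn_in = 1500L,
                         thin = 2L), seed = 16L))
  for (nm in c("b", "c")) {
    draws <- param_draws(fit, paste0("beta.x:", nm))
    mcse <- sd(draws) / sqrt(nrow(fit$draws) / 10) # conservative ESS guess
    expect_lt(abs(mean(draws) - ml$coef[[nm]]),
              max(2 * mcse, 2 * ml$se[[nm]]))
  }
})

test_that("posterior quantiles match an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  g <- lattice_graph(3L, 4L)
  cfg <- sim_config(n_areas = 12L, graph = g, mean_individuals = 60,
                    nb_size = Inf, alpha = -0.8, individual = list(),
                    area = list(), sigma_u2 = 0.5, sigma_v2 = 0.3, seed = 11L)
  sim <- simulate_cohort(cfg)
  y <- sim$ds$records$outcome
  ai <- match(sim$ds$records$area_id, sim$ds$areas)
  Q <- car_precision(g)

  jm <- "
  model {
    for (r in 1:n) { y[r] ~ dbern(ilogit(alpha + u[area[r]] + v[area[r]])) }
    for (i in 1:N) { v[i] ~ dnorm(0, tauv) }
    for (i in 1:(N-1)) { uf[i] ~ dnorm(0, 1.0E-6) }
    u[1:(N-1)] <- uf
    u[N] <- -sum(uf)
    for (i in 1:N) { Qu[i] <- inprod(Q[i,1:N], u[1:N]) }
    qf <- inprod(u[1:N], Qu[1:N])
    phi <- 0.5*qf*tauu - 0.5*(N-1)*log(tauu) + 1000
    zero ~ dpois(phi)
    alpha ~ dnorm(0, 1.0E-4)
    tauv ~ dgamma(1, 0.0005)
    tauu ~ dgamma(1, 0.0005)
    sv2 <- 1/tauv
    su2 <- 1/tauu
  }"
  mf <- withr::local_tempfile(fileext = ".jags")
  writeLines(jm, mf)
  jmod <- rjags::jags.model(
    mf, data = list(y = y, area = ai, n = length(y), N = 12L,
                    Q = unname(Q), zero = 0),
    n.chains = 1L, n.adapt = 1500L, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 20L))
  stats::update(jmod, 4000L, progress.bar = "none")
  samp <- rjags::coda.samples(jmod, c("alpha", "su2", "sv2"),
                              n.iter = 20000L, thin = 10L,
                              progress.bar = "none")[[1L]]

  fit <- suppressWarnings(
    fit_bym(sim$ds, g, model_spec("M4"),
            mcmc_control(chains = 1L, iter = 14000L, burn_in = 4000L,
                         thin = 5L), seed = 21L))

  for (pair in list(c("alpha", "alpha"), c("su2", "sigma_u2"),
                    c("sv2", "sigma_v2"))) {
    qj <- quantile(samp[, pair[1L]], c(0.25, 0.5, 0.75))
    qo <- quantile(param_draws(fit, pair[2L]), c(0.25, 0.5, 0.75))
    scale <- max(abs(qj), 0.05)
    expect_lt(max(abs(qj - qo)) / scale, 0.35)
  }
})
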