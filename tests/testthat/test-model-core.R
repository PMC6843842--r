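make_design <- function(n = 10L, seed = 14L) {
  ds <- tiny_dataset(n = n, n_areas = 4L, seed = seed)
  spec <- model_spec("M4", c("smoking", "mvpa"), "dist_pa_m")
  list(ds = ds, spec = spec, dm = encode_design(ds, spec))
}

test_that("linear predictor equals brute-force per-row dot products", {
  f <- make_design(n = 10L)
  set.seed(3)
  st <- parameter_state(f$spec, f$dm,
                        alpha = rnorm(1), beta = rnorm(3), gamma = rnorm(2),
                        u = rnorm(4), v = rnorm(4),
                        sigma_u2 = 0.5, sigma_v2 = 0.5)
  st$u <- st$u - mean(st$u)
  eta <- linear_predictor(st, f$dm, f$spec)
  for (r in seq_len(10L)) {
    a <- f$dm$area_index[r]
    manual <- st$alpha + sum(f$dm$X[r, ] * st$beta) +
      sum(f$dm$W[r, ] * st$gamma) + st$u[a] + st$v[a]
    expect_equal(eta[r], manual, tolerance = 1e-12)
  }
})

test_that("variant components are pinned at zero where absent", {
  f <- make_design()
  m1 <- model_spec("M1")
  st <- parameter_state(m1, f$dm, alpha = 0)
  expect_equal(linear_predictor(st, f$dm, m1), rep(0, 10L))
  expect_equal(inv_logit(linear_predictor(st, f$dm, m1)), rep(0.5, 10L))

  # M4 with all indicators zeroed reduces to alpha + u + v
  spec4 <- f$spec
  st4 <- parameter_state(spec4, f$dm, alpha = 0.3,
                         u = c(1, -1, 0.5, -0.5), v = c(0.1, 0.2, -0.1, -0.2))
  dm0 <- f$dm
  dm0$X[] <- 0; dm0$W[] <- 0; dm0$W_area[] <- 0
  eta <- linear_predictor(st4, dm0, spec4)
  expect_equal(eta, 0.3 + (st4$u + st4$v)[dm0$area_index])
})

test_that("Bernoulli log-likelihood matches the naive form and its limits", {
  expect_equal(log_likelihood_bern(1, 0), log(0.5))
  expect_equal(log_likelihood_bern(c(1, 0), c(0, 0)), 2 * log(0.5))
  # saturating limit: y = 1, lambda large -> contribution ~ 0
  expect_lt(abs(log_likelihood_bern(1, 700)), 1e-12)
  expect_true(is.finite(log_likelihood_bern(0, 700)))
  expect_true(is.finite(log_likelihood_bern(1, -700)))

  set.seed(4)
  y <- rbinom(20, 1, 0.5)
  eta <- rnorm(20, 0, 3)
  naive <- sum(log(ifelse(y == 1, plogis(eta), 1 - plogis(eta))))
  expect_equal(log_likelihood_bern(y, eta), naive, tolerance = 1e-10)
})

test_that("log prior matches closed forms", {
  f <- make_design()
  m1 <- model_spec("M1")
  # alpha = 0, v = 0, variances at 1: N(0,10000) at 0 + v normals +
  # Gamma(1, 5e-4) on tau_v = 1
  st <- parameter_state(m1, f$dm, alpha = 0, sigma_v2 = 1)
  lp <- log_prior(st, m1)
  manual <- dnorm(0, 0, 100, log = TRUE) + sum(dnorm(rep(0, 4), 0, 1, TRUE)) +
    dgamma(1, 1, rate = 5e-4, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12)

  # Gamma(1, 0.0005) on the precision is Exponential(0.0005):
  # at tau = 2000 the log-density is log(0.0005) - 1
  expect_equal(dgamma(2000, shape = 1, rate = 5e-4, log = TRUE),
               log(5e-4) - 1)
  st2 <- parameter_state(m1, f$dm, alpha = 0, sigma_v2 = 1 / 2000)
  lp2 <- log_prior(st2, m1)
  manual2 <- dnorm(0, 0, 100, log = TRUE) +
    sum(dnorm(rep(0, 4), 0, sqrt(1 / 2000), TRUE)) + (log(5e-4) - 1)
  expect_equal(lp2, manual2, tolerance = 1e-12)
})

test_that("sensitivity prior swaps in Exponential(1) on the precision", {
  f <- make_design()
  m1 <- model_spec("M1", prior_logprec_rate = 1)
  st <- parameter_state(m1, f$dm, alpha = 0, sigma_v2 = 1)
  lp <- log_prior(st, m1)
  manual <- dnorm(0, 0, 100, log = TRUE) + sum(dnorm(rep(0, 4), 0, 1, TRUE)) +
    dexp(1, rate = 1, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12)
})

test_that("CAR prior term uses rank(Q) and the edgewise quadratic form", {
  g <- lattice_graph(2L, 2L)
  ds <- tiny_dataset(n = 40L, n_areas = 4L, seed = 21L)
  ds$areas <- g$areas
  ds$records$area_id <- g$areas[match(ds$records$area_id, sort(unique(ds$records$area_id)))]
  spec <- model_spec("M4")
  dm <- encode_design(ds, spec)
  u <- c(0.4, -0.1, -0.2, -0.1)
  st <- parameter_state(spec, dm, u = u, sigma_u2 = 0.7, sigma_v2 = 1)
  qf <- car_quadform(g, u)
  expect_equal(qf, drop(t(u) %*% car_precision(g) %*% u), tolerance = 1e-12)
  lp <- log_prior(st, spec, g)
  car_term <- -(car_rank(g) / 2) * log(0.7) - qf / (2 * 0.7)
  base <- log_prior(parameter_state(spec, dm, u = rep(0, 4), sigma_u2 = 1,
                                    sigma_v2 = 1), spec, g)
  base_car <- 0 # log(1) terms vanish at sigma_u2 = 1, u = 0
  gamma_term <- dgamma(1 / 0.7, 1, rate = 5e-4, log = TRUE) -
    dgamma(1, 1, rate = 5e-4, log = TRUE)
  expect_equal(lp - base, car_term - base_car + gamma_term, tolerance = 1e-10)
})

test_that("M4 with u fixed at zero reproduces the M3 likelihood exactly", {
  ds <- tiny_dataset(n = 120L, seed = 33L)
  m3 <- model_spec("M3", c("smoking", "mvpa"), "dist_pa_m")
  m4 <- model_spec("M4", c("smoking", "mvpa"), "dist_pa_m")
  dm3 <- encode_design(ds, m3)
  dm4 <- encode_design(ds, m4)
  set.seed(5)
  beta <- rnorm(3); gamma <- rnorm(2); v <- rnorm(6, 0, 0.3)
  st3 <- parameter_state(m3, dm3, alpha = -1, beta = beta, gamma = gamma,
                         v = v)
  st4 <- parameter_state(m4, dm4, alpha = -1, beta = beta, gamma = gamma,
                         u = rep(0, 6), v = v)
  expect_equal(log_likelihood_bern(dm3$y, linear_predictor(st3, dm3, m3)),
               log_likelihood_bern(dm4$y, linear_predictor(st4, dm4, m4)),
               tolerance = 1e-12)
})

test_that("log posterior is finite on valid random states", {
  f <- make_design(n = 60L)
  g <- lattice_graph(2L, 2L)
  set.seed(6)
  for (k in 1:20) {
    st <- parameter_state(f$spec, f$dm, alpha = rnorm(1, 0, 5),
                          beta = rnorm(3, 0, 3), gamma = rnorm(2, 0, 3),
                          u = rnorm(4, 0, 2), v = rnorm(4, 0, 2),
                          sigma_u2 = runif(1, 0.01, 10),
                          sigma_v2 = runif(1, 0.01, 10))
    expect_true(is.finite(log_posterior(st, f$dm, f$spec, g)))
  }
})
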