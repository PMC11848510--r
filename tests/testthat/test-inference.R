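test_that("detection rates follow lambda = exp(g0) p*", {
  land <- landscape(matrix(0, 5, 5))
  ud <- equilibrium_distribution(
    build_generator(land, c(2.5, 2.5), homerange_params(log(2))))
  det <- detector_array(x = c(0.5, 2.5, 4.5), y = c(0.5, 2.5, 4.5))
  lam <- detection_rates(ud, det, g0 = -3)
  cells <- detector_cell_index(det, land)
  expect_equal(lam, exp(-3) * ud$p[cells])
  ## g0 = 0 is the identity on the utilization mass
  expect_equal(detection_rates(ud, det, 0), ud$p[cells])
  ## uniform home range: every detector sees mass/n_cells
  uni <- ud; uni$p <- rep(1 / 25, 25)
  expect_equal(detection_rates(uni, det, -3), rep(exp(-3) / 25, 3))
})

test_that("full likelihood matches a scalar hand computation", {
  land <- landscape(matrix(c(0.3, -0.3), 2, 1))
  det <- detector_array(x = 0.5, y = 0.5)
  data <- capture_data(matrix(1L, 1, 1), det)
  prm <- adcr_params(rho = -1, g0 = -0.5, gamma0 = 0.2, beta = 0.7)
  ## hand evaluation over the two candidate centres
  pstar <- sapply(1:2, function(m) {
    equilibrium_distribution(build_generator(
      land, c(m - 0.5, 0.5), homerange_params(0.2, 0.7)))$p
  })
  lam <- exp(-0.5) * pstar[1, ]
  by_hand <- -exp(-1) * sum(1 - exp(-lam)) +
    log(exp(-1) * sum(stats::dpois(1, lam))) - lfactorial(1)
  expect_equal(full_loglik(prm, data, land), by_hand, tolerance = 1e-12)

  ## empty data: only the no-detection term
  none <- capture_data(matrix(0L, 0, 1), det)
  expect_equal(full_loglik(prm, none, land),
               -exp(-1) * sum(1 - exp(-lam)), tolerance = 1e-12)
})

test_that("the likelihood normalizes over datasets (enumeration oracle)", {
  land <- landscape(matrix(c(0.3, -0.3), 2, 1))
  det <- detector_array(x = 0.5, y = 0.5, effort = 2)
  prm <- adcr_params(rho = -0.7, g0 = -0.2, gamma0 = 0.1, beta = 0.4)
  pstar <- sapply(1:2, function(m) {
    equilibrium_distribution(build_generator(
      land, c(m - 0.5, 0.5), homerange_params(0.1, 0.4)))$p
  })
  lam <- 2 * exp(-0.2) * pstar[1, ]   # exposure 2
  ## detected individuals form a Poisson process over count values y >= 1
  ## with intensity nu(y); total dataset probability sums to 1
  nu <- vapply(1:80, function(y) exp(-0.7) * sum(stats::dpois(y, lam)),
               numeric(1))
  nu_tot <- exp(-0.7) * sum(1 - exp(-lam))
  total <- exp(-nu_tot) * sum(vapply(0:50, function(n) {
    sum(nu)^n / factorial(n)
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-10)
  ## and the package's log-likelihood reproduces log nu terms: a dataset of
  ## one individual with y detections
  for (y in c(1L, 3L)) {
    d <- capture_data(matrix(y, 1, 1), det)
    expect_equal(full_loglik(prm, d, land),
                 -nu_tot + log(nu[y]) - lfactorial(1), tolerance = 1e-10)
  }
})

test_that("surface caching never changes the likelihood", {
  set.seed(2)
  land <- generate_patch_landscape(8, 8, 1, c(8, 12), seed = 6)
  det <- baseline_detectors(land, spacing = 2, margin = 2, effort = 50)
  truth <- list(rho = -0.8, g0 = -2, gamma0 = 0.8, beta = 0.8)
  data <- sim_iid_dataset(land, det, truth)
  prm <- adcr_params(-0.8, -2, 0.8, 0.8)
  cache <- new.env(parent = emptyenv())
  plain <- full_loglik(prm, data, land)
  warm1 <- full_loglik(prm, data, land, cache = cache)
  warm2 <- full_loglik(prm, data, land, cache = cache)
  expect_lt(abs(plain - warm1), 1e-10)
  expect_identical(warm1, warm2)
})

test_that("the fitted ADCR is a local maximum of its own likelihood", {
  set.seed(5)
  land <- generate_patch_landscape(10, 10, 1, c(12, 20), seed = 9)
  det <- baseline_detectors(land, spacing = 2, margin = 2, effort = 80)
  truth <- list(rho = -0.7, g0 = -2, gamma0 = 1, beta = 1)
  data <- sim_iid_dataset(land, det, truth)
  fit <- fit_adcr(data, land)
  expect_true(fit$convergence)
  ll_hat <- fit$loglik
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(fit$par)) for (d in c(-1, 1)) {
    p <- fit$par
    p[i] <- p[i] + d * 0.05 * max(1, abs(p[i]))
    ll <- full_loglik(adcr_params(p[1], p[2], p[3], p[4]), data, land,
                      cache = cache)
    expect_lt(ll, ll_hat)
  }
  ## prediction at the fitted parameters is deterministic and proper
  ud1 <- predict_homerange(fit, c(5.5, 5.5))
  ud2 <- predict_homerange(fit, c(5.5, 5.5))
  expect_identical(ud1$p, ud2$p)
  expect_lt(abs(sum(ud1$p) - 1), 1e-10)
})

test_that("with no covariates ADCR reduces to Gaussian-home-range SCR", {
  set.seed(7)
  land <- landscape(matrix(0, 10, 10))
  det <- baseline_detectors(land, spacing = 2, margin = 2, effort = 80)
  truth <- list(rho = -0.7, g0 = -2, gamma0 = log(2.5), beta = numeric(0))
  data <- sim_iid_dataset(land, det, truth)
  fit_a <- fit_adcr(data, land, n_beta = 0)
  fit_g <- fit_scr(data, land, mode = "euclidean", normalize = TRUE)
  ## shared parameters agree at the common optimum
  expect_lt(abs(fit_a$par[["rho"]] - fit_g$par[["rho"]]), 1e-4)
  expect_lt(abs(fit_a$par[["g0"]] - fit_g$par[["g0"]]), 1e-4)
  ## g1 = -1 / (2 exp(gamma0)) links the two parameterizations
  expect_lt(abs(fit_a$par[["gamma0"]] - log(-1 / (2 * fit_g$par[["g1"]]))),
            1e-4)
  expect_lt(abs(fit_a$loglik - fit_g$loglik), 1e-6)
})

test_that("predict_homerange reproduces the true surface at true values", {
  land <- generate_patch_landscape(9, 9, 1, c(10, 14), seed = 2)
  mu <- c(4.5, 4.5)
  truth_ud <- equilibrium_distribution(
    build_generator(land, mu, homerange_params(0.9, 1.1)))
  fake_fit <- structure(
    list(model = "adcr", par = c(rho = -1, g0 = -2, gamma0 = 0.9,
                                 beta = 1.1),
         landscape = land, scheme = "exp"),
    class = "adcr_fit")
  expect_lt(max(abs(predict_homerange(fake_fit, mu)$p - truth_ud$p)), 1e-10)
})
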