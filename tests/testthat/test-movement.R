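test_that("step kernel is the explicit-method transition distribution", {
  land <- generate_patch_landscape(5, 5, 1, c(4, 4), seed = 2)
  gen <- build_generator(land, c(2.5, 2.5), homerange_params(0, 1))
  ## dt = 0: identity
  expect_equal(step_kernel(gen, 7, dt = 0), replace(numeric(25), 7, 1))
  ## stochastic rows
  k <- step_kernel(gen, 1, dt = 1)
  expect_gte(min(k), 0)
  expect_lt(abs(sum(k) - 1), 1e-10)
  ## insufficient substeps refused with the required count
  expect_error(step_kernel(gen, 1, dt = 1, substeps = 1), "need >=")
  ## long-time kernel approaches the equilibrium distribution
  p_eq <- equilibrium_distribution(gen)$p
  k_long <- step_kernel(gen, 1, dt = 300)
  expect_lt(0.5 * sum(abs(k_long - p_eq)), 1e-6)
})

test_that("tracks are reproducible and faithful to site fidelity", {
  land <- landscape(matrix(0, 9, 9))
  gen <- build_generator(land, c(4.5, 4.5), homerange_params(0))
  t1 <- simulate_track(gen, 41, 500, burn_in = 10, seed = 5)
  t2 <- simulate_track(gen, 41, 500, burn_in = 10, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 1 & t1 <= 81))
  ## tiny diffusion-to-drift ratio: the animal stays in the centre's
  ## neighbourhood
  tight <- build_generator(land, c(4.5, 4.5), homerange_params(-8))
  tr <- simulate_track(tight, 41, 2000, seed = 1)
  cc <- cell_centers(land)
  expect_true(all(abs(cc$x[tr] - 4.5) + abs(cc$y[tr] - 4.5) <= 1))
})

test_that("long-run occupancy converges to the equilibrium distribution", {
  land <- generate_patch_landscape(10, 10, 2, c(10, 20), seed = 5)
  mu <- c(5.5, 5.5)
  gen <- build_generator(land, mu, movement_params(-0.5, 0.5, 1))
  tr <- simulate_track(gen, 45, 1e6, burn_in = 1000, seed = 9)
  occ <- tabulate(tr, nbins = 100) / length(tr)
  p_eq <- equilibrium_distribution(
    build_generator(land, mu, homerange_params(1, 1)))$p
  expect_lt(0.5 * sum(abs(occ - p_eq)), 0.05)
})

test_that("detections follow the Poisson count model at detectors", {
  land <- landscape(matrix(0, 4, 4))
  det <- detector_array(x = c(0.5, 2.5), y = c(0.5, 2.5))
  ## no detectability: silence
  expect_equal(simulate_detections(rep(1L, 100), det, -Inf, land), c(0L, 0L))
  ## track pinned to detector 1's cell: total ~ Poisson(T exp(g0))
  set.seed(8)
  T_ <- 1e4; g0 <- -1
  counts <- simulate_detections(rep(1L, T_), det, g0, land)
  lambda <- T_ * exp(g0)
  expect_lt(abs(counts[1] - lambda), 3 * sqrt(lambda))
  ## unvisited detector stays silent
  expect_equal(counts[2], 0L)
})

test_that("datasets censor undetected individuals and stay reproducible", {
  scn <- sim_scenario(rho = -1.2, alpha0 = -0.5, beta0 = 0.5, beta = 1,
                      g0 = -2.5, n_steps = 300, burn_in = 20,
                      patch_spec = list(nx = 12, ny = 12, n_patches = 2,
                                        area_range = c(10, 16)),
                      detector_spec = list(spacing = 2, margin = 3, K = 1))
  sim1 <- simulate_dataset(scn, seed = 13)
  sim2 <- simulate_dataset(scn, seed = 13)
  expect_identical(sim1$data$Y, sim2$data$Y)
  expect_identical(sim1$truth$tracks, sim2$truth$tracks)
  expect_lte(sim1$data$n, sim1$truth$N)
  if (sim1$data$n > 0) {
    expect_true(all(apply(sim1$data$Y, 1, sum) >= 1))
  }
  expect_equal(sum(sim1$truth$counts[sim1$truth$detected, ]),
               sum(sim1$data$Y))
  ## detector exposure records the movement-simulation length
  expect_equal(sim1$data$detectors$effort, 300)
  ## an essentially empty population yields a valid empty dataset
  empty <- simulate_dataset(
    sim_scenario(rho = -10, n_steps = 50, burn_in = 5,
                 patch_spec = list(nx = 12, ny = 12, n_patches = 1,
                                   area_range = c(10, 10)),
                 detector_spec = list(spacing = 2, margin = 3, K = 1)),
    seed = 1)
  expect_equal(empty$data$n, 0L)
  expect_equal(dim(empty$data$Y)[1], 0L)
})

test_that("sparse scenario fixes parameters and filters detectors", {
  land <- generate_patch_landscape(20, 20, 2, c(30, 50), seed = 3)
  base <- sim_scenario(land = land, n_steps = 200, burn_in = 10,
                       detectors = baseline_detectors(land, spacing = 2,
                                                      margin = 4))
  sp <- sparse_scenario(base)
  expect_equal(sp$g0, -5)
  expect_equal(sp$rho, -2)
  expect_equal(sp$alpha0, -0.5)
  expect_equal(sp$beta, 2)
  expect_equal(sp$beta0, 1)
  ## exactly the detectors on patch (+0.5) cells survive
  z <- as.vector(land$layers$z)
  full <- baseline_detectors(land, spacing = 2, margin = 4)
  on_patch <- z[detector_cell_index(full, land)] > 0
  expect_equal(nrow(sp$detectors$points), sum(on_patch))
  zkept <- z[detector_cell_index(sp$detectors, land)]
  expect_true(all(zkept == 0.5))
  ## a patchless landscape leaves nothing and errors
  flat <- generate_patch_landscape(20, 20, 0)
  expect_error(sparse_scenario(sim_scenario(land = flat, n_steps = 200,
                                            burn_in = 10)),
               "no detectors remain")
})
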