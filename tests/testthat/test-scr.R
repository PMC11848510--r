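test_that("least-cost distances collapse to octile distance at g2 = 0", {
  land <- generate_patch_landscape(6, 5, 1, c(6, 6), seed = 8)
  cc <- cell_centers(land)
  d <- lcp_distances(land, 0, seq_len(30), seq_len(30))
  oct <- outer(seq_len(30), seq_len(30), function(a, b) {
    octile_distance(cc$ix[a] - cc$ix[b], cc$iy[a] - cc$iy[b])
  })
  expect_equal(unname(d), oct, tolerance = 1e-12)
  ## rook-adjacent pair at unit spacing
  expect_equal(unname(d[1, 2]), 1)
  expect_equal(diag(d), rep(0, 30), ignore_attr = TRUE)
})

test_that("least-cost distances agree with independent shortest-path oracles", {
  ## 5x5 grid with an expensive middle column: Floyd-Warshall oracle
  z <- matrix(0, 5, 5); z[3, ] <- 1
  land <- landscape(z)
  g2 <- 5
  ed <- edges8_with_costs(land, g2)
  oracle <- floyd_warshall(25, ed$from, ed$to, ed$w)
  d <- lcp_distances(land, g2, seq_len(25), seq_len(25))
  expect_equal(unname(d), oracle, tolerance = 1e-10)
  expect_equal(unname(d), unname(t(d)))   # symmetry
  ## flanking the wall is far costlier than a same-side move
  left <- adcr:::cell_index(land, 2L, 3L); right <- adcr:::cell_index(land, 4L, 3L)
  expect_gt(d[left, right], d[left, adcr:::cell_index(land, 1L, 3L)])

  ## exhaustive simple-path enumeration on a 3x4 grid
  z2 <- matrix(rnorm(12), 3, 4)
  land2 <- landscape(z2)
  ed2 <- edges8_with_costs(land2, 1.3)
  adj <- vector("list", 12); w <- vector("list", 12)
  for (e in seq_along(ed2$from)) {
    adj[[ed2$from[e]]] <- c(adj[[ed2$from[e]]], ed2$to[e])
    w[[ed2$from[e]]] <- c(w[[ed2$from[e]]], ed2$w[e])
    adj[[ed2$to[e]]] <- c(adj[[ed2$to[e]]], ed2$from[e])
    w[[ed2$to[e]]] <- c(w[[ed2$to[e]]], ed2$w[e])
  }
  d2 <- lcp_distances(land2, 1.3, 1, 12)
  expect_equal(d2[1, 1], dfs_min_path_cost(12, adj, w, 1, 12),
               tolerance = 1e-10)
})

test_that("least-cost distances satisfy the triangle inequality", {
  set.seed(10)
  land <- generate_patch_landscape(6, 6, 1, c(8, 10), seed = 3)
  d <- lcp_distances(land, 2, seq_len(36), seq_len(36))
  trio <- expand.grid(a = 1:36, b = 1:36)
  for (k in sample(nrow(trio), 200)) {
    a <- trio$a[k]; b <- trio$b[k]
    expect_true(all(d[a, b] <= d[a, ] + d[, b] + 1e-9))
  }
})

test_that("SCR likelihood shares the full-likelihood skeleton", {
  set.seed(6)
  land <- landscape(matrix(0, 8, 8))
  det <- baseline_detectors(land, spacing = 2, margin = 2, effort = 40)
  ## n = 0: first term only, computable by hand
  none <- capture_data(matrix(0L, 0, nrow(det$points)), det)
  prm <- scr_params(-1, -3, -0.5)
  cc <- cell_centers(land)
  dc <- detector_cell_index(det, land)
  d2 <- outer(seq_len(64), dc, function(m, j) {
    (cc$x[m] - cc$x[j])^2 + (cc$y[m] - cc$y[j])^2
  })
  Lam <- 40 * rowSums(exp(-3 - 0.5 * d2))
  expect_equal(scr_loglik(prm, none, land, mode = "euclidean"),
               -exp(-1) * sum(1 - exp(-Lam)), tolerance = 1e-10)
  ## lcp with g2 = 0 equals the same functional form on octile distance
  prm_lcp <- scr_params(-1, -3, -0.5, g2 = 0)
  d_oct <- outer(seq_len(64), dc, function(m, j) {
    octile_distance(cc$ix[m] - cc$ix[j], cc$iy[m] - cc$iy[j])
  })
  Lam_oct <- 40 * rowSums(exp(-3 - 0.5 * d_oct))
  expect_equal(scr_loglik(prm_lcp, none, land, mode = "lcp"),
               -exp(-1) * sum(1 - exp(-Lam_oct)), tolerance = 1e-10)
})

test_that("euclidean SCR recovers its own parameters", {
  set.seed(21)
  land <- landscape(matrix(0, 12, 12))
  det <- baseline_detectors(land, spacing = 2, margin = 2, effort = 1)
  truth <- scr_params(rho = -0.6, g0 = 1.2, g1 = -1 / (2 * 3))
  cc <- cell_centers(land)
  dc <- detector_cell_index(det, land)
  n_rep <- 20
  hits <- 0L; tries <- 0L
  for (r in seq_len(n_rep)) {
    N <- rpois(1, exp(truth$rho) * 144)
    centers <- sample.int(144, N, replace = TRUE)
    d2 <- outer(dc, centers, function(j, m) {
      (cc$x[j] - cc$x[m])^2 + (cc$y[j] - cc$y[m])^2
    })
    lam <- exp(truth$g0 + truth$g1 * d2)
    Y <- matrix(rpois(length(lam), lam), nrow = length(dc))
    Y <- t(Y)
    keep <- rowSums(Y) > 0
    data <- capture_data(Y[keep, , drop = FALSE], det)
    fit <- fit_scr(data, land, mode = "euclidean")
    z <- (fit$par - c(truth$rho, truth$g0, truth$g1)) / fit$se
    hits <- hits + sum(abs(z) < 2)
    tries <- tries + length(z)
  }
  expect_gte(hits / tries, 0.9)
})

test_that("fits are deterministic given the data", {
  set.seed(31)
  land <- generate_patch_landscape(8, 8, 1, c(8, 12), seed = 2)
  det <- baseline_detectors(land, spacing = 2, margin = 2, effort = 60)
  data <- sim_iid_dataset(land, det,
                          list(rho = -0.8, g0 = -2, gamma0 = 0.8,
                               beta = 0.5))
  f1 <- fit_scr(data, land, mode = "lcp")
  f2 <- fit_scr(data, land, mode = "lcp")
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("SCR home-range surfaces behave geometrically", {
  z <- matrix(0, 9, 9); z[5, ] <- 1    # costly wall column
  land <- landscape(z)
  mu <- c(2.5, 4.5)
  fit_e <- structure(list(model = "scr", mode = "euclidean",
                          lcp_exponent = 1,
                          par = c(rho = -1, g0 = 0, g1 = -0.3),
                          landscape = land),
                     class = "adcr_fit")
  ud_e <- scr_homerange(fit_e, mu)
  expect_lt(abs(sum(ud_e$p) - 1), 1e-12)
  m <- as.matrix(ud_e)
  ## symmetric and unimodal about the activity centre (cell 3, 5)
  for (k in 1:2) {
    expect_equal(m[3 + k, 5], m[3 - k, 5])
    expect_equal(m[3, 5 + k], m[3, 5 - k])
  }
  expect_true(all(diff(m[, 5])[1:2] > 0) && all(diff(m[, 5])[3:8] < 0))
  expect_equal(which.max(ud_e$p),
               adcr:::coord_to_cell(land, mu[1], mu[2]))
  ## wall depresses mass beyond it for the LCP surface at equal parameters
  fit_l <- structure(list(model = "scr_lcp", mode = "lcp", lcp_exponent = 1,
                          par = c(rho = -1, g0 = 0, g1 = -0.3, g2 = 4),
                          landscape = land),
                     class = "adcr_fit")
  ud_l <- scr_homerange(fit_l, mu)
  beyond <- cell_centers(land)$ix > 5
  expect_lt(sum(ud_l$p[beyond]), sum(ud_e$p[beyond]))
  expect_lt(abs(sum(ud_l$p) - 1), 1e-12)
})
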