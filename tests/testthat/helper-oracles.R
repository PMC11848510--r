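## Independent oracles and shared fixtures for the test suite. Everything
## here is deliberately brute-force and separate from the code paths it
## checks.

## label 4-connected components of a logical matrix by flood fill;
## returns an integer vector of component sizes
flood_fill_sizes <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  sizes <- integer(0)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- cur[1] + d[1]; b <- cur[2] + d[2]
        if (a >= 1 && a <= nx && b >= 1 && b <= ny &&
            mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

## stationary distribution by dense null space (SVD), independent of the
## package's sparse solve
dense_equilibrium <- function(gen) {
  Q <- as.matrix(gen$Q)
  sv <- svd(t(Q))
  p <- sv$v[, ncol(Q)]
  if (sum(p) < 0) p <- -p
  p / sum(p)
}

## closed-form octile (8-neighbour lattice shortest path) distance
octile_distance <- function(dx, dy, h = 1) {
  a <- abs(dx); b <- abs(dy)
  h * (pmax(a, b) + (sqrt(2) - 1) * pmin(a, b))
}

## all-pairs shortest paths by Floyd-Warshall over an explicit edge list;
## independent of igraph
floyd_warshall <- function(n, from, to, w) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (e in seq_along(from)) {
    d[from[e], to[e]] <- min(d[from[e], to[e]], w[e])
    d[to[e], from[e]] <- min(d[to[e], from[e]], w[e])
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    for (i in seq_len(n)) {
      cand <- dk[i] + dk
      better <- cand < d[i, ]
      if (any(better)) d[i, better] <- cand[better]
    }
  }
  d
}

## minimum-cost simple path between two cells by exhaustive DFS (tiny grids)
dfs_min_path_cost <- function(n, adj, w, from, to) {
  best <- Inf
  visit <- function(v, cost, seen) {
    if (cost >= best) return()
    if (v == to) { best <<- cost; return() }
    for (k in seq_along(adj[[v]])) {
      u <- adj[[v]][k]
      if (!seen[u]) {
        seen[u] <- TRUE
        visit(u, cost + w[[v]][k], seen)
        seen[u] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n); seen[from] <- TRUE
  visit(from, 0, seen)
  best
}

## 8-neighbour edge list with the package's LCP cost convention, built
## independently of lcp_distances()
edges8_with_costs <- function(land, g2) {
  nx <- land$nx; ny <- land$ny; h <- land$h
  z <- as.vector(land$layers[[1]])
  from <- integer(0); to <- integer(0); w <- numeric(0)
  idx <- function(i, j) i + (j - 1L) * nx
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    s <- idx(i, j)
    for (d in list(c(1, 0, h), c(0, 1, h), c(1, 1, sqrt(2) * h),
                   c(-1, 1, sqrt(2) * h))) {
      a <- i + d[1]; b <- j + d[2]
      if (a >= 1 && a <= nx && b <= ny) {
        t <- idx(a, b)
        from <- c(from, s); to <- c(to, t)
        w <- c(w, exp(g2 * (z[s] + z[t]) / 2) * d[3])
      }
    }
  }
  list(from = from, to = to, w = w)
}

## i.i.d.-from-model capture data: centres uniform over cells, counts
## Poisson(E exp(g0) p*(s_j | mu)), undetected individuals censored
sim_iid_dataset <- function(land, det, truth, P = NULL) {
  stopifnot(det$K == 1)  # pooled single occasion; exposure via det$effort
  if (is.null(P)) {
    cc <- cell_centers(land)
    P <- ud_surfaces(land, truth$gamma0, truth$beta, cc$x, cc$y)
  }
  dc <- detector_cell_index(det, land)
  E <- det$K * det$effort
  N <- rpois(1, exp(truth$rho) * land$nx * land$ny * land$h^2)
  centers <- sample.int(land$nx * land$ny, N, replace = TRUE)
  J <- nrow(det$points)
  lam <- E * exp(truth$g0) * P[dc, centers, drop = FALSE]
  Y <- matrix(rpois(N * J, t(lam)), N, J, byrow = FALSE)
  keep <- rowSums(Y) > 0
  capture_data(array(Y[keep, , drop = FALSE], c(sum(keep), J, det$K)),
               det)
}

## thin internal accessors used by fixtures
ud_surfaces <- function(land, gamma0, beta, x, y) {
  adcr:::ud_batch_(land, gamma0, beta, x, y)
}
detector_cell_index <- function(det, land) {
  adcr:::detector_cells_(det, land)
}
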