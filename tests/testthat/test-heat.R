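toy_features <- function(grid, fill = 0) {
  matrix(fill, grid$n_rows * grid$n_cols, 8,
         dimnames = list(NULL, c("E", "NE", "N", "NW", "W", "SW", "S", "SE")))
}

test_that("adjacency sums the directional contributions of both ends", {
  g <- electrode_grid(1, 2, pitch = 42)
  f <- toy_features(g)
  f[1, "E"] <- 0.4   # electrode (1,1) towards its east neighbour
  f[2, "W"] <- 0.3   # electrode (1,2) towards its west neighbour
  A <- build_adjacency(f, g)
  expect_equal(A[1, 2], 0.7)
  expect_equal(A[2, 1], 0.7)
  expect_equal(diag(A), rep(0, 2))
})

test_that("all-zero features give a zero adjacency; non-adjacent pairs stay zero", {
  g <- electrode_grid(3, 3)
  expect_true(all(build_adjacency(toy_features(g), g) == 0))
  f <- toy_features(g, fill = 0.125)
  A <- build_adjacency(f, g)
  # corner (1,1) and corner (3,3) are not lattice-adjacent
  expect_equal(A[1, 9], 0)
  # diagonal neighbours are adjacent under 8-connectivity
  expect_gt(A[1, 5], 0)
  expect_equal(A, t(A))
})

test_that("heat kernel at t = 0 is the identity", {
  set.seed(1)
  A <- matrix(runif(36), 6, 6); A <- A + t(A); diag(A) <- 0
  hk <- heat_kernel(A, t = 0)
  expect_equal(hk$h, diag(6), tolerance = 1e-10)
})

test_that("two-node heat kernel matches the closed form", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  hk <- heat_kernel(A, t = 1)
  # eigenvalues {0, 2w}: off-diagonal heat (1 - exp(-2wt)) / 2
  expect_equal(hk$h[1, 2], (1 - exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(sort(hk$values), c(0, 2), tolerance = 1e-12)
})

test_that("heat is conserved, symmetric and non-negative on random graphs", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    A <- matrix(rbinom(n^2, 1, 0.4) * runif(n^2), n, n)
    A <- (A + t(A)) / 2; diag(A) <- 0
    for (t in c(0.5, 5, 25)) {
      hk <- heat_kernel(A, t)
      expect_equal(rowSums(hk$h), rep(1, n), tolerance = 1e-9)
      expect_equal(hk$h, t(hk$h), tolerance = 1e-10)
      expect_gte(min(hk$h), -1e-10)
      expect_gte(min(eigen(hk$h, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
    }
  }
})

test_that("heat kernels compose under the semigroup property", {
  set.seed(3)
  for (rep in 1:4) {
    n <- sample(4:10, 1)
    A <- matrix(runif(n^2), n, n); A <- A + t(A); diag(A) <- 0
    t1 <- runif(1, 0.1, 3); t2 <- runif(1, 0.1, 3)
    h12 <- heat_kernel(A, t1 + t2)$h
    expect_equal(heat_kernel(A, t1)$h %*% heat_kernel(A, t2)$h, h12,
                 tolerance = 1e-8)
  }
})

test_that("on a connected graph all heat converges to 1/|V|", {
  set.seed(4)
  n <- 8
  A <- matrix(runif(n^2, 0.2, 1), n, n); A <- A + t(A); diag(A) <- 0
  lam2 <- sort(heat_kernel(A, 1)$values)[2]
  hk <- heat_kernel(A, t = 30 / lam2)
  expect_equal(max(abs(hk$h - 1 / n)), 0, tolerance = 1e-9)
})

test_that("a non-symmetric adjacency violates the contract", {
  A <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(heat_kernel(A, 1), "symmetric")
})

test_that("growing t never shrinks the explored set of seed pairs", {
  g <- electrode_grid(8, 8)
  f <- toy_features(g, fill = 0.125)
  A <- build_adjacency(f, g)
  seeds <- seq(1, 64, by = 3)
  eps <- c(1e-6, 1e-4, 1e-3)
  reached <- sapply(c(1, 5, 10, 25), function(t) {
    h <- heat_kernel(A, t)$h[seeds, seeds]
    sapply(eps, function(e) sum(h[upper.tri(h)] > e))
  })
  for (i in seq_along(eps)) {
    expect_true(all(diff(reached[i, ]) >= 0))
  }
})

test_that("normalised map is in [0, 1] with unit maximum and zero diagonal", {
  g <- electrode_grid(6, 6)
  f <- toy_features(g, fill = 0.125)
  hk <- heat_kernel(build_adjacency(f, g), 10)
  sc <- propagate_and_normalize(hk, seeds = c(1, 8, 15, 22, 29, 36))
  expect_equal(max(sc$map), 1)
  expect_gte(min(sc$map), 0)
  expect_equal(diag(sc$map), setNames(rep(0, 6), sc$seeds))
})

test_that("a single seed yields an empty off-diagonal map; empty seeds error", {
  hk <- heat_kernel(matrix(c(0, 1, 1, 0), 2, 2), 1)
  sc <- propagate_and_normalize(hk, seeds = 1)
  expect_equal(dim(sc$map), c(1, 1))
  expect_equal(sum(sc$map), 0)
  expect_error(propagate_and_normalize(hk, integer(0)), "empty")
})

test_that("heat decays with lattice distance on a homogeneous array", {
  g <- electrode_grid(9, 9)
  f <- toy_features(g, fill = 0.125)
  hk <- heat_kernel(build_adjacency(f, g), 10)
  centre <- electrode_index(g, 5, 5)
  along_row <- sapply(6:9, function(cc) hk$h[centre, electrode_index(g, 5, cc)])
  expect_true(all(diff(along_row) < 0))
})

test_that("structural distances reproduce lattice geometry", {
  g <- electrode_grid(2, 2, pitch = 42)
  map <- matrix(1, 4, 4); diag(map) <- 0
  sg <- structural_distances(manual_sc(map, 1:4), g, sc_threshold = 0.5)
  # electrodes 1,2 are axially adjacent; 1,4 diagonal
  expect_equal(sg$d_um["1", "2"], 42)
  expect_equal(sg$d_um["1", "4"], 42 * sqrt(2))
  expect_equal(diag(sg$d_um), setNames(rep(0, 4), 1:4))
})

test_that("shortest-path distances equal the exhaustive path oracle", {
  g <- electrode_grid(3, 3, pitch = 42)
  pos <- electrode_positions(g)
  eu <- as.matrix(dist(pos[, c("x_um", "y_um")]))
  set.seed(5)
  for (rep in 1:8) {
    # random connectivity over the 9 electrodes, always keeping a spanning
    # path so most pairs are reachable
    map <- matrix(0, 9, 9)
    on <- which(upper.tri(map))
    on <- sample(on, 14)
    map[on] <- 1
    map <- pmax(map, t(map))
    sg <- structural_distances(manual_sc(map, 1:9), g, sc_threshold = 0.5)
    w <- ifelse(map >= 0.5, eu, Inf); diag(w) <- Inf
    for (pair in list(c(1, 9), c(2, 7), c(3, 5))) {
      expect_equal(sg$d_um[pair[1], pair[2]],
                   brute_shortest_path(w, pair[1], pair[2]))
    }
    # triangle inequality over all finite triples
    d <- sg$d_um
    for (k in 1:9) {
      lhs <- d
      rhs <- outer(d[, k], d[k, ], "+")
      expect_true(all(lhs <= rhs + 1e-9 | !is.finite(rhs)))
    }
  }
})

test_that("distances lower-bound the straight line and normalise to [0, 1]", {
  g <- electrode_grid(3, 3, pitch = 42)
  pos <- electrode_positions(g)
  eu <- as.matrix(dist(pos[, c("x_um", "y_um")]))
  map <- matrix(0, 9, 9)
  # ring topology: no chords, so paths are longer than straight lines
  ring <- cbind(c(1, 2, 3, 6, 9, 8, 7, 4), c(2, 3, 6, 9, 8, 7, 4, 1))
  map[ring] <- 1; map <- pmax(map, t(map))
  sg <- structural_distances(manual_sc(map, 1:9), g, sc_threshold = 0.5)
  reach <- is.finite(sg$d_um)
  expect_true(all(sg$d_um[reach] >= eu[reach] - 1e-9))
  expect_true(all(sg$d_norm >= 0 & sg$d_norm <= 1))
  # electrode 5 is isolated: unreachable and flagged at maximal distance
  expect_true(all(sg$unreachable["5", -5]))
  expect_true(all(sg$d_norm["5", -5] == 1))
})
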