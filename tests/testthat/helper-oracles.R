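# Independent oracles and small fixture builders used across the suite.

# All-pairs O(Nx * Ny) correlogram counting by direct interval logic:
# bin k (centre k*dt) counts differences u - t in [k*dt - dt/2, k*dt + dt/2).
brute_cc_counts <- function(x, y, tau_max, dt) {
  K <- round(tau_max / dt)
  d <- as.vector(outer(y, x, "-"))
  vapply(-K:K, function(k) {
    sum(d >= k * dt - dt / 2 & d < k * dt + dt / 2)
  }, 0L)
}

# Minimal total-weight simple path between two nodes by exhaustive
# enumeration (graphs of <= 8 nodes). `w` is a symmetric weight matrix
# with NA/Inf for absent edges.
brute_shortest_path <- function(w, from, to) {
  n <- nrow(w)
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) return()
    if (node == to) { best <<- len; return() }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(w[node, nxt])) {
        visited[nxt] <- TRUE
        recurse(nxt, visited, len + w[node, nxt])
        visited[nxt] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  recurse(from, visited, 0)
  best
}

# Adaptive-quadrature probability of a Von Mises mixture over [a, b].
quad_mixture_prob <- function(components, a, b) {
  dens <- function(th) {
    out <- 0
    for (i in seq_len(nrow(components))) {
      out <- out + components$weight[i] *
        dvonmises(th, components$mu[i], components$kappa[i])
    }
    out
  }
  stats::integrate(dens, a, b, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# Homogeneous Poisson spike train on [0, T].
rpois_train <- function(rate, T_s) {
  sort(stats::runif(stats::rpois(1, rate * T_s), 0, T_s))
}

# A spike_train_set of independent Poisson trains on the first
# `n` electrodes of a grid.
poisson_train_set <- function(n, rate, T_s, grid = NULL) {
  if (is.null(grid)) {
    side <- ceiling(sqrt(n))
    grid <- electrode_grid(side, side, 42)
  }
  trains <- lapply(seq_len(n), function(i) rpois_train(rate, T_s))
  names(trains) <- as.character(seq_len(n))
  spike_train_set(trains, grid, t_r = T_s)
}

# Draw an anti-aliased-free straight bright line on a matrix (value 1).
draw_line <- function(mat, r0, c0, r1, c1) {
  n <- max(2, ceiling(2 * sqrt((r1 - r0)^2 + (c1 - c0)^2)))
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  ok <- rr >= 1 & rr <= nrow(mat) & cc >= 1 & cc <= ncol(mat)
  mat[cbind(rr[ok], cc[ok])] <- 1
  mat
}

# Smallest angular separation between two orientations (mod pi).
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  min(d, pi - d)
}

# Manually assembled normalised structural map (propagate_and_normalize
# output shape) from an explicit seed x seed strength matrix.
manual_sc <- function(map, seeds) {
  dimnames(map) <- list(seeds, seeds)
  list(map = map, seeds = seeds, normaliser = 1)
}
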