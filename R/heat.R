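#' Symmetrised adjacency matrix from directional features
#'
#' For lattice-adjacent electrodes x and y (8-connectivity) the weight is
#' the sum of the probability contributions in the two edge directions:
#' `A(x, y) = feature_x[dir x->y] + feature_y[dir y->x]`. Non-adjacent
#' pairs get weight zero; the diagonal is zero.
#'
#' @param features `n_electrodes x 8` feature matrix from
#'   [directional_features()].
#' @param grid An `electrode_grid`.
#' @return Symmetric non-negative adjacency matrix.
#' @export
build_adjacency <- function(features, grid) {
  n <- n_electrodes(grid)
  stopifnot(nrow(features) == n, ncol(features) == 8)
  dirs <- mea_directions()
  M <- matrix(0, n, n)
  g <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  idx <- (g$row - 1L) * grid$n_cols + g$col
  for (k in 1:8) {
    r2 <- g$row + dirs$dr[k]
    c2 <- g$col + dirs$dc[k]
    ok <- r2 >= 1 & r2 <= grid$n_rows & c2 >= 1 & c2 <= grid$n_cols
    from <- idx[ok]
    to <- (r2[ok] - 1L) * grid$n_cols + c2[ok]
    M[cbind(from, to)] <- M[cbind(from, to)] + features[from, k]
  }
  A <- M + t(M)
  diag(A) <- 0
  A
}

#' Graph heat kernel by Laplacian eigendecomposition
#'
#' Solves the heat equation on the weighted graph with combinatorial
#' Laplacian `L = D - A`: `h_t(x, y) = sum_i exp(-lambda_i t) phi_i(x)
#' phi_i(y)` with `(lambda_i, phi_i)` the eigensystem of `L`. Entry
#' `(x, y)` is the amount of heat at node y after time t from a unit
#' source at x. Rows of `h_t` sum to 1 (heat conservation) and `h_0` is
#' the identity.
#'
#' @param A Symmetric non-negative adjacency matrix.
#' @param t Diffusion time (dimensionless, >= 0). Default 25, a value
#'   suited to exploring a 64 x 64 lattice without flooding it.
#' @return Object of class `heat_kernel`: list with `A`, `L`, `values`,
#'   `vectors`, `t`, `h` (the `|V| x |V|` heat matrix).
#' @export
heat_kernel <- function(A, t = 25) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), t >= 0)
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency matrix must be symmetric")
  if (min(A) < 0) stop("adjacency matrix must be non-negative")
  L <- diag(rowSums(A)) - A
  eig <- eigen(L, symmetric = TRUE)
  h <- eig$vectors %*% (exp(-eig$values * t) * t(eig$vectors))
  h <- (h + t(h)) / 2
  structure(list(A = A, L = L, values = eig$values, vectors = eig$vectors,
                 t = t, h = h),
            class = "heat_kernel")
}

#' @export
print.heat_kernel <- function(x, ...) {
  cat(sprintf("<heat_kernel> %d nodes, t = %g, %d zero eigenvalue(s)\n",
              nrow(x$h), x$t, sum(abs(x$values) < 1e-9)))
  invisible(x)
}

#' Seed-restricted, max-normalised structural connectivity map
#'
#' Restricts the heat matrix to the seed electrodes (those with at least
#' one neuron in their recording area -- the only ones that can contribute
#' recorded activity) and normalises by the maximum entry so that
#' connectivity strengths lie in \[0, 1\]. The self-heat diagonal always
#' dominates the matrix, so by default the maximum is taken over
#' off-diagonal seed pairs (the actual candidate links) and the diagonal of
#' the returned map is set to zero; `include_diagonal = TRUE` reproduces
#' the full-matrix maximum instead.
#'
#' @param hk A [heat_kernel()] result.
#' @param seeds Integer electrode indices with >= 1 neuron.
#' @param include_diagonal Use the full-matrix maximum (including
#'   self-heat) as the normaliser.
#' @return List with `map` (seed x seed matrix, entries in \[0, 1\], zero
#'   diagonal), `seeds`, `normaliser`.
#' @export
propagate_and_normalize <- function(hk, seeds, include_diagonal = FALSE) {
  stopifnot(inherits(hk, "heat_kernel"))
  seeds <- sort(unique(as.integer(seeds)))
  if (length(seeds) == 0) stop("seed set is empty")
  sub <- hk$h[seeds, seeds, drop = FALSE]
  sub <- pmax(sub, 0)  # clip eigendecomposition round-off
  off <- sub
  if (!include_diagonal) diag(off) <- 0
  m <- max(off)
  map <- if (m > 0) sub / m else sub
  diag(map) <- 0
  map <- pmin(map, 1)
  dimnames(map) <- list(seeds, seeds)
  list(map = map, seeds = seeds, normaliser = m)
}

#' Shortest-path structural distances between seed electrodes
#'
#' Thresholds the normalised structural map into a discrete structural
#' graph (edges where connectivity strength >= `sc_threshold`, edge length
#' = euclidean distance between the electrode centres in um) and computes
#' the structural distance of every seed pair as the minimal total edge
#' length along the graph -- the length of the most probable anatomical
#' path. Distances are also returned normalised to \[0, 1\] by the maximum
#' finite distance; unreachable pairs are `Inf` in `d_um` and 1 (flagged)
#' in `d_norm`.
#'
#' @param sc Result of [propagate_and_normalize()].
#' @param grid An `electrode_grid`.
#' @param sc_threshold Minimum normalised strength for a structural link
#'   (default 0.05, calibrated on the synthetic generator for full
#'   recovery of ground-truth neurite edges).
#' @return Object of class `structural_graph`: list with `edges` (data
#'   frame `a, b, strength, euclid_um` over electrode indices), `d_um`,
#'   `d_norm` (seed x seed matrices), `unreachable` (logical matrix),
#'   `seeds`, `sc_threshold`.
#' @export
structural_distances <- function(sc, grid, sc_threshold = 0.05) {
  seeds <- sc$seeds
  pos <- electrode_positions(grid)
  ns <- length(seeds)
  ut <- which(upper.tri(sc$map) & sc$map >= sc_threshold, arr.ind = TRUE)
  a <- seeds[ut[, 1]]; b <- seeds[ut[, 2]]
  eu <- sqrt((pos$x_um[a] - pos$x_um[b])^2 + (pos$y_um[a] - pos$y_um[b])^2)
  edges <- data.frame(a = a, b = b,
                      strength = sc$map[ut],
                      euclid_um = eu)
  g <- igraph::make_empty_graph(n = ns, directed = FALSE)
  igraph::V(g)$name <- as.character(seeds)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(a, seeds), match(b, seeds)))
    igraph::E(g)$weight <- eu
  }
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- list(seeds, seeds)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  dmax <- if (length(finite) > 0) max(finite) else NA_real_
  d_norm <- d
  if (!is.na(dmax) && dmax > 0) d_norm <- d / dmax
  unreachable <- !is.finite(d)
  d_norm[unreachable] <- 1
  structure(list(edges = edges, d_um = d, d_norm = d_norm,
                 unreachable = unreachable, seeds = seeds,
                 sc_threshold = sc_threshold, graph = g),
            class = "structural_graph")
}

#' @export
print.structural_graph <- function(x, ...) {
  cat(sprintf("<structural_graph> %d nodes, %d SC links (threshold %g)\n",
              length(x$seeds), nrow(x$edges), x$sc_threshold))
  invisible(x)
}
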