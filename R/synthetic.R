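#' Generate a ground-truth synthetic culture network
#'
#' Emulates a sparse dissociated culture on an HD-MEA: neurons are placed
#' on distinct electrodes (one per electrode, with a sub-patch positional
#' offset), neurites are drawn as curved polylines between spatially
#' proximal neurons, and a subset of those structural edges is promoted to
#' directed functional links with a coupling probability and a
#' conduction delay consistent with the neurite path length.
#'
#' @param n_neurons Number of neurons (default 1000, the order of a
#'   typical low-density culture on a 64 x 64 array).
#' @param grid An `electrode_grid` (default 64 x 64, 42 um pitch).
#' @param edge_density Target mean structural degree per neuron
#'   (default 4).
#' @param max_reach_um Maximum neurite span in um (default 6 electrode
#'   pitches).
#' @param p_functional Probability that a structural edge carries a
#'   functional link (default 0.5).
#' @param coupling_p Spike transmission probability of a functional link
#'   (default 0.8).
#' @param velocity_mm_s Axonal conduction velocity in mm/s used for link
#'   delays (default 100, within the unmyelinated in vitro range and
#'   below the 400 mm/s physiological bound).
#' @param curvature_sd Perpendicular midpoint jitter of the neurite
#'   polyline, as a fraction of its span (default 0.15).
#' @param seed Integer seed; the network is reproducible from it.
#' @return Object of class `synthetic_network`: `grid`, `neurons` (data
#'   frame `id, row, col, index, x_um, y_um`), `edges` (structural:
#'   `a, b, index_a, index_b, path_um, polyline` list-column of um
#'   coordinates), `links` (functional: `source, target, index_a,
#'   index_b, coupling_p, delay_s, path_um`), `neuron_map`, `seed`.
#' @export
generate_network <- function(n_neurons = 1000, grid = electrode_grid(),
                             edge_density = 4, max_reach_um = 6 * grid$pitch,
                             p_functional = 0.5, coupling_p = 0.8,
                             velocity_mm_s = 100, curvature_sd = 0.15,
                             seed = 1L) {
  stopifnot(n_neurons >= 2, edge_density > 0, p_functional >= 0,
            p_functional <= 1, coupling_p >= 0, coupling_p <= 1,
            velocity_mm_s > 0)
  if (n_neurons > n_electrodes(grid)) {
    stop("more neurons than electrodes (one neuron per electrode)")
  }
  set.seed(as.integer(seed))
  pos <- electrode_positions(grid)
  occ <- sort(sample.int(n_electrodes(grid), n_neurons))
  # soma: electrode centre + sub-patch offset
  off <- matrix(stats::runif(2 * n_neurons, -0.2, 0.2) * grid$pitch,
                ncol = 2)
  neurons <- data.frame(
    id = seq_len(n_neurons),
    row = pos$row[occ], col = pos$col[occ], index = occ,
    x_um = pos$x_um[occ] + off[, 1],
    y_um = pos$y_um[occ] + off[, 2])
  # candidate edges: pairs within reach, connection probability decaying
  # with distance, scaled to the target mean degree
  pr <- utils::combn(n_neurons, 2)
  dx <- neurons$x_um[pr[1, ]] - neurons$x_um[pr[2, ]]
  dy <- neurons$y_um[pr[1, ]] - neurons$y_um[pr[2, ]]
  dist <- sqrt(dx^2 + dy^2)
  cand <- which(dist <= max_reach_um & dist > 0)
  w <- exp(-dist[cand] / (2 * grid$pitch))
  target_edges <- min(round(edge_density * n_neurons / 2), length(cand))
  scale <- if (length(cand) > 0) target_edges / sum(w) else 0
  keep <- cand[stats::runif(length(cand)) < pmin(w * scale, 1)]
  a <- pr[1, keep]; b <- pr[2, keep]
  # curved polyline: quadratic bezier through a jittered midpoint
  polylines <- vector("list", length(keep))
  path_um <- numeric(length(keep))
  for (k in seq_along(keep)) {
    p0 <- c(neurons$x_um[a[k]], neurons$y_um[a[k]])
    p2 <- c(neurons$x_um[b[k]], neurons$y_um[b[k]])
    span <- sqrt(sum((p2 - p0)^2))
    u <- (p2 - p0) / span
    perp <- c(-u[2], u[1])
    p1 <- (p0 + p2) / 2 + perp * stats::rnorm(1, 0, curvature_sd * span)
    tt <- seq(0, 1, length.out = 12)
    bez <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
      outer(tt^2, p2)
    polylines[[k]] <- bez
    path_um[k] <- sum(sqrt(rowSums(diff(bez)^2)))
  }
  edges <- data.frame(a = a, b = b,
                      index_a = neurons$index[a], index_b = neurons$index[b],
                      euclid_um = dist[keep], path_um = path_um)
  edges$polyline <- polylines
  # functional links: directed subset of structural edges
  fl <- which(stats::runif(nrow(edges)) < p_functional)
  flip <- stats::runif(length(fl)) < 0.5
  src <- ifelse(flip, edges$b[fl], edges$a[fl])
  tgt <- ifelse(flip, edges$a[fl], edges$b[fl])
  delay <- edges$path_um[fl] / (velocity_mm_s * 1e3)
  delay <- pmax(delay, edges$path_um[fl] / (400 * 1e3))
  links <- data.frame(
    source = src, target = tgt,
    index_a = neurons$index[src], index_b = neurons$index[tgt],
    coupling_p = rep(coupling_p, length(fl)), delay_s = delay,
    path_um = edges$path_um[fl])
  neuron_map <- integer(n_electrodes(grid))
  neuron_map[occ] <- 1L
  structure(list(grid = grid, neurons = neurons, edges = edges,
                 links = links, neuron_map = neuron_map,
                 params = list(edge_density = edge_density,
                               p_functional = p_functional,
                               coupling_p = coupling_p,
                               velocity_mm_s = velocity_mm_s,
                               curvature_sd = curvature_sd),
                 seed = as.integer(seed)),
            class = "synthetic_network")
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf(
    "<synthetic_network> %d neurons on %d x %d grid, %d structural edges, %d functional links (seed %d)\n",
    nrow(x$neurons), x$grid$n_rows, x$grid$n_cols, nrow(x$edges),
    nrow(x$links), x$seed))
  invisible(x)
}

#' Render a fluorescence-like image of a synthetic network
#'
#' Rasterises the neurite polylines bright-on-dark, draws soma blobs at
#' the neuron positions, applies a Gaussian point-spread blur and adds
#' Gaussian pixel noise -- emulating a tubulin-stained culture image
#' registered to the electrode lattice.
#'
#' @param net A [generate_network()] result.
#' @param px_per_electrode Rendered patch side in pixels (default 12).
#' @param psf_sigma Blur sigma in pixels (default 0.7).
#' @param noise_level Standard deviation of the additive noise
#'   (default 0.05).
#' @param soma_radius_px Soma blob radius in pixels (default 1.5).
#' @return Grayscale matrix in \[0, 1\] of size
#'   `(n_rows * px_per_electrode) x (n_cols * px_per_electrode)`; the
#'   matching registration is `pixels_per_um = px_per_electrode / pitch`.
#' @export
render_image <- function(net, px_per_electrode = 12, psf_sigma = 0.7,
                         noise_level = 0.05, soma_radius_px = 1.5) {
  grid <- net$grid
  ppu <- px_per_electrode / grid$pitch
  nr <- grid$n_rows * px_per_electrode
  nc <- grid$n_cols * px_per_electrode
  img <- matrix(0, nr, nc)
  stamp <- function(r, c, val) {
    r <- round(r); c <- round(c)
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    img[cbind(r[ok], c[ok])] <<- pmax(img[cbind(r[ok], c[ok])], val)
  }
  for (k in seq_len(nrow(net$edges))) {
    bez <- net$edges$polyline[[k]]
    # resample at ~0.4 px spacing
    seg_len <- sqrt(rowSums(diff(bez)^2)) * ppu
    n_pts <- max(2, ceiling(sum(seg_len) / 0.4))
    tt <- seq(0, 1, length.out = n_pts)
    xi <- stats::approx(seq(0, 1, length.out = nrow(bez)), bez[, 1], tt)$y
    yi <- stats::approx(seq(0, 1, length.out = nrow(bez)), bez[, 2], tt)$y
    stamp(yi * ppu + 0.5, xi * ppu + 0.5, 1)
  }
  rad <- ceiling(soma_radius_px)
  disc <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  disc <- disc[disc$dr^2 + disc$dc^2 <= soma_radius_px^2, ]
  for (k in seq_len(nrow(net$neurons))) {
    stamp(net$neurons$y_um[k] * ppu + 0.5 + disc$dr,
          net$neurons$x_um[k] * ppu + 0.5 + disc$dc, 1)
  }
  if (psf_sigma > 0) img <- EBImage::gblur(img, sigma = psf_sigma)
  img <- img / max(max(img), 1e-12)
  if (noise_level > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_level), nr, nc)
  }
  pmin(pmax(img, 0), 1)
}

#' Registration-matched grid for a rendered image
#' @param net A `synthetic_network`.
#' @param px_per_electrode Patch side used in [render_image()].
#' @return The network's grid with `pixels_per_um` set to match the
#'   rendering.
#' @export
rendered_grid <- function(net, px_per_electrode = 12) {
  g <- net$grid
  g$pixels_per_um <- px_per_electrode / g$pitch
  g$patch_px <- px_per_electrode
  g
}

#' Simulate spike trains on a synthetic network
#'
#' Each neuron fires background spikes as a homogeneous Poisson process;
#' each functional link converts source background spikes into target
#' spikes with probability `coupling_p` at the link's conduction delay
#' plus a Gaussian synaptic jitter (delays never fall below the
#' 400 mm/s physiological bound for the link's path). Couplings are
#' propagated one generation (evoked spikes do not themselves trigger
#' further spikes), keeping firing rates analytically accountable. Merged
#' trains are sorted and de-duplicated within one sampling period.
#'
#' @param net A [generate_network()] result.
#' @param T_s Recording length in seconds (default 300).
#' @param bg_rate Background firing rate in Hz (default 1, matching
#'   sparse-culture firing statistics).
#' @param coupling_p Optional override of the per-link transmission
#'   probability.
#' @param delay_jitter Synaptic delay jitter SD in seconds
#'   (default 0.3 ms).
#' @param n_noise_electrodes Number of neuron-free electrodes that emit
#'   independent Poisson spike trains at `bg_rate` (emulating
#'   spike-detection noise and stray dendritic pickup; these are the
#'   nodes the pruning stage exists to remove). Default 0.
#' @param seed Integer seed.
#' @return A [spike_train_set()] with `t_r = T_s`.
#' @export
simulate_spikes <- function(net, T_s = 300, bg_rate = 1,
                            coupling_p = NULL, delay_jitter = 3e-4,
                            n_noise_electrodes = 0, seed = 1L) {
  stopifnot(T_s > 0, bg_rate >= 0, delay_jitter >= 0)
  set.seed(as.integer(seed))
  grid <- net$grid
  n <- nrow(net$neurons)
  bg <- vector("list", n)
  for (i in seq_len(n)) {
    k <- stats::rpois(1, bg_rate * T_s)
    bg[[i]] <- sort(stats::runif(k, 0, T_s))
  }
  evoked <- lapply(seq_len(n), function(i) numeric(0))
  lk <- net$links
  for (j in seq_len(nrow(lk))) {
    p <- if (is.null(coupling_p)) lk$coupling_p[j] else coupling_p
    src <- bg[[lk$source[j]]]
    if (length(src) == 0 || p == 0) next
    fire <- src[stats::runif(length(src)) < p]
    if (length(fire) == 0) next
    d <- lk$delay_s[j] + stats::rnorm(length(fire), 0, delay_jitter)
    d <- pmax(d, lk$path_um[j] / (400 * 1e3))
    tt <- fire + d
    tt <- tt[tt >= 0 & tt <= T_s]
    tgt <- lk$target[j]
    evoked[[tgt]] <- c(evoked[[tgt]], tt)
  }
  dt_min <- 1 / (if (!is.null(grid$f_s)) grid$f_s else 7000)
  trains <- list()
  for (i in seq_len(n)) {
    tt <- sort(c(bg[[i]], evoked[[i]]))
    if (length(tt) == 0) next
    keep <- c(TRUE, diff(tt) >= dt_min)
    trains[[as.character(net$neurons$index[i])]] <- tt[keep]
  }
  if (n_noise_electrodes > 0) {
    free <- which(net$neuron_map == 0)
    stopifnot(n_noise_electrodes <= length(free))
    noisy <- sample(free, n_noise_electrodes)
    for (e in noisy) {
      k <- stats::rpois(1, bg_rate * T_s)
      if (k > 0) trains[[as.character(e)]] <- sort(stats::runif(k, 0, T_s))
    }
  }
  spike_train_set(trains, grid, t_r = T_s)
}

#' Write the ground truth of a synthetic network as JSON
#' @param net A `synthetic_network`.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(net, path) {
  gt <- list(
    seed = net$seed,
    grid = list(n_rows = net$grid$n_rows, n_cols = net$grid$n_cols,
                pitch = net$grid$pitch),
    params = net$params,
    neurons = net$neurons,
    edges = net$edges[, c("index_a", "index_b", "euclid_um", "path_um")],
    links = net$links[, c("index_a", "index_b", "coupling_p", "delay_s",
                          "path_um")])
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
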