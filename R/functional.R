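#' Spike-train set for an electrode array
#'
#' Container for per-electrode spike-time lists. Trains are keyed by the
#' linear electrode index; electrodes without spikes may be absent.
#'
#' @param trains Named list of numeric vectors of spike times (seconds,
#'   sorted ascending); names are linear electrode indices.
#' @param grid An `electrode_grid`.
#' @param t_r Recording length in seconds.
#' @param f_s Sampling rate in Hz.
#' @return Object of class `spike_train_set` with an `electrodes` summary
#'   table (`index`, `row`, `col`, `n`, `mfr`).
#' @export
spike_train_set <- function(trains, grid, t_r, f_s = grid$f_s) {
  stopifnot(t_r > 0)
  trains <- trains[vapply(trains, length, 0L) > 0]
  for (tr in trains) {
    if (is.unsorted(tr)) stop("spike times must be sorted ascending")
    if (any(tr < 0 | tr > t_r)) stop("spike times must lie in [0, t_r]")
  }
  idx <- as.integer(names(trains))
  n <- vapply(trains, length, 0L)
  electrodes <- data.frame(
    index = idx,
    row = (idx - 1L) %/% grid$n_cols + 1L,
    col = (idx - 1L) %% grid$n_cols + 1L,
    n = n,
    mfr = n / t_r
  )
  structure(list(trains = trains, electrodes = electrodes,
                 grid = grid, t_r = t_r, f_s = f_s),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "<spike_train_set> %d active electrodes, t_r = %g s, mean MFR %.3g Hz\n",
    nrow(x$electrodes), x$t_r, mean(x$electrodes$mfr)))
  invisible(x)
}

#' Read / write spike events as CSV
#'
#' One event per line with columns `row`, `col`, `time_s`.
#'
#' @param path CSV path.
#' @param grid An `electrode_grid`.
#' @param t_r Recording length in seconds (defaults to the latest event
#'   time rounded up to the next second).
#' @return A [spike_train_set()].
#' @export
read_spikes_csv <- function(path, grid, t_r = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "col", "time_s") %in% names(df)))
  if (is.null(t_r)) t_r <- ceiling(max(df$time_s))
  idx <- electrode_index(grid, df$row, df$col)
  trains <- split(df$time_s, idx)
  trains <- lapply(trains, sort)
  spike_train_set(trains, grid, t_r)
}

#' @rdname read_spikes_csv
#' @param spikes A `spike_train_set`.
#' @export
write_spikes_csv <- function(spikes, path) {
  idx <- rep(spikes$electrodes$index, spikes$electrodes$n)
  df <- data.frame(
    row = (idx - 1L) %/% spikes$grid$n_cols + 1L,
    col = (idx - 1L) %% spikes$grid$n_cols + 1L,
    time_s = unlist(spikes$trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pairwise cross-correlogram functional links
#'
#' Computes the cross-correlogram and its peak statistics for every
#' unordered pair of active electrodes (each with at least one spike).
#' The correlogram is directional (positive lag: second electrode fires
#' after the first); one row is emitted per unordered pair, with the
#' dominant direction carried by the sign of `C_tau`.
#'
#' @param spikes A [spike_train_set()].
#' @param delta Correlogram bin width in seconds (default 0.5 ms).
#' @param tau_max Lag window half-width in seconds (default 50 ms).
#' @param min_spikes Minimum spikes per train for a pair to be evaluated
#'   (default 1).
#' @return Data frame of class `functional_links`: one row per pair with
#'   `a`, `b` (electrode indices, a < b), `C_P`, `C_tau` (s), `C_O`,
#'   `C_H` (bits), `euclid_um`.
#' @export
functional_links <- function(spikes, delta = 5e-4, tau_max = 0.05,
                             min_spikes = 1) {
  el <- spikes$electrodes[spikes$electrodes$n >= min_spikes, , drop = FALSE]
  idx <- el$index
  np <- length(idx) * (length(idx) - 1) / 2
  if (np == 0) {
    return(structure(data.frame(
      a = integer(0), b = integer(0), C_P = numeric(0), C_tau = numeric(0),
      C_O = integer(0), C_H = numeric(0), euclid_um = numeric(0)),
      class = c("functional_links", "data.frame"),
      delta = delta, tau_max = tau_max))
  }
  pr <- utils::combn(seq_along(idx), 2)
  a <- idx[pr[1, ]]; b <- idx[pr[2, ]]
  res <- matrix(NA_real_, ncol(pr), 4)
  for (k in seq_len(ncol(pr))) {
    cg <- cross_correlogram(spikes$trains[[as.character(a[k])]],
                            spikes$trains[[as.character(b[k])]],
                            delta, tau_max)
    pk <- cc_peak(cg)
    res[k, ] <- c(pk$C_P, if (pk$defined) pk$C_tau else NA_real_,
                  pk$C_O, correlogram_entropy(cg))
  }
  g <- spikes$grid
  eu <- g$pitch * sqrt(
    (((a - 1L) %/% g$n_cols) - ((b - 1L) %/% g$n_cols))^2 +
    (((a - 1L) %% g$n_cols) - ((b - 1L) %% g$n_cols))^2)
  structure(data.frame(a = a, b = b, C_P = res[, 1], C_tau = res[, 2],
                       C_O = as.integer(res[, 3]), C_H = res[, 4],
                       euclid_um = eu),
            class = c("functional_links", "data.frame"),
            delta = delta, tau_max = tau_max)
}

#' Physiological propagation-velocity filter
#'
#' Discards functional links whose correlation-peak latency is smaller
#' than the time an action potential needs to traverse the straight-line
#' distance between the electrodes at the maximum propagation velocity of
#' in vitro preparations (400 mm/s): a link is implausible when
#' `|C_tau| < euclid / v_max`. Coincident electrodes (distance 0) are
#' never discarded by this filter; links with undefined lag fail it.
#'
#' @param links A [functional_links()] table.
#' @param v_max Maximum propagation velocity in mm/s (default 400).
#' @return The table with a logical column `passed_velocity` added.
#' @export
velocity_filter <- function(links, v_max = 400) {
  stopifnot(v_max > 0)
  min_lat <- links$euclid_um / (v_max * 1e3)  # um / (um/s) = s
  links$passed_velocity <- ifelse(
    is.na(links$C_tau), links$euclid_um == 0,
    abs(links$C_tau) >= min_lat)
  links
}

#' Spike-dithering null model and significance threshold
#'
#' Destroys fine-timescale correlation while preserving firing rates by
#' jittering every spike with an i.i.d. uniform offset in
#' `[-jitter, +jitter]` (clipped to the recording window), then recomputes
#' the correlogram peak. The procedure is repeated `reps` times on each of
#' a random sample of active electrode pairs; the pooled null peaks define
#' the global significance threshold `C_s` as their empirical
#' `(1 - p)`-quantile (order statistic). A link is significant when its
#' observed peak strictly exceeds `C_s`; with the discrete counts of a
#' correlogram this keeps the false-positive rate at or below `p`.
#'
#' @param spikes A [spike_train_set()].
#' @param n_pairs Number of sampled pairs (default `min(500, all active
#'   pairs)`).
#' @param jitter Jitter half-width in seconds (default 5 ms).
#' @param reps Repetitions per pair (default 100).
#' @param p Significance level (default 0.05).
#' @param seed Integer seed; the null model is deterministic given the
#'   seed.
#' @param delta,tau_max Correlogram parameters, as in
#'   [functional_links()].
#' @param min_spikes Minimum spikes per train.
#' @return Object of class `null_model`: list with `C_s`, `peaks` (data
#'   frame `a, b, rep, peak, count`), `jitter`, `reps`, `p`, `seed`,
#'   `n_pairs`.
#' @export
dither_null <- function(spikes, n_pairs = 500, jitter = 5e-3, reps = 100,
                        p = 0.05, seed = 1L, delta = 5e-4, tau_max = 0.05,
                        min_spikes = 1) {
  stopifnot(reps >= 1, jitter > 0, p > 0, p < 1)
  el <- spikes$electrodes[spikes$electrodes$n >= min_spikes, , drop = FALSE]
  idx <- el$index
  if (length(idx) < 2) stop("need at least two active electrodes")
  all_pairs <- utils::combn(idx, 2)
  set.seed(as.integer(seed))
  n_pairs <- min(n_pairs, ncol(all_pairs))
  sel <- sort(sample.int(ncol(all_pairs), n_pairs))
  a <- all_pairs[1, sel]; b <- all_pairs[2, sel]
  t_r <- spikes$t_r
  out_a <- rep(a, each = reps)
  out_b <- rep(b, each = reps)
  out_rep <- rep(seq_len(reps), times = n_pairs)
  peak_v <- numeric(n_pairs * reps)
  peak_c <- integer(n_pairs * reps)
  row <- 1L
  for (k in seq_len(n_pairs)) {
    x0 <- spikes$trains[[as.character(a[k])]]
    y0 <- spikes$trains[[as.character(b[k])]]
    norm <- sqrt(length(x0) * length(y0))
    for (r in seq_len(reps)) {
      x <- sort(pmin(pmax(x0 + stats::runif(length(x0), -jitter, jitter), 0), t_r))
      y <- sort(pmin(pmax(y0 + stats::runif(length(y0), -jitter, jitter), 0), t_r))
      pk <- cc_peak_counts(x, y, tau_max, delta)
      peak_c[row] <- pk$count
      peak_v[row] <- pk$count / norm
      row <- row + 1L
    }
  }
  peaks <- data.frame(a = out_a, b = out_b, rep = out_rep,
                      peak = peak_v, count = peak_c)
  structure(list(
    C_s = unname(stats::quantile(peak_v, 1 - p, type = 1)),
    peaks = peaks, jitter = jitter, reps = reps, p = p,
    seed = as.integer(seed), n_pairs = n_pairs,
    delta = delta, tau_max = tau_max
  ), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "<null_model> C_s = %.4g (p = %g, %d pairs x %d reps, +-%g ms jitter)\n",
    x$C_s, x$p, x$n_pairs, x$reps, x$jitter * 1e3))
  invisible(x)
}

#' Functional connectivity graph from spike trains
#'
#' Convenience wrapper: pairwise correlograms, velocity filter, dithering
#' null and significance flags (`significant = passed_velocity & C_P >=
#' C_s`).
#'
#' @inheritParams functional_links
#' @inheritParams dither_null
#' @param v_max Velocity bound in mm/s.
#' @return List of class `functional_graph`: `links` (with
#'   `passed_velocity` and `significant` columns), `null` (the
#'   `null_model`), `spikes` parameters.
#' @export
functional_graph <- function(spikes, delta = 5e-4, tau_max = 0.05,
                             v_max = 400, n_pairs = 500, jitter = 5e-3,
                             reps = 100, p = 0.05, seed = 1L,
                             min_spikes = 1) {
  links <- functional_links(spikes, delta, tau_max, min_spikes)
  links <- velocity_filter(links, v_max)
  null <- dither_null(spikes, n_pairs, jitter, reps, p, seed, delta,
                      tau_max, min_spikes)
  links$significant <- links$passed_velocity & links$C_P > null$C_s
  structure(list(links = links, null = null,
                 params = list(delta = delta, tau_max = tau_max,
                               v_max = v_max, seed = as.integer(seed))),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf(
    "<functional_graph> %d pairs, %d passed velocity filter, %d significant (C_s = %.4g)\n",
    nrow(x$links), sum(x$links$passed_velocity), sum(x$links$significant),
    x$null$C_s))
  invisible(x)
}
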