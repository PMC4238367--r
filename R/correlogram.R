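#' Cross-correlogram of two spike trains
#'
#' Histogram of spike-time differences `u - t` (`t` a spike of train x,
#' `u` a spike of train y) in bins of width `delta` centred at lags
#' `-tau_max ... tau_max`, normalised by the geometric mean of the spike
#' counts: `C(tau) = count(tau) / sqrt(N_x * N_y)`. A positive lag means y
#' fires after x. Raw counts are retained alongside the normalised values.
#'
#' @param x,y Numeric vectors of spike times in seconds, sorted ascending,
#'   each with at least one spike.
#' @param delta Bin width in seconds (default 0.5 ms).
#' @param tau_max Half-width of the lag window in seconds (default 50 ms;
#'   must comfortably exceed the largest physiologically plausible latency
#'   on the array).
#' @return Object of class `correlogram`: list with `lags` (bin centres,
#'   s), `counts`, `values`, `delta`, `n_x`, `n_y`.
#' @export
cross_correlogram <- function(x, y, delta = 5e-4, tau_max = 0.05) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both spike trains must contain at least one spike")
  }
  stopifnot(!is.unsorted(x), !is.unsorted(y), delta > 0, tau_max >= delta)
  counts <- cc_counts(x, y, tau_max, delta)
  K <- (length(counts) - 1L) / 2L
  structure(list(
    lags = (-K:K) * delta,
    counts = counts,
    values = counts / sqrt(length(x) * length(y)),
    delta = delta, n_x = length(x), n_y = length(y)
  ), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d bins of %g ms, N_x = %d, N_y = %d, peak %g\n",
              length(x$lags), x$delta * 1e3, x$n_x, x$n_y, max(x$values)))
  invisible(x)
}

#' Cross-correlation peak
#'
#' The peak statistic of a correlogram: `C_P = max_tau C(tau)`, its lag
#' `C_tau` and the raw coincidence count `C_O` at the peak bin. Ties are
#' broken towards the smallest absolute lag, then towards the positive
#' lag. An all-zero correlogram yields `C_P = 0` with an undefined lag
#' (`C_tau = NA`).
#'
#' @param cg A [cross_correlogram()].
#' @return List with `C_P`, `C_tau` (seconds, `NA` if undefined), `C_O`
#'   (integer count), `defined` (logical).
#' @export
cc_peak <- function(cg) {
  stopifnot(inherits(cg, "correlogram"))
  if (all(cg$counts == 0L)) {
    return(list(C_P = 0, C_tau = NA_real_, C_O = 0L, defined = FALSE))
  }
  mx <- max(cg$counts)
  cand <- which(cg$counts == mx)
  lag <- cg$lags[cand]
  cand <- cand[order(abs(lag), -sign(lag))]
  k <- cand[1]
  list(C_P = cg$values[k], C_tau = cg$lags[k], C_O = cg$counts[k],
       defined = TRUE)
}

#' Entropy of the cross-correlation function
#'
#' Spread of the correlogram measured as the Shannon entropy of the
#' normalised correlogram `C_n(tau) = C(tau) / sum C(tau)`:
#' `C_H = -sum C_n(tau) log2 C_n(tau)` (zero bins contribute nothing).
#' Broad, unreliable correlograms have high entropy; a single sharp peak
#' has entropy zero.
#'
#' @param cg A [cross_correlogram()], or a non-negative numeric vector of
#'   correlogram values.
#' @return Entropy in bits; `NA` for an all-zero correlogram.
#' @export
correlogram_entropy <- function(cg) {
  v <- if (inherits(cg, "correlogram")) cg$values else cg
  stopifnot(is.numeric(v), all(v >= 0))
  s <- sum(v)
  if (s == 0) return(NA_real_)
  p <- v[v > 0] / s
  -sum(p * log2(p))
}
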