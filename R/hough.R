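#' Hough line-segment detection parameters
#'
#' Controls the per-patch segment detector used to summarise local neurite
#' orientation. Neurite staining renders processes as bright ridges on a
#' dark background, so the edge map is a simple intensity threshold.
#'
#' @param edge_threshold Intensity (image normalised to \[0, 1\]) above
#'   which a pixel is treated as neurite evidence.
#' @param vote_threshold Minimum Hough accumulator votes for a candidate
#'   line to be considered.
#' @param min_length Minimum segment length in pixels.
#' @param max_gap Maximum along-line gap (pixels) bridged within a segment.
#' @param theta_step Angular resolution of the accumulator in degrees.
#' @param dist_tol Perpendicular distance tolerance (pixels) for assigning
#'   edge pixels to a candidate line.
#' @param max_segments Maximum number of segments extracted per patch.
#' @return A list of class `hough_config`.
#' @export
hough_config <- function(edge_threshold = 0.4, vote_threshold = 5,
                         min_length = 4, max_gap = 2,
                         theta_step = 3, dist_tol = 1, max_segments = 8) {
  stopifnot(edge_threshold > 0, vote_threshold >= 1, min_length > 0,
            max_gap >= 0, theta_step > 0, dist_tol > 0, max_segments >= 1)
  structure(as.list(environment()), class = "hough_config")
}

# Accumulate votes over (theta, rho) for edge points (x, y).
# rho = x cos(theta) + y sin(theta), 1 px rho bins.
hough_accumulate <- function(x, y, thetas, rho_max) {
  n_rho <- 2L * ceiling(rho_max) + 1L
  acc <- matrix(0L, n_rho, length(thetas))
  for (k in seq_along(thetas)) {
    rho <- x * cos(thetas[k]) + y * sin(thetas[k])
    bin <- round(rho) + ceiling(rho_max) + 1L
    tab <- tabulate(bin, nbins = n_rho)
    acc[, k] <- tab
  }
  acc
}

#' Detect bright line segments in an image patch
#'
#' A Hough-transform segment detector: edge pixels (intensity above
#' `edge_threshold`) vote in a (theta, rho) accumulator; accumulator peaks
#' are converted to segments by collecting the pixels within `dist_tol` of
#' the peak line, ordering them along the line and splitting at gaps larger
#' than `max_gap`. Each returned segment carries its endpoints (pixel
#' coordinates local to the patch), its supporting vote count and its
#' orientation. Pixels claimed by a segment are removed before the next
#' peak is sought.
#'
#' @param patch Numeric matrix (grayscale patch) or a patch list from
#'   [partition_image()].
#' @param config A [hough_config()].
#' @return Data frame with one row per segment: `r1, c1, r2, c2`
#'   (endpoints, patch-local pixel coordinates), `votes`, `theta`
#'   (orientation in \[0, pi), counterclockwise from +x with north = up).
#'   Zero rows when no segment is found.
#' @export
detect_segments <- function(patch, config = hough_config()) {
  px <- if (is.list(patch)) patch$pixels else patch
  stopifnot(is.matrix(px))
  empty <- data.frame(r1 = numeric(0), c1 = numeric(0),
                      r2 = numeric(0), c2 = numeric(0),
                      votes = integer(0), theta = numeric(0))
  idx <- which(px >= config$edge_threshold, arr.ind = TRUE)
  if (nrow(idx) < config$vote_threshold) return(empty)
  # pixel centres: x = col, y = row
  pts <- data.frame(x = idx[, 2], y = idx[, 1])
  thetas <- seq(0, pi - 1e-9, by = config$theta_step * pi / 180)
  rho_max <- sqrt(nrow(px)^2 + ncol(px)^2)
  segs <- empty
  for (iter in seq_len(config$max_segments)) {
    if (nrow(pts) < config$vote_threshold) break
    acc <- hough_accumulate(pts$x, pts$y, thetas, rho_max)
    best <- which.max(acc)
    if (acc[best] < config$vote_threshold) break
    k <- (best - 1L) %/% nrow(acc) + 1L
    rbin <- (best - 1L) %% nrow(acc) + 1L
    theta <- thetas[k]
    rho <- rbin - ceiling(rho_max) - 1L
    d <- abs(pts$x * cos(theta) + pts$y * sin(theta) - rho)
    on_line <- d <= config$dist_tol
    if (!any(on_line)) break
    sel <- pts[on_line, , drop = FALSE]
    # position along the line direction (-sin, cos)
    s <- -sel$x * sin(theta) + sel$y * cos(theta)
    ord <- order(s)
    sel <- sel[ord, , drop = FALSE]
    s <- s[ord]
    run_id <- cumsum(c(1, diff(s) > config$max_gap))
    used <- logical(nrow(sel))
    for (run in unique(run_id)) {
      in_run <- run_id == run
      if (sum(in_run) < config$vote_threshold) next
      srun <- s[in_run]
      if (max(srun) - min(srun) < config$min_length) next
      p <- sel[in_run, , drop = FALSE]
      a <- p[1L, ]
      b <- p[nrow(p), ]
      ang <- atan2(-(b$y - a$y), b$x - a$x) %% pi
      segs <- rbind(segs, data.frame(
        r1 = a$y, c1 = a$x, r2 = b$y, c2 = b$x,
        votes = sum(in_run), theta = ang))
      used[in_run] <- TRUE
    }
    if (!any(used)) {
      # peak produced no admissible run: drop its strip to make progress
      used[] <- TRUE
    }
    drop_keys <- paste(sel$x[used], sel$y[used])
    pts <- pts[!(paste(pts$x, pts$y) %in% drop_keys), , drop = FALSE]
  }
  segs
}
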