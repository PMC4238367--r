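#' Von Mises density
#'
#' Density of the Von Mises distribution, the circular analogue of the
#' Gaussian, with mean direction `mu` and concentration `kappa`
#' (`kappa = 0` is uniform on the circle). Computed with exponentially
#' scaled Bessel functions so that large concentrations do not overflow.
#'
#' @param theta Angles (radians).
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Density values.
#' @export
dvonmises <- function(theta, mu, kappa) {
  stopifnot(kappa >= 0)
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# P(theta in [a, b]) for a Von Mises(mu, kappa), b - a <= 2*pi, via the
# Fourier series of the density:
#   (b-a)/(2*pi) + (1/pi) * sum_j (I_j(k)/I_0(k)) * (sin(j(b-mu)) - sin(j(a-mu))) / j
# The Bessel ratio decays like exp(-j^2 / (2*kappa)); the truncation order
# scales with sqrt(kappa).
vonmises_sector_prob <- function(mu, kappa, a, b) {
  if (kappa == 0) return((b - a) / (2 * pi))
  jmax <- max(60L, ceiling(8 * sqrt(kappa)))
  j <- seq_len(jmax)
  ratio <- besselI(kappa, 0, expon.scaled = TRUE)
  rj <- vapply(j, function(jj) besselI(kappa, jj, expon.scaled = TRUE), 0) / ratio
  p <- (b - a) / (2 * pi) +
    sum(rj / j * (sin(j * (b - mu)) - sin(j * (a - mu)))) / pi
  min(max(p, 0), 1)
}

#' Fit a Von Mises mixture to segment endpoints of a patch
#'
#' Each detected segment contributes two mixture components, one per
#' endpoint. The component mean is the angle of the endpoint as projected
#' from the patch centre onto the circle circumscribing the patch -- the
#' most probable direction at which the neurite crosses into the
#' neighbouring electrode area. The concentration encodes the certainty of
#' that crossing angle and is inversely proportional to the endpoint's
#' distance from the patch boundary: `kappa = kappa_scale / (d + eps)`,
#' capped at `kappa_max`. Mixture weights are proportional to the segments'
#' Hough votes (each endpoint inherits its segment's votes) and normalised
#' to sum to one.
#'
#' @param segments Data frame from [detect_segments()].
#' @param patch_dim Integer vector `c(n_rows_px, n_cols_px)` of the patch,
#'   or a patch list from [partition_image()].
#' @param kappa_scale Proportionality constant in pixels (default 10).
#' @param eps Regulariser for endpoints on the boundary (default 1 px).
#' @param kappa_max Concentration cap for numerical stability.
#' @return Data frame with one row per component: `mu`, `kappa`, `weight`.
#'   Zero rows if no segments were supplied.
#' @export
fit_vmm <- function(segments, patch_dim, kappa_scale = 10, eps = 1,
                    kappa_max = 1e4) {
  stopifnot(kappa_scale > 0, eps > 0)
  if (is.list(patch_dim) && !is.null(patch_dim$pixels)) {
    patch_dim <- dim(patch_dim$pixels)
  }
  nr <- patch_dim[1]; nc <- patch_dim[2]
  if (is.null(segments) || nrow(segments) == 0) {
    return(data.frame(mu = numeric(0), kappa = numeric(0), weight = numeric(0)))
  }
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ep <- rbind(
    data.frame(r = segments$r1, c = segments$c1, votes = segments$votes),
    data.frame(r = segments$r2, c = segments$c2, votes = segments$votes)
  )
  mu <- atan2(-(ep$r - cy), ep$c - cx) %% (2 * pi)
  d <- pmin(ep$r - 0.5, nr + 0.5 - ep$r, ep$c - 0.5, nc + 0.5 - ep$c)
  d <- pmax(d, 0)
  kappa <- pmin(kappa_scale / (d + eps), kappa_max)
  data.frame(mu = mu, kappa = kappa, weight = ep$votes / sum(ep$votes))
}

#' Discretise a Von Mises mixture into the 8 neighbour directions
#'
#' Integrates the mixture density over eight 45-degree sectors centred on
#' the neighbour bearings (E = 0, NE = 45, ..., SE = 315 degrees,
#' counterclockwise from the +x image axis). The result is the directional
#' feature of the electrode: entry k is the probability that a neurite
#' leaves the patch towards neighbour k.
#'
#' @param components Data frame from [fit_vmm()] (columns `mu`, `kappa`,
#'   `weight`).
#' @return Named numeric 8-vector (E, NE, N, NW, W, SW, S, SE) summing to 1
#'   when components exist, all zero otherwise.
#' @export
discretize_vmm <- function(components) {
  dirs <- mea_directions()
  out <- setNames(numeric(8), dirs$name)
  if (is.null(components) || nrow(components) == 0) return(out)
  w <- components$weight
  stopifnot(abs(sum(w) - 1) < 1e-8)
  for (k in 1:8) {
    a <- dirs$angle[k] - pi / 8
    b <- dirs$angle[k] + pi / 8
    out[k] <- sum(vapply(seq_len(nrow(components)), function(i) {
      w[i] * vonmises_sector_prob(components$mu[i], components$kappa[i], a, b)
    }, 0))
  }
  # the 8 sectors tile the circle; renormalise away quadrature truncation
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

#' Directional features for every electrode patch
#'
#' Runs segment detection, Von Mises mixture fitting and sector
#' discretisation on each patch of a partitioned image.
#'
#' @param patches List from [partition_image()].
#' @param hough A [hough_config()].
#' @param kappa_scale,eps,kappa_max Passed to [fit_vmm()].
#' @return Matrix `n_electrodes x 8` (row-major electrode order, columns
#'   E, NE, N, NW, W, SW, S, SE). Rows are all-zero for patches without
#'   detected segments.
#' @export
directional_features <- function(patches, hough = hough_config(),
                                 kappa_scale = 10, eps = 1, kappa_max = 1e4) {
  feats <- matrix(0, length(patches), 8,
                  dimnames = list(NULL, mea_directions()$name))
  for (i in seq_along(patches)) {
    segs <- detect_segments(patches[[i]]$pixels, hough)
    if (nrow(segs) == 0) next
    comp <- fit_vmm(segs, dim(patches[[i]]$pixels), kappa_scale, eps, kappa_max)
    feats[i, ] <- discretize_vmm(comp)
  }
  feats
}
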