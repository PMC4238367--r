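#' Read / write a neuron-to-electrode map
#'
#' The neuron map gives the number of detected neuron somata in each
#' electrode's recording area. It is either produced by an external
#' nuclei-detection pipeline, by [detect_neurons()], or by the synthetic
#' generator. CSV columns: `row`, `col`, `n_neurons`. Electrodes absent
#' from the file are taken to have zero neurons.
#'
#' @param path CSV file path.
#' @param grid An `electrode_grid`.
#' @return Integer vector of length `n_electrodes` (row-major), names the
#'   electrode indices.
#' @export
read_neuron_map <- function(path, grid) {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "col", "n_neurons") %in% names(df)))
  neuron_map_from_df(df, grid)
}

#' @rdname read_neuron_map
#' @param df Data frame with columns `row`, `col`, `n_neurons`.
#' @export
neuron_map_from_df <- function(df, grid) {
  m <- integer(n_electrodes(grid))
  if (nrow(df) > 0) {
    idx <- electrode_index(grid, df$row, df$col)
    m[idx] <- m[idx] + as.integer(df$n_neurons)
  }
  m
}

#' @rdname read_neuron_map
#' @param neuron_map Integer vector of per-electrode neuron counts.
#' @export
write_neuron_map <- function(neuron_map, grid, path) {
  idx <- which(neuron_map > 0)
  row <- (idx - 1L) %/% grid$n_cols + 1L
  col <- (idx - 1L) %% grid$n_cols + 1L
  utils::write.csv(data.frame(row = row, col = col,
                              n_neurons = neuron_map[idx]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Simple intensity blob detector for neuron somata
#'
#' Counts bright connected components per electrode patch as a stand-in
#' for a full nuclei-detection pipeline: the image is lightly smoothed,
#' thresholded, connected components are labelled (8-connectivity) and
#' components of at least `min_area` pixels are assigned to the electrode
#' patch containing their centroid.
#'
#' @param image Grayscale matrix in \[0, 1\] (nuclei bright on dark).
#' @param grid An `electrode_grid`.
#' @param threshold Intensity threshold for soma pixels.
#' @param min_area Minimum component area in pixels.
#' @param sigma Smoothing sigma in pixels.
#' @return Integer vector of per-electrode neuron counts (row-major).
#' @export
detect_neurons <- function(image, grid, threshold = 0.6, min_area = 3,
                           sigma = 1) {
  sm <- EBImage::gblur(image, sigma = sigma)
  lab <- EBImage::bwlabel(sm >= threshold)
  m <- integer(n_electrodes(grid))
  nlab <- max(lab)
  if (nlab == 0) return(m)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  area <- tabulate(labs, nlab)
  cr <- tapply(idx[, 1], labs, mean)
  cc <- tapply(idx[, 2], labs, mean)
  keep <- which(area >= min_area)
  side <- grid$patch_px
  for (k in keep) {
    i <- floor((cr[[as.character(k)]] - 1 - grid$offset_y) / side) + 1
    j <- floor((cc[[as.character(k)]] - 1 - grid$offset_x) / side) + 1
    if (i >= 1 && i <= grid$n_rows && j >= 1 && j <= grid$n_cols) {
      e <- (i - 1) * grid$n_cols + j
      m[e] <- m[e] + 1L
    }
  }
  m
}

#' Read a grayscale culture image
#'
#' Reads a single-channel PNG or TIFF into a numeric matrix in \[0, 1\];
#' multi-channel images are averaged to grayscale.
#'
#' @param path Image file path (.png, .tif/.tiff).
#' @return Numeric matrix (rows = image rows).
#' @export
read_culture_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image
#' @param image Matrix in \[0, 1\].
#' @param path Output path (.png or .tif/.tiff).
#' @export
write_culture_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Structural connectivity prior from a culture image
#'
#' Full structural pipeline: partition the image over the electrode
#' lattice, extract per-patch directional features (Hough segments +
#' Von Mises mixture + 8-sector discretisation), assemble the symmetrised
#' lattice adjacency, diffuse it with the graph heat kernel, restrict to
#' seed electrodes (>= 1 neuron) and normalise, then derive the discrete
#' structural graph and shortest-path distance table.
#'
#' @param image Grayscale matrix, registered to `grid`.
#' @param grid An `electrode_grid`.
#' @param neuron_map Integer vector of per-electrode neuron counts
#'   (row-major); if `NULL`, [detect_neurons()] is run on the image.
#' @param t Heat-diffusion time (default 25).
#' @param sc_threshold Structural-link threshold on the normalised map.
#' @param hough A [hough_config()].
#' @param kappa_scale,eps,kappa_max Von Mises fitting parameters, see
#'   [fit_vmm()].
#' @param include_diagonal Normalisation convention, see
#'   [propagate_and_normalize()].
#' @return Object of class `structural_prior`: list with `features`,
#'   `adjacency`, `kernel`, `map` (normalised seed x seed connectivity),
#'   `graph` (a `structural_graph` with distances), `neuron_map`, `seeds`,
#'   `grid`, `params`.
#' @export
structural_prior <- function(image, grid, neuron_map = NULL, t = 25,
                             sc_threshold = 0.05, hough = hough_config(),
                             kappa_scale = 10, eps = 1, kappa_max = 1e4,
                             include_diagonal = FALSE) {
  if (is.null(neuron_map)) neuron_map <- detect_neurons(image, grid)
  stopifnot(length(neuron_map) == n_electrodes(grid))
  seeds <- which(neuron_map > 0)
  if (length(seeds) == 0) stop("no electrode has a neuron: empty seed set")
  patches <- partition_image(image, grid)
  features <- directional_features(patches, hough, kappa_scale, eps, kappa_max)
  A <- build_adjacency(features, grid)
  hk <- heat_kernel(A, t)
  sc <- propagate_and_normalize(hk, seeds, include_diagonal)
  sg <- structural_distances(sc, grid, sc_threshold)
  structure(list(features = features, adjacency = A, kernel = hk,
                 map = sc$map, graph = sg, neuron_map = neuron_map,
                 seeds = seeds, grid = grid,
                 params = list(t = t, sc_threshold = sc_threshold,
                               kappa_scale = kappa_scale, eps = eps,
                               kappa_max = kappa_max,
                               include_diagonal = include_diagonal,
                               hough = unclass(hough))),
            class = "structural_prior")
}

#' @export
print.structural_prior <- function(x, ...) {
  cat(sprintf(
    "<structural_prior> %d x %d grid, %d seed electrodes, %d SC links, t = %g\n",
    x$grid$n_rows, x$grid$n_cols, length(x$seeds), nrow(x$graph$edges),
    x$params$t))
  invisible(x)
}

#' Export a structural edge list
#' @param sp A `structural_prior`.
#' @param path Output CSV path.
#' @return The path, invisibly. Columns: `row_a, col_a, row_b, col_b,
#'   strength, euclid_um`.
#' @export
write_structural_edges <- function(sp, path) {
  e <- sp$graph$edges
  nc <- sp$grid$n_cols
  out <- data.frame(
    row_a = (e$a - 1L) %/% nc + 1L, col_a = (e$a - 1L) %% nc + 1L,
    row_b = (e$b - 1L) %/% nc + 1L, col_b = (e$b - 1L) %% nc + 1L,
    strength = e$strength, euclid_um = e$euclid_um)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
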