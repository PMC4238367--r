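#' Electrode grid geometry
#'
#' Describes the regular lattice of recording electrodes of a high-density
#' micro-electrode array (HD-MEA) and its registration to a culture image.
#' The default geometry is the 64 x 64 layout with 42 um pitch used by
#' 4096-electrode CMOS arrays.
#'
#' @param n_rows,n_cols Number of electrode rows / columns.
#' @param pitch Electrode pitch in micrometres (centre-to-centre).
#' @param f_s Sampling rate of the electrophysiology in Hz.
#' @param t_r Recording length in seconds (may be `NULL` until spikes are
#'   attached).
#' @param pixels_per_um Image registration scale: image pixels per
#'   micrometre. One electrode patch is `pitch * pixels_per_um` pixels wide.
#' @param offset_x,offset_y Registration offset in pixels of the top-left
#'   corner of electrode (1, 1) within the image (x = columns, y = rows).
#'
#' @return An object of class `electrode_grid`.
#' @export
electrode_grid <- function(n_rows = 64L, n_cols = 64L, pitch = 42,
                           f_s = 7000, t_r = NULL,
                           pixels_per_um = 1, offset_x = 0, offset_y = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0, pixels_per_um > 0)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    pitch = pitch, f_s = f_s, t_r = t_r,
    pixels_per_um = pixels_per_um,
    offset_x = offset_x, offset_y = offset_y,
    patch_px = pitch * pixels_per_um
  ), class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d electrodes, pitch %g um (%g px/patch)\n",
              x$n_rows, x$n_cols, x$pitch, x$patch_px))
  invisible(x)
}

n_electrodes <- function(grid) grid$n_rows * grid$n_cols

#' Linear electrode index (row-major)
#' @param grid An `electrode_grid`.
#' @param row,col Electrode row / column indices (1-based).
#' @return Integer index in `1:(n_rows * n_cols)`.
#' @export
electrode_index <- function(grid, row, col) {
  stopifnot(all(row >= 1 & row <= grid$n_rows), all(col >= 1 & col <= grid$n_cols))
  as.integer((row - 1L) * grid$n_cols + col)
}

#' Electrode centre positions in micrometres
#'
#' Positions are measured from the top-left corner of the active area;
#' `x` grows with columns, `y` with rows (image convention). Only relative
#' (euclidean) distances are used downstream.
#'
#' @param grid An `electrode_grid`.
#' @return Data frame with columns `row`, `col`, `index`, `x_um`, `y_um`.
#' @export
electrode_positions <- function(grid) {
  g <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  data.frame(
    row = g$row, col = g$col,
    index = electrode_index(grid, g$row, g$col),
    x_um = (g$col - 0.5) * grid$pitch,
    y_um = (g$row - 0.5) * grid$pitch
  )[order(g$row * grid$n_cols + g$col), c("row", "col", "index", "x_um", "y_um")]
}

#' Euclidean distance between two electrodes in micrometres
#' @param grid An `electrode_grid`.
#' @param row_a,col_a,row_b,col_b Electrode coordinates (vectorised).
#' @return Numeric vector of distances in um.
#' @export
electrode_distance_um <- function(grid, row_a, col_a, row_b, col_b) {
  grid$pitch * sqrt((row_a - row_b)^2 + (col_a - col_b)^2)
}

# The 8 neighbour directions, indexed 1..8 = E, NE, N, NW, W, SW, S, SE.
# Angles are counterclockwise from the +x image axis with north = up
# (decreasing image row).
mea_directions <- function() {
  data.frame(
    dir = 1:8,
    name = c("E", "NE", "N", "NW", "W", "SW", "S", "SE"),
    dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
    dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
    angle = (0:7) * pi / 4
  )
}

#' Partition a culture image into per-electrode patches
#'
#' Tiles the image into `n_rows * n_cols` rectangular patches, one per
#' electrode recording area, using the grid's registration (offset and
#' scale). Patch boundaries are rounded to whole pixels so the patches tile
#' the active area without overlap even when the patch side is not an
#' integer number of pixels.
#'
#' @param image Numeric matrix (grayscale, rows = image rows).
#' @param grid An `electrode_grid` whose registration matches the image.
#' @return A list of length `n_rows * n_cols` (row-major electrode order);
#'   each element has `row`, `col`, `rows`, `cols` (pixel index ranges) and
#'   `pixels` (the patch sub-matrix).
#' @export
partition_image <- function(image, grid) {
  stopifnot(is.matrix(image))
  side <- grid$patch_px
  need_r <- grid$offset_y + grid$n_rows * side
  need_c <- grid$offset_x + grid$n_cols * side
  if (nrow(image) < floor(need_r) || ncol(image) < floor(need_c)) {
    stop(sprintf(
      "image (%d x %d px) smaller than grid extent (%g x %g px)",
      nrow(image), ncol(image), need_r, need_c))
  }
  r_edges <- round(grid$offset_y + (0:grid$n_rows) * side)
  c_edges <- round(grid$offset_x + (0:grid$n_cols) * side)
  patches <- vector("list", n_electrodes(grid))
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      rows <- (r_edges[i] + 1L):r_edges[i + 1L]
      cols <- (c_edges[j] + 1L):c_edges[j + 1L]
      patches[[(i - 1L) * grid$n_cols + j]] <- list(
        row = i, col = j, rows = rows, cols = cols,
        pixels = image[rows, cols, drop = FALSE]
      )
    }
  }
  patches
}
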