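#' Hyperspectral cube container
#'
#' A focal-plane-array style image: an `n_rows x n_cols` grid of pixels, each
#' carrying a full spectrum on a shared axis. Data are held as a 3-d array
#' `[row, col, channel]`. Pixel indexing is 0-based in the ROI interface to
#' keep region arithmetic unambiguous.
#'
#' @param data numeric array `[n_rows, n_cols, n_channels]`.
#' @param wavenumber shared axis (cm^-1), strictly increasing.
#' @param pixel_size pixel edge length in micrometres (5.5 for the reference
#'   FPA geometry).
#' @param modality `"IR"` or `"RAMAN"`.
#' @param mask optional logical `n_rows x n_cols` matrix marking cell pixels
#'   (carried as provenance by the synthetic generator).
#' @return An object of class `vib_hypercube`.
#' @export
hypercube <- function(data, wavenumber, pixel_size = 5.5,
                      modality = c("IR", "RAMAN"), mask = NULL) {
  modality <- match.arg(modality)
  check_axis(wavenumber)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_contract("cube data must be a 3-d array [row, col, channel]")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L) stop_contract("cube needs at least one pixel")
  if (d[3] != length(wavenumber))
    stop_contract("cube has %d channels but axis has %d points", d[3], length(wavenumber))
  if (anyNA(data) || any(!is.finite(data))) stop_contract("cube intensities must be finite")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  }
  structure(list(data = data, wavenumber = as.numeric(wavenumber),
                 n_rows = d[1], n_cols = d[2],
                 pixel_size = pixel_size, modality = modality, mask = mask),
            class = "vib_hypercube")
}

#' @export
print.vib_hypercube <- function(x, ...) {
  cat(sprintf("<vib_hypercube> %s, %d x %d pixels (%.1f um), %d channels, %.0f-%.0f cm^-1\n",
              x$modality, x$n_rows, x$n_cols, x$pixel_size,
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle: rows `row0 .. row0+height-1`, columns
#' `col0 .. col0+width-1`.
#'
#' @param row0,col0 top-left pixel (0-based)
#' @param height,width extents in pixels, both >= 1
#' @return an object of class `vib_roi`
#' @export
roi <- function(row0, col0, height, width) {
  if (height < 1 || width < 1) stop_contract("ROI extents must be >= 1")
  if (row0 < 0 || col0 < 0) stop_contract("ROI origin must be >= 0")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "vib_roi")
}

check_roi <- function(cube, r) {
  stopifnot(inherits(r, "vib_roi"))
  if (r$row0 + r$height > cube$n_rows || r$col0 + r$width > cube$n_cols)
    stop_contract("ROI [%d+%d, %d+%d] exceeds cube %d x %d",
                  r$row0, r$height, r$col0, r$width, cube$n_rows, cube$n_cols)
  invisible(r)
}

#' Extract one pixel spectrum from a cube
#'
#' @param cube a [hypercube()]
#' @param row,col 0-based pixel indices
#' @return a [spectrum()] sharing the cube axis; `meta` records `(row, col)`
#' @export
extract_pixel <- function(cube, row, col) {
  stopifnot(inherits(cube, "vib_hypercube"))
  if (row < 0 || row >= cube$n_rows || col < 0 || col >= cube$n_cols)
    stop_contract("pixel (%d, %d) outside cube %d x %d", row, col,
                  cube$n_rows, cube$n_cols)
  spectrum(cube$wavenumber, cube$data[row + 1L, col + 1L, ],
           modality = cube$modality,
           meta = list(row = as.integer(row), col = as.integer(col)))
}

# pixels x channels matrix view (row-major pixel order)
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(aperm(cube$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  m
}

# inverse of cube_matrix
matrix_to_cube <- function(m, cube) {
  arr <- aperm(array(m, dim = c(cube$n_cols, cube$n_rows, length(cube$wavenumber))),
               c(2, 1, 3))
  hypercube(arr, cube$wavenumber, pixel_size = cube$pixel_size,
            modality = cube$modality, mask = cube$mask)
}

#' Restrict a cube to a wavenumber window
#'
#' Channels with `lo <= wavenumber <= hi` are retained for every pixel.
#'
#' @param cube a [hypercube()]
#' @param lo,hi closed window bounds (cm^-1)
#' @return a [hypercube()] on the restricted axis
#' @export
crop_cube <- function(cube, lo, hi) {
  idx <- axis_window_idx(cube$wavenumber, lo, hi)
  if (!length(idx)) stop_contract("window [%g, %g] contains no channels", lo, hi)
  hypercube(cube$data[, , idx, drop = FALSE], cube$wavenumber[idx],
            pixel_size = cube$pixel_size, modality = cube$modality,
            mask = cube$mask)
}
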