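#' Calibrated single-channel fluorescence image
#'
#' Container for one tangential-section fluorescence channel on a
#' micrometre-calibrated pixel grid, together with a boolean analysis mask
#' marking valid tissue (e.g. the V1 outline). All downstream operations
#' restrict themselves to masked pixels.
#'
#' The coordinate convention used throughout the package: the origin sits at
#' the centre of the upper-left pixel, `x` runs along columns and `y` along
#' rows, so a point at `(x_um, y_um)` falls on pixel
#' `(row, col) = (y_um / pixel_size_um + 1, x_um / pixel_size_um + 1)`
#' (1-based indices). Physical micrometres, never pixel indices, cross
#' function boundaries.
#'
#' @param pixels Numeric matrix of intensities (arbitrary fluorescence
#'   units). Masked pixels must be finite and non-negative.
#' @param pixel_size_um Pixel pitch in micrometres per pixel (> 0).
#' @param mask Logical matrix of the same dimension, `TRUE` for pixels inside
#'   the analysis region. Defaults to the full frame.
#' @return An object of class `planar_image`: a list with elements `pixels`,
#'   `pixel_size_um` and `mask`.
#' @export
planar_image <- function(pixels, pixel_size_um, mask = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  } else {
    if (!is.matrix(mask) || !is.logical(mask) ||
        !identical(dim(mask), dim(pixels)))
      stop("`mask` must be a logical matrix matching `pixels` in dimension")
  }
  v <- pixels[mask]
  if (length(v) == 0L) stop("mask is empty: no pixels to analyse")
  if (any(!is.finite(v)) || any(v < 0))
    stop("masked pixel values must be finite and >= 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um, mask = mask),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "planar_image: %d x %d px at %g um/px (%g x %g um), %d masked px\n",
    d[1], d[2], x$pixel_size_um,
    d[2] * x$pixel_size_um, d[1] * x$pixel_size_um, sum(x$mask)))
  invisible(x)
}

#' @export
dim.planar_image <- function(x) dim(x$pixels)

is_planar_image <- function(x) inherits(x, "planar_image")

# x/y coordinates (um) of every pixel centre, as matrices matching the grid
pixel_coords_um <- function(image) {
  d <- dim(image$pixels)
  px <- image$pixel_size_um
  list(
    x = matrix((seq_len(d[2]) - 1) * px, d[1], d[2], byrow = TRUE),
    y = matrix((seq_len(d[1]) - 1) * px, d[1], d[2])
  )
}

# nearest pixel (row, col) for points in um; NA outside the grid
points_to_pixels <- function(x_um, y_um, dim, pixel_size_um) {
  row <- round(y_um / pixel_size_um) + 1
  col <- round(x_um / pixel_size_um) + 1
  bad <- row < 1 | row > dim[1] | col < 1 | col > dim[2] |
    !is.finite(row) | !is.finite(col)
  row[bad] <- NA_real_
  col[bad] <- NA_real_
  cbind(row = row, col = col)
}
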