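#' Read a grayscale TIFF as a calibrated image
#'
#' Accepts single-channel 8/16-bit integer or 32-bit float TIFFs. The pixel
#' size comes from the TIFF resolution tags when present; an explicit
#' `pixel_size_um` always wins, with a warning if the two disagree.
#' Multi-channel (RGB) input is rejected with an explicit error.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Pixel size in um/px; required when the file carries
#'   no resolution tags.
#' @param mask Optional logical mask matrix (defaults to full frame).
#' @return A [planar_image()].
#' @export
read_image <- function(path, pixel_size_um = NULL, mask = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  px <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE, info = TRUE))
  if (length(dim(px)) == 3L)
    stop(sprintf(paste0("%s has %d channels; expected a single-channel ",
                        "grayscale TIFF"), path, dim(px)[3]))
  tag_px <- tiff_pixel_size_um(attributes(px))
  if (is.null(pixel_size_um)) {
    if (is.null(tag_px))
      stop("no resolution tags in ", path,
           " and no `pixel_size_um` supplied")
    pixel_size_um <- tag_px
  } else if (!is.null(tag_px) &&
             abs(tag_px - pixel_size_um) > 1e-6 * pixel_size_um) {
    warning(sprintf(
      "pixel size %g um/px from configuration overrides %g um/px from %s",
      pixel_size_um, tag_px, path))
  }
  m <- matrix(as.numeric(px), nrow(px), ncol(px))
  planar_image(m, pixel_size_um, mask)
}

# resolution tags -> um/px (x resolution; pixels per unit)
tiff_pixel_size_um <- function(att) {
  if (is.null(att$x.resolution) || att$x.resolution <= 0) return(NULL)
  unit_um <- switch(as.character(att$resolution.unit %||% "inch"),
                    inch = 25400, cm = 10000, NULL)
  if (is.null(unit_um)) return(NULL)
  unit_um / att$x.resolution
}

#' Write a calibrated image as TIFF
#'
#' Integer modes store rounded intensities losslessly (values must fit the
#' bit depth), so an integer-valued image survives a write/read round trip
#' pixelwise; float mode stores 32-bit values. Resolution tags are not
#' written: the pixel size travels in the run configuration, which always
#' takes precedence on reading anyway.
#'
#' @param image A [planar_image()].
#' @param path Output path.
#' @param bits 8, 16 (integers) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  stopifnot(is_planar_image(image))
  px <- image$pixels
  if (bits %in% c(8L, 16L)) {
    top <- 2^bits - 1
    if (any(px < 0 | px > top))
      stop(sprintf("intensities outside [0, %d]; rescale before writing",
                   top))
    # half-offset defeats the writer's truncation; exact for integers
    tiff::writeTIFF(pmin((round(px) + 0.5) / top, 1), path,
                    bits.per.sample = bits, reduce = FALSE,
                    compression = "none")
  } else if (bits == 32L) {
    tiff::writeTIFF(px, path, bits.per.sample = 32L, reduce = FALSE,
                    compression = "none")
  } else stop("`bits` must be 8, 16 or 32")
  invisible(path)
}

#' Write a module label map as an 8-bit TIFF
#'
#' Quantile labels 1..n are stored as-is; 0 marks background.
#'
#' @param module_map A `module_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(module_map, path) {
  stopifnot(inherits(module_map, "module_map"))
  tiff::writeTIFF((module_map$quantile_label + 0.5) / 255, path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

validate_csv <- function(d, required, path) {
  miss <- setdiff(required, names(d))
  if (length(miss) > 0)
    stop(path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in required) {
    if (col %in% c("kind", "layer")) next
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "")
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value in column `%s` at data row %d",
                   path, col, bad[1]))
    d[[col]] <- v
  }
  d
}

#' Read / write labeled point tables
#'
#' Points interchange as UTF-8 comma-delimited CSV with columns `x_um`,
#' `y_um`, `section_index`, `kind` (`cell_body` or `apical_dendrite`);
#' unknown columns are preserved. A header-only file yields an empty set.
#'
#' @param path CSV path.
#' @return Data frame of points.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("no such points file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_csv(d, c("x_um", "y_um", "section_index", "kind"), path)
}

#' @rdname read_points
#' @param points Data frame with the required point columns.
#' @export
write_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Read / write landmark correspondence tables
#'
#' Landmarks interchange as CSV with columns `section_index`, `x_ref_um`,
#' `y_ref_um`, `x_sec_um`, `y_sec_um`: reference-frame and section-frame
#' coordinates of the same blood-vessel landmark.
#'
#' @param path CSV path.
#' @return Data frame of landmark pairs.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such landmarks file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_csv(d, c("section_index", "x_ref_um", "y_ref_um", "x_sec_um",
                    "y_sec_um"), path)
}

#' @rdname read_landmarks
#' @param landmarks Data frame with the required landmark columns.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML configuration for [run_pipeline()]. Paths are resolved relative to
#' the configuration file's directory. All physical quantities are in um.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("m2_image", "axon_image", "mask_image", "landmarks",
              "points", "out_dir")) {
    if (!is.null(cfg[[f]]) && !grepl("^(/|[A-Za-z]:)", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  cfg
}
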