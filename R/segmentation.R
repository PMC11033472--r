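#' Segmentation parameters for module delineation
#'
#' Bundles the tunable parameters of [delineate_modules()]. Defaults follow
#' the standard delineation recipe for M2 patch/interpatch maps: divide each
#' pixel by the mean intensity of a surrounding 100 um-radius disc, blur with
#' a 30 um-radius circular averaging filter, then partition the masked
#' intensities into 6 equal-count quantiles with the top 2 taken as M2+
#' patches and the bottom 2 as M2- interpatches.
#'
#' @param norm_radius_um Radius (um) of the local-mean disc used for
#'   normalization.
#' @param blur_radius_um Radius (um) of the circular averaging filter.
#' @param n_quantiles Number of equal-count intensity classes.
#' @param top_k Number of top quantiles forming the patch mask.
#' @param bottom_k Number of bottom quantiles forming the interpatch mask.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(norm_radius_um = 100, blur_radius_um = 30,
                                n_quantiles = 6L, top_k = 2L, bottom_k = 2L) {
  if (norm_radius_um <= 0 || blur_radius_um <= 0)
    stop("filter radii must be positive")
  n_quantiles <- as.integer(n_quantiles)
  top_k <- as.integer(top_k); bottom_k <- as.integer(bottom_k)
  if (n_quantiles < 2L) stop("`n_quantiles` must be >= 2")
  if (top_k < 1L || bottom_k < 1L || top_k + bottom_k > n_quantiles)
    stop("need top_k >= 1, bottom_k >= 1 and top_k + bottom_k <= n_quantiles")
  structure(list(norm_radius_um = norm_radius_um,
                 blur_radius_um = blur_radius_um,
                 n_quantiles = n_quantiles, top_k = top_k,
                 bottom_k = bottom_k),
            class = "segmentation_params")
}

# Disc structuring element: a pixel belongs to the disc iff its centre lies
# within `radius_px` (inclusive) of the disc centre.
disc_kernel <- function(radius_px) {
  r <- floor(radius_px)
  dx <- -r:r
  k <- outer(dx^2, dx^2, "+") <= radius_px^2
  storage.mode(k) <- "double"
  k
}

# Masked disc-mean filter (normalized convolution): at each pixel the mean
# of in-mask values over the disc. Zero-padded FFT convolution via EBImage.
disc_mean_filter <- function(image, radius_um) {
  radius_px <- radius_um / image$pixel_size_um
  if (radius_px < 1)
    stop(sprintf("filter radius %g um is below one pixel (%g um/px)",
                 radius_um, image$pixel_size_um))
  k <- disc_kernel(radius_px)
  m <- image$mask * 1
  num <- EBImage::filter2(image$pixels * m, k, boundary = 0)
  den <- EBImage::filter2(m, k, boundary = 0)
  out <- matrix(0, nrow(image$pixels), ncol(image$pixels))
  inm <- image$mask
  out[inm] <- num[inm] / den[inm]
  out <- pmax(out, 0)          # FFT round-off can leave ~ -1e-17
  list(values = out, disc_count = den)
}

#' Local-mean intensity normalization (high-pass)
#'
#' Divides each pixel by the average intensity of the surrounding disc
#' (default radius 100 um), computed over in-mask pixels only. This removes
#' smooth illumination and labeling-density gradients while preserving
#' structure at the module scale; it is the high-pass step of the
#' delineation recipe and is scale invariant (multiplying the input by any
#' k > 0 leaves the output unchanged).
#'
#' @param image A [planar_image()].
#' @param norm_radius_um Disc radius in um (default 100).
#' @return A `planar_image` of normalized intensities (masked identically).
#' @export
normalize_local <- function(image, norm_radius_um = 100) {
  stopifnot(is_planar_image(image))
  f <- disc_mean_filter(image, norm_radius_um)
  loc <- f$values
  bad <- image$mask & (!is.finite(loc) | loc <= 0)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stop(sprintf(paste0(
      "zero local mean inside mask at %d pixel(s) ",
      "(first at row %d, col %d): cannot normalize"),
      nrow(idx), idx[1, 1], idx[1, 2]))
  }
  out <- matrix(0, nrow(image$pixels), ncol(image$pixels))
  out[image$mask] <- image$pixels[image$mask] / loc[image$mask]
  planar_image(out, image$pixel_size_um, image$mask)
}

#' Circular averaging blur
#'
#' Replaces each pixel by the mean of the surrounding disc (default radius
#' 30 um) intersected with the mask. Idempotent on constant images; at
#' tissue edges the mean is taken over in-mask disc pixels only rather than
#' padding, so edge quantiles are not biased toward zero.
#'
#' @inheritParams normalize_local
#' @param blur_radius_um Disc radius in um (default 30).
#' @return A blurred `planar_image`.
#' @export
blur_circular <- function(image, blur_radius_um = 30) {
  stopifnot(is_planar_image(image))
  f <- disc_mean_filter(image, blur_radius_um)
  planar_image(f$values, image$pixel_size_um, image$mask)
}

#' Equal-count quantile partition of masked intensities
#'
#' Ranks the masked pixel values and cuts them into `n_quantiles` classes of
#' (as near as possible) equal pixel count, boundary ranks at
#' `i * N / n_quantiles`. Tied values are always assigned to the lower
#' quantile, so results are deterministic across platforms; the per-class
#' counts then deviate from `N / n_quantiles` by at most the number of
#' boundary ties. The top `top_k` classes form the patch mask and the bottom
#' `bottom_k` the interpatch mask.
#'
#' @inheritParams normalize_local
#' @param n_quantiles Number of classes (default 6).
#' @param top_k,bottom_k Classes counted as patches / interpatches.
#' @return A `module_map`: list with `quantile_label` (integer matrix, 0 =
#'   background), `n_quantiles`, `top_k`, `bottom_k`, `pixel_size_um`.
#' @export
quantile_partition <- function(image, n_quantiles = 6L, top_k = 2L,
                               bottom_k = 2L) {
  stopifnot(is_planar_image(image))
  n_quantiles <- as.integer(n_quantiles)
  v <- image$pixels[image$mask]
  if (length(unique(v)) < n_quantiles ||
      diff(range(v)) <= 1e-9 * max(abs(v), 1))
    stop(sprintf(paste0("degenerate partition: only %d distinct masked ",
                        "values (relative range %.2g) for %d quantiles"),
                 length(unique(v)), diff(range(v)) / max(abs(v), 1),
                 n_quantiles))
  n <- length(v)
  s <- sort(v)
  thr <- s[ceiling(seq_len(n_quantiles) * n / n_quantiles)]
  # label = smallest q with value <= threshold_q  (ties fall to lower q)
  lab_masked <- findInterval(v, thr[-n_quantiles], left.open = TRUE) + 1L
  lab <- matrix(0L, nrow(image$pixels), ncol(image$pixels))
  lab[image$mask] <- lab_masked
  structure(list(quantile_label = lab, n_quantiles = n_quantiles,
                 top_k = as.integer(top_k), bottom_k = as.integer(bottom_k),
                 pixel_size_um = image$pixel_size_um),
            class = "module_map")
}

#' @export
print.module_map <- function(x, ...) {
  n <- sum(x$quantile_label > 0L)
  cat(sprintf(
    "module_map: %d quantiles over %d px at %g um/px; patch %d px, interpatch %d px\n",
    x$n_quantiles, n, x$pixel_size_um,
    sum(patch_mask(x)), sum(interpatch_mask(x))))
  invisible(x)
}

#' Patch / interpatch / middle masks of a module map
#'
#' @param module_map A `module_map` from [quantile_partition()] or
#'   [delineate_modules()].
#' @return Logical matrix selecting pixels in the top `top_k` quantiles
#'   (patches), bottom `bottom_k` quantiles (interpatches), or the remaining
#'   middle quantiles.
#' @export
patch_mask <- function(module_map) {
  module_map$quantile_label >= module_map$n_quantiles - module_map$top_k + 1L
}

#' @rdname patch_mask
#' @export
interpatch_mask <- function(module_map) {
  lab <- module_map$quantile_label
  lab >= 1L & lab <= module_map$bottom_k
}

#' @rdname patch_mask
#' @export
middle_mask <- function(module_map) {
  lab <- module_map$quantile_label
  lab > module_map$bottom_k &
    lab < module_map$n_quantiles - module_map$top_k + 1L
}

#' Delineate M2+ patches and M2- interpatches
#'
#' Full delineation recipe: local-mean normalization (high-pass), circular
#' averaging blur, then equal-count quantile partition of the masked
#' intensities, with the top quantiles labeled patches and the bottom
#' quantiles interpatches. The result is invariant to global rescaling of
#' the input intensities.
#'
#' @inheritParams normalize_local
#' @param params A [segmentation_params()] bundle.
#' @return A `module_map`.
#' @export
delineate_modules <- function(image, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  img <- normalize_local(image, params$norm_radius_um)
  img <- blur_circular(img, params$blur_radius_um)
  quantile_partition(img, params$n_quantiles, params$top_k, params$bottom_k)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical matrices of equal dimension.
#' @return `2 |a & b| / (|a| + |b|)`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
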