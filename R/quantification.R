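#' Locate the injection centre from the saturated core
#'
#' The injection core is intensely fluorescent, so its centre is estimated
#' as the intensity-weighted centroid of pixels at or above a high intensity
#' quantile of the masked values. The core radius is an analysis choice
#' supplied by the caller, not estimated.
#'
#' @param image A `planar_image` of the tracer channel.
#' @param saturation_quantile Quantile of masked intensities defining the
#'   saturated set (default 0.999).
#' @param core_radius_um Core radius to record on the returned site.
#' @return An [injection_site()].
#' @export
detect_injection_center <- function(image, saturation_quantile = 0.999,
                                    core_radius_um = 200) {
  stopifnot(is_planar_image(image))
  v <- image$pixels[image$mask]
  thr <- stats::quantile(v, saturation_quantile, names = FALSE, type = 7)
  sel <- image$mask & image$pixels >= thr
  if (!any(sel)) stop("no pixels at or above the saturation quantile")
  xy <- pixel_coords_um(image)
  w <- image$pixels[sel]
  injection_site(c(sum(xy$x[sel] * w), sum(xy$y[sel] * w)) / sum(w),
                 core_radius_um)
}

#' Place rectangular ROIs inside the analysis mask
#'
#' Draws `n` axis-aligned, non-overlapping rectangles fully inside the mask
#' (every covered pixel in-mask), optionally avoiding a disc around the
#' injection core, by seeded rejection sampling. The standard analysis uses
#' 550 x 400 um ROIs, 3 per section.
#'
#' @param image A `planar_image` (only its geometry and mask are used) or a
#'   `module_map`.
#' @param n Number of ROIs.
#' @param width_um,height_um ROI extent in um (defaults 550 x 400).
#' @param seed Integer RNG seed.
#' @param avoid_center_xy_um,avoid_radius_um Optional exclusion disc (e.g.
#'   the injection core): no ROI pixel may fall inside it.
#' @param max_tries Rejection-sampling budget before giving up.
#' @return Data frame with `roi`, `x_um`, `y_um` (lower corner), `width_um`,
#'   `height_um`.
#' @export
place_rois <- function(image, n = 3, width_um = 550, height_um = 400,
                       seed = 1, avoid_center_xy_um = NULL,
                       avoid_radius_um = 0, max_tries = 5000) {
  if (inherits(image, "module_map")) {
    mask <- image$quantile_label > 0L
    px <- image$pixel_size_um
  } else {
    mask <- image$mask
    px <- image$pixel_size_um
  }
  d <- dim(mask)
  wmax <- (d[2] - 1) * px - width_um
  hmax <- (d[1] - 1) * px - height_um
  if (wmax < 0 || hmax < 0) stop("ROI does not fit inside the field")
  set.seed(sub_seed(seed, 6))
  out <- data.frame(roi = integer(0), x_um = numeric(0), y_um = numeric(0),
                    width_um = numeric(0), height_um = numeric(0))
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    tries <- tries + 1
    x0 <- stats::runif(1, 0, wmax)
    y0 <- stats::runif(1, 0, hmax)
    # overlap with accepted ROIs?
    if (nrow(out) > 0 &&
        any(x0 < out$x_um + out$width_um & x0 + width_um > out$x_um &
            y0 < out$y_um + out$height_um & y0 + height_um > out$y_um))
      next
    sel <- roi_pixel_mask(d, px, x0, y0, width_um, height_um)
    if (!all(mask[sel])) next
    if (!is.null(avoid_center_xy_um) && avoid_radius_um > 0) {
      xy <- list(
        x = matrix((seq_len(d[2]) - 1) * px, d[1], d[2], byrow = TRUE),
        y = matrix((seq_len(d[1]) - 1) * px, d[1], d[2]))
      dist2 <- (xy$x[sel] - avoid_center_xy_um[1])^2 +
        (xy$y[sel] - avoid_center_xy_um[2])^2
      if (any(dist2 <= avoid_radius_um^2)) next
    }
    out <- rbind(out, data.frame(roi = nrow(out) + 1L, x_um = x0, y_um = y0,
                                 width_um = width_um, height_um = height_um))
  }
  if (nrow(out) < n)
    stop(sprintf("could only place %d of %d ROIs in %d tries",
                 nrow(out), n, max_tries))
  out
}

# logical matrix of pixel centres covered by one ROI rectangle
roi_pixel_mask <- function(dim, px, x0, y0, w, h) {
  cols <- (seq_len(dim[2]) - 1) * px
  rows <- (seq_len(dim[1]) - 1) * px
  outer(rows >= y0 & rows < y0 + h, cols >= x0 & cols < x0 + w, "&")
}

#' Per-quantile ROI optical density
#'
#' For each ROI, groups the in-mask pixels of the signal image by their
#' module-map quantile label and reports the mean intensity (optical
#' density) and pixel count per quantile; quantiles absent from an ROI are
#' reported as missing (`NA` mean, zero count), never as zero density. A
#' summary table aggregates the per-ROI means into mean +/- SEM per
#' quantile across ROIs.
#'
#' @param signal A `planar_image`, co-registered with `module_map`.
#' @param module_map A `module_map` on the same grid.
#' @param rois ROI table from [place_rois()] (or with the same columns).
#' @return List of class `quantile_density` with `per_roi` and `summary`
#'   data frames.
#' @export
roi_quantile_density <- function(signal, module_map, rois) {
  stopifnot(is_planar_image(signal), inherits(module_map, "module_map"))
  if (!identical(dim(signal$pixels), dim(module_map$quantile_label)))
    stop("signal and module map are not on the same grid")
  d <- dim(signal$pixels)
  px <- signal$pixel_size_um
  nq <- module_map$n_quantiles
  per <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
    sel <- roi_pixel_mask(d, px, rois$x_um[i], rois$y_um[i],
                          rois$width_um[i], rois$height_um[i]) &
      signal$mask & module_map$quantile_label > 0L
    lab <- module_map$quantile_label[sel]
    val <- signal$pixels[sel]
    cnt <- tabulate(lab, nbins = nq)
    mu <- rep(NA_real_, nq)
    if (length(val) > 0) {
      sums <- vapply(seq_len(nq), function(q) sum(val[lab == q]), 0)
      mu[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
    }
    data.frame(roi = rois$roi[i], quantile = seq_len(nq),
               mean_intensity = mu, pixel_count = cnt)
  }))
  summ <- do.call(rbind, lapply(seq_len(nq), function(q) {
    m <- per$mean_intensity[per$quantile == q]
    m <- m[is.finite(m)]
    data.frame(quantile = q, mean = mean(m),
               sem = stats::sd(m) / sqrt(length(m)), n_roi = length(m))
  }))
  structure(list(per_roi = per, summary = summ), class = "quantile_density")
}

#' Per-ROI patch and interpatch mean intensities
#'
#' The sampling units of the patch-vs-interpatch comparison: for each ROI
#' the mean signal over its patch pixels and over its interpatch pixels
#' (disjoint pixel sets). ROIs lacking either class yield `NA`.
#'
#' @inheritParams roi_quantile_density
#' @return Data frame with `roi`, `patch_mean`, `interpatch_mean`.
#' @export
roi_class_means <- function(signal, module_map, rois) {
  stopifnot(is_planar_image(signal), inherits(module_map, "module_map"))
  d <- dim(signal$pixels)
  px <- signal$pixel_size_um
  pm <- patch_mask(module_map)
  im <- interpatch_mask(module_map)
  do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
    sel <- roi_pixel_mask(d, px, rois$x_um[i], rois$y_um[i],
                          rois$width_um[i], rois$height_um[i]) & signal$mask
    data.frame(
      roi = rois$roi[i],
      patch_mean = if (any(sel & pm)) mean(signal$pixels[sel & pm]) else NA,
      interpatch_mean =
        if (any(sel & im)) mean(signal$pixels[sel & im]) else NA)
  }))
}

#' Module-conditioned radial density profile
#'
#' Bins the field (or point set) into concentric annuli around the
#' injection centre, starting at the core-exclusion radius (the intensely
#' fluorescent core is discounted; 250 um for axon densities and 300 um --
#' a 600 um-wide core -- for labeled-point densities are the standard
#' choices), and reports for each annulus and module class (patch,
#' interpatch) the density: signal sum, or point count, divided by the
#' class area within the annulus. Both class curves are divided by one
#' shared constant, the joint maximum, so the global peak equals 1. When a
#' list of replicate signals (or a `subject` column on points) is supplied,
#' per-bin SEM across replicates is computed on the normalized densities. A
#' 3-bin moving-average `smoothed` column is provided for display; all
#' statistics use the raw bins.
#'
#' @param x A `planar_image`, a list of replicate `planar_image`s, or a
#'   point data frame with `x_um`/`y_um` (optionally `subject`).
#' @param module_map Module map on the reference grid.
#' @param center_xy_um Injection centre, um.
#' @param bin_width_um Annulus width (default 50 um).
#' @param exclusion_radius_um Core exclusion radius (default 250 um).
#' @param max_radius_um Outer limit; defaults to the largest masked radius.
#' @return Data frame of class `radial_profile`: `bin_lo_um`, `bin_hi_um`,
#'   `bin_mid_um`, `class`, `area_um2`, `density`, `density_norm`, `sem`,
#'   `smoothed`. Annuli where a class has zero area carry `NA` density
#'   (flagged missing, not zero).
#' @export
radial_density_profile <- function(x, module_map, center_xy_um,
                                   bin_width_um = 50,
                                   exclusion_radius_um = 250,
                                   max_radius_um = NULL) {
  stopifnot(inherits(module_map, "module_map"))
  if (exclusion_radius_um < 0) stop("exclusion radius must be >= 0")
  d <- dim(module_map$quantile_label)
  px <- module_map$pixel_size_um
  analysis_mask <- module_map$quantile_label > 0L
  xy <- list(
    x = matrix((seq_len(d[2]) - 1) * px, d[1], d[2], byrow = TRUE),
    y = matrix((seq_len(d[1]) - 1) * px, d[1], d[2]))
  if (center_xy_um[1] < 0 || center_xy_um[1] > (d[2] - 1) * px ||
      center_xy_um[2] < 0 || center_xy_um[2] > (d[1] - 1) * px)
    stop("injection centre lies outside the analysis frame")
  r_pix <- sqrt((xy$x - center_xy_um[1])^2 + (xy$y - center_xy_um[2])^2)
  if (is.null(max_radius_um)) max_radius_um <- max(r_pix[analysis_mask])
  edges <- seq(exclusion_radius_um, max_radius_um, by = bin_width_um)
  if (length(edges) < 2) stop("no annuli between exclusion and max radius")
  nb <- length(edges) - 1
  classes <- list(patch = patch_mask(module_map),
                  interpatch = interpatch_mask(module_map))
  bin_of_pix <- findInterval(r_pix, edges, rightmost.closed = FALSE)
  bin_of_pix[bin_of_pix < 1 | bin_of_pix > nb | !analysis_mask] <- NA

  area_tab <- sapply(classes, function(cm) {
    a <- tabulate(bin_of_pix[cm & !is.na(bin_of_pix)], nbins = nb)
    a * px^2
  })

  sum_one <- function(obj) {
    if (is_planar_image(obj)) {
      if (!identical(dim(obj$pixels), d))
        stop("signal and module map are not on the same grid")
      sapply(classes, function(cm) {
        sel <- cm & obj$mask & !is.na(bin_of_pix)
        vapply(seq_len(nb), function(b)
          sum(obj$pixels[sel & bin_of_pix == b]), 0)
      })
    } else {
      rc <- points_to_pixels(obj$x_um, obj$y_um, d, px)
      ok <- !is.na(rc[, 1])
      r_pt <- sqrt((obj$x_um - center_xy_um[1])^2 +
                     (obj$y_um - center_xy_um[2])^2)
      b_pt <- findInterval(r_pt, edges, rightmost.closed = FALSE)
      lab <- rep(0L, length(r_pt))
      lab[ok] <- module_map$quantile_label[rc[ok, , drop = FALSE]]
      sapply(seq_along(classes), function(ci) {
        inc <- if (ci == 1)
          lab >= module_map$n_quantiles - module_map$top_k + 1L
        else lab >= 1L & lab <= module_map$bottom_k
        vapply(seq_len(nb), function(b)
          sum(inc & b_pt == b, na.rm = TRUE), 0L) * 1.0
      })
    }
  }

  reps <- if (is_planar_image(x)) {
    list(sum_one(x))
  } else if (is.data.frame(x)) {
    if (!is.null(x$subject)) {
      lapply(split(x, x$subject), sum_one)
    } else list(sum_one(x))
  } else if (is.list(x)) {
    lapply(x, sum_one)
  } else stop("`x` must be a planar_image, list of them, or a point table")

  dens_reps <- lapply(reps, function(s) {
    dns <- s / area_tab
    dns[area_tab == 0] <- NA
    dns
  })
  dens <- Reduce(`+`, lapply(dens_reps, function(z) {
    z[is.na(z)] <- 0; z
  })) / Reduce(`+`, lapply(dens_reps, function(z) !is.na(z) * 1))
  dens[!is.finite(dens)] <- NA
  norm_const <- suppressWarnings(max(dens, na.rm = TRUE))
  # an empty pattern (e.g. all points inside the exclusion radius) keeps
  # its all-zero bins rather than failing the joint normalization
  if (!is.finite(norm_const) || norm_const <= 0) norm_const <- 1
  dens_norm <- dens / norm_const
  sem <- if (length(dens_reps) > 1) {
    arr <- simplify2array(lapply(dens_reps, function(z) z / norm_const))
    apply(arr, c(1, 2), function(v)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))))
  } else matrix(NA_real_, nb, 2)

  smooth3 <- function(v) {
    stats::filter(v, rep(1 / 3, 3), sides = 2)
  }
  out <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    data.frame(bin_lo_um = edges[-(nb + 1)], bin_hi_um = edges[-1],
               bin_mid_um = (edges[-1] + edges[-(nb + 1)]) / 2,
               class = names(classes)[ci], area_um2 = area_tab[, ci],
               density = dens[, ci], density_norm = dens_norm[, ci],
               sem = sem[, ci],
               smoothed = as.numeric(smooth3(dens_norm[, ci])))
  }))
  attr(out, "normalization_constant") <- norm_const
  attr(out, "exclusion_radius_um") <- exclusion_radius_um
  attr(out, "bin_width_um") <- bin_width_um
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Estimate the interpatch/patch preference ratio from a radial profile
#'
#' Distance-controlled preference estimate: the mean over annuli of the
#' per-annulus interpatch/patch density ratio, weighted by the smaller of
#' the two class areas (bins where either class is missing are skipped).
#' Under the planted-field model this recovers the generative `rho`.
#'
#' @param profile A [radial_density_profile()].
#' @return Scalar ratio estimate.
#' @export
estimate_preference_ratio <- function(profile) {
  p <- profile[profile$class == "patch", ]
  i <- profile[profile$class == "interpatch", ]
  ok <- is.finite(p$density) & is.finite(i$density) & p$density > 0
  if (!any(ok)) stop("no annulus has both classes present")
  w <- pmin(p$area_um2[ok], i$area_um2[ok])
  sum(w * i$density[ok] / p$density[ok]) / sum(w)
}

#' Assign module classes to labeled points
#'
#' Looks up each point's module-map quantile at the nearest pixel (points
#' must already be registered to the map's frame) and adds a `module`
#' column: `patch`, `interpatch`, `middle`, or `background` for points off
#' the analysis mask or outside the frame.
#'
#' @param points Data frame with `x_um`, `y_um`.
#' @param module_map A `module_map`.
#' @return `points` with a `module` factor column added.
#' @export
assign_point_modules <- function(points, module_map) {
  stopifnot(inherits(module_map, "module_map"))
  d <- dim(module_map$quantile_label)
  rc <- points_to_pixels(points$x_um, points$y_um, d,
                         module_map$pixel_size_um)
  lab <- rep(0L, nrow(points))
  ok <- !is.na(rc[, 1])
  lab[ok] <- module_map$quantile_label[rc[ok, , drop = FALSE]]
  mod <- rep("background", nrow(points))
  mod[lab >= 1L & lab <= module_map$bottom_k] <- "interpatch"
  mod[lab >= module_map$n_quantiles - module_map$top_k + 1L] <- "patch"
  mod[lab > module_map$bottom_k &
        lab < module_map$n_quantiles - module_map$top_k + 1L] <- "middle"
  points$module <- factor(mod,
                          levels = c("patch", "interpatch", "middle",
                                     "background"))
  points
}

#' Point densities per module class
#'
#' Counts points per module class inside each ROI and divides by the class
#' area within the ROI, in points per mm^2; also reports the pooled
#' patch/interpatch density ratio (and per-layer ratios when a `layer`
#' column is present).
#'
#' @param points Data frame with `x_um`, `y_um` (optionally `layer`),
#'   registered to the module map's frame.
#' @param module_map A `module_map`.
#' @param rois ROI table from [place_rois()]; `NULL` treats the whole
#'   analysis mask as a single ROI.
#' @return List of class `point_density` with `per_roi` (data frame),
#'   `ratio` (pooled patch/interpatch), and `by_layer` (or `NULL`).
#' @export
point_module_density <- function(points, module_map, rois = NULL) {
  stopifnot(inherits(module_map, "module_map"))
  d <- dim(module_map$quantile_label)
  px <- module_map$pixel_size_um
  if (is.null(rois)) {
    rois <- data.frame(roi = 1L, x_um = 0, y_um = 0,
                       width_um = d[2] * px, height_um = d[1] * px)
  }
  pts <- assign_point_modules(points, module_map)
  pm <- patch_mask(module_map); im <- interpatch_mask(module_map)
  per <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
    sel <- roi_pixel_mask(d, px, rois$x_um[i], rois$y_um[i],
                          rois$width_um[i], rois$height_um[i])
    a_p <- sum(sel & pm) * px^2 / 1e6   # mm^2
    a_i <- sum(sel & im) * px^2 / 1e6
    inroi <- pts$x_um >= rois$x_um[i] &
      pts$x_um < rois$x_um[i] + rois$width_um[i] &
      pts$y_um >= rois$y_um[i] &
      pts$y_um < rois$y_um[i] + rois$height_um[i]
    n_p <- sum(inroi & pts$module == "patch")
    n_i <- sum(inroi & pts$module == "interpatch")
    data.frame(roi = rois$roi[i], patch_area_mm2 = a_p,
               interpatch_area_mm2 = a_i, patch_n = n_p, interpatch_n = n_i,
               patch_density = if (a_p > 0) n_p / a_p else NA_real_,
               interpatch_density = if (a_i > 0) n_i / a_i else NA_real_)
  }))
  if (sum(per$interpatch_area_mm2) <= 0)
    stop("zero interpatch area: patch/interpatch ratio undefined")
  ratio <- (sum(per$patch_n) / sum(per$patch_area_mm2)) /
    (sum(per$interpatch_n) / sum(per$interpatch_area_mm2))
  by_layer <- NULL
  if (!is.null(points$layer)) {
    by_layer <- do.call(rbind, lapply(split(pts, points$layer), function(s) {
      data.frame(layer = s$layer[1],
                 patch_n = sum(s$module == "patch"),
                 interpatch_n = sum(s$module == "interpatch"))
    }))
    a_p <- sum(per$patch_area_mm2); a_i <- sum(per$interpatch_area_mm2)
    by_layer$patch_density <- by_layer$patch_n / a_p
    by_layer$interpatch_density <- by_layer$interpatch_n / a_i
    by_layer$ratio <- by_layer$patch_density / by_layer$interpatch_density
    rownames(by_layer) <- NULL
  }
  structure(list(per_roi = per, ratio = ratio, by_layer = by_layer),
            class = "point_density")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the patch and interpatch sample distributions with the
#' two-sample KS statistic (the supremum difference of the empirical CDFs).
#' The p-value is computed exactly when both samples have at most 25
#' observations and from the asymptotic KS distribution otherwise.
#'
#' @param sample_patch,sample_interpatch Numeric vectors (non-empty; NAs
#'   dropped).
#' @param alpha Nominal test level used for the `reject` flag.
#' @return List of class `ks_comparison`: `statistic`, `p_value`, `n_patch`,
#'   `n_interpatch`, `alpha`, `reject`.
#' @export
ks_compare <- function(sample_patch, sample_interpatch, alpha = 0.05) {
  a <- sample_patch[is.finite(sample_patch)]
  b <- sample_interpatch[is.finite(sample_interpatch)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  exact <- length(a) <= 25 && length(b) <= 25
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n_patch = length(a), n_interpatch = length(b),
                 alpha = alpha, reject = unname(kt$p.value) <= alpha),
            class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf(
    "KS comparison: D = %.4f, p = %.3g (n = %d vs %d)%s\n",
    x$statistic, x$p_value, x$n_patch, x$n_interpatch,
    if (x$reject) sprintf(" *reject at alpha = %g*", x$alpha) else ""))
  invisible(x)
}

#' Anisotropy aspect ratio from second moments
#'
#' Measures the elongation of a labeled field (or point cloud) as the
#' square root of the ratio of the major to minor eigenvalue of the
#' intensity-weighted second central moment matrix, computed over pixels at
#' or above an intensity quantile (points are unweighted). The ratio is
#' invariant to rotation (up to discretization) and to uniform intensity
#' scaling; the major-axis angle is reported in degrees from +x in
#' [0, 180).
#'
#' @param x A `planar_image` or a point data frame with `x_um`, `y_um`.
#' @param intensity_quantile Quantile of masked intensities defining the
#'   super-threshold set (images only; default 0.75).
#' @return List of class `anisotropy_result`: `aspect_ratio` (>= 1),
#'   `angle_deg`, `eigenvalues`, `n`.
#' @export
anisotropy_aspect_ratio <- function(x, intensity_quantile = 0.75) {
  if (is_planar_image(x)) {
    v <- x$pixels[x$mask]
    thr <- stats::quantile(v, intensity_quantile, names = FALSE)
    sel <- x$mask & x$pixels >= thr
    if (sum(sel) < 3) stop("fewer than 3 super-threshold pixels")
    xy <- pixel_coords_um(x)
    px_x <- xy$x[sel]; px_y <- xy$y[sel]; w <- x$pixels[sel]
  } else {
    if (nrow(x) < 3) stop("fewer than 3 points")
    px_x <- x$x_um; px_y <- x$y_um; w <- rep(1, nrow(x))
  }
  w <- w / sum(w)
  mx <- sum(w * px_x); my <- sum(w * px_y)
  cxx <- sum(w * (px_x - mx)^2)
  cyy <- sum(w * (px_y - my)^2)
  cxy <- sum(w * (px_x - mx) * (px_y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * ev$values[1])
    stop("degenerate (collinear) support: minor moment is ~0")
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  structure(list(aspect_ratio = sqrt(ev$values[1] / ev$values[2]),
                 angle_deg = ang %% 180,
                 eigenvalues = ev$values, n = length(px_x)),
            class = "anisotropy_result")
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("anisotropy: aspect ratio %.3f, major axis %.1f deg (n = %d)\n",
              x$aspect_ratio, x$angle_deg, x$n))
  invisible(x)
}
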