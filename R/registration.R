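#' Planar projective (homography) transform
#'
#' An invertible 3x3 homogeneous matrix acting on physical (um) coordinates,
#' normalized so that the lower-right element equals 1. Used to undo the
#' section-to-section distortion introduced by cutting and mounting
#' tangential sections; fitted from blood-vessel landmark correspondences by
#' [fit_projective()].
#'
#' @param matrix A 3x3 invertible numeric matrix.
#' @param residual_rms_um Optional fit residual (RMS, um) carried along for
#'   reporting.
#' @return An object of class `projective_transform`.
#' @export
projective_transform <- function(matrix, residual_rms_um = NA_real_) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(3L, 3L)) ||
      any(!is.finite(matrix)))
    stop("`matrix` must be a finite 3x3 matrix")
  if (abs(matrix[3, 3]) < 1e-12)
    stop("degenerate homography: lower-right element is ~0")
  m <- matrix / matrix[3, 3]
  rc <- rcond(m)
  if (!is.finite(rc) || rc < 1e-12)
    stop(sprintf("homography is numerically singular (rcond = %g)", rc))
  structure(list(matrix = m, residual_rms_um = residual_rms_um),
            class = "projective_transform")
}

#' @export
print.projective_transform <- function(x, ...) {
  cat("projective_transform (um frame)\n")
  print(signif(x$matrix, 6))
  if (is.finite(x$residual_rms_um))
    cat(sprintf("fit residual RMS: %.4g um\n", x$residual_rms_um))
  invisible(x)
}

#' @rdname projective_transform
#' @export
identity_transform <- function() projective_transform(diag(3))

#' Invert / compose projective transforms
#'
#' @param transform,a,b `projective_transform` objects; `compose_transforms`
#'   returns the map applying `b` first, then `a`.
#' @return A `projective_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "projective_transform"))
  projective_transform(solve(transform$matrix))
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "projective_transform"),
            inherits(b, "projective_transform"))
  projective_transform(a$matrix %*% b$matrix)
}

#' Fit a homography to landmark correspondences
#'
#' Estimates the projective transform mapping section-frame coordinates onto
#' the reference (L1) frame from >= 4 landmark pairs, using the normalized
#' direct linear transform: both point sets are conditioned to zero mean and
#' unit RMS, the 9-parameter system is solved by SVD, and the conditioning
#' is undone. Exact for 4 non-degenerate pairs, least-squares for more. The
#' returned object carries the RMS residual (um) of the mapped section
#' landmarks against the reference landmarks.
#'
#' @param landmarks Data frame with columns `x_ref_um`, `y_ref_um`,
#'   `x_sec_um`, `y_sec_um` (one row per landmark pair), e.g. from
#'   [read_landmarks()].
#' @return A `projective_transform` mapping section -> reference coordinates.
#' @export
fit_projective <- function(landmarks) {
  req <- c("x_ref_um", "y_ref_um", "x_sec_um", "y_sec_um")
  miss <- setdiff(req, names(landmarks))
  if (length(miss) > 0)
    stop("landmarks are missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(landmarks)
  if (n < 4)
    stop(sprintf("projective fit is underdetermined: %d landmark pair(s), need >= 4", n))
  ref <- cbind(landmarks$x_ref_um, landmarks$y_ref_um)
  sec <- cbind(landmarks$x_sec_um, landmarks$y_sec_um)
  if (any(!is.finite(ref)) || any(!is.finite(sec)))
    stop("landmark coordinates must be finite")

  cond <- function(p) {
    ctr <- colMeans(p)
    q <- sweep(p, 2, ctr)
    s <- sqrt(mean(rowSums(q^2)))
    if (s < 1e-9) stop("degenerate landmark configuration: points coincide")
    t <- diag(3); t[1, 1] <- t[2, 2] <- sqrt(2) / s
    t[1, 3] <- -ctr[1] * sqrt(2) / s; t[2, 3] <- -ctr[2] * sqrt(2) / s
    list(t = t, p = cbind(q * sqrt(2) / s, 1))
  }
  cr <- cond(ref); cs <- cond(sec)
  a <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- cs$p[i, ]; u <- cr$p[i, 1]; v <- cr$p[i, 2]
    a[2 * i - 1, ] <- c(-x, 0, 0, 0, u * x)
    a[2 * i, ] <- c(0, 0, 0, -x, v * x)
  }
  sv <- svd(a, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-10)
    stop("degenerate landmark configuration: homography is not identifiable")
  h <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  m <- solve(cr$t) %*% h %*% cs$t
  tf <- projective_transform(m)
  mapped <- apply_transform(tf, sec)
  tf$residual_rms_um <- sqrt(mean(rowSums((mapped - ref)^2)))
  tf
}

#' Apply a projective transform to points or an image
#'
#' For an `n x 2` matrix or a data frame with `x_um`/`y_um` columns, maps the
#' points exactly through the homography. For a [planar_image()], resamples
#' the image onto the reference grid by inverse mapping with bilinear
#' interpolation (the mask is transported nearest-neighbor); reference
#' pixels that map outside the source frame become background (0 intensity,
#' mask `FALSE`).
#'
#' @param transform A `projective_transform` (section -> reference).
#' @param x Points (matrix or data frame) in the transform's source frame,
#'   or a `planar_image` in the source frame.
#' @param out_dim Output grid dimension `c(rows, cols)` for image
#'   resampling; defaults to the input dimension.
#' @param out_pixel_size_um Output pixel size; defaults to the input's.
#' @return Transformed points (same container as supplied) or a resampled
#'   `planar_image` in the reference frame.
#' @export
apply_transform <- function(transform, x, out_dim = NULL,
                            out_pixel_size_um = NULL) {
  stopifnot(inherits(transform, "projective_transform"))
  if (is_planar_image(x))
    return(warp_image(transform, x, out_dim, out_pixel_size_um))
  if (is.data.frame(x)) {
    if (!all(c("x_um", "y_um") %in% names(x)))
      stop("point data frame needs `x_um` and `y_um` columns")
    p <- map_points(transform$matrix, cbind(x$x_um, x$y_um))
    x$x_um <- p[, 1]; x$y_um <- p[, 2]
    return(x)
  }
  if (is.matrix(x) && ncol(x) == 2) return(map_points(transform$matrix, x))
  stop("`x` must be a planar_image, an n x 2 matrix, or a data frame")
}

map_points <- function(m, p) {
  h <- m %*% rbind(t(p), 1)
  w <- h[3, ]
  if (any(abs(w) < 1e-12)) stop("point maps to infinity under the homography")
  cbind(h[1, ] / w, h[2, ] / w)
}

warp_image <- function(transform, image, out_dim = NULL,
                       out_pixel_size_um = NULL) {
  if (is.null(out_dim)) out_dim <- dim(image$pixels)
  if (is.null(out_pixel_size_um)) out_pixel_size_um <- image$pixel_size_um
  inv <- solve(transform$matrix)
  px_out <- out_pixel_size_um
  px_in <- image$pixel_size_um
  grid <- expand.grid(row = seq_len(out_dim[1]), col = seq_len(out_dim[2]))
  src <- map_points(inv, cbind((grid$col - 1) * px_out,
                               (grid$row - 1) * px_out))
  # fractional source pixel indices
  sc <- src[, 1] / px_in + 1
  sr <- src[, 2] / px_in + 1
  d <- dim(image$pixels)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inside <- r0 >= 1 & c0 >= 1 & r0 + 1 <= d[1] & c0 + 1 <= d[2]
  val <- numeric(nrow(grid))
  at <- function(r, c) image$pixels[cbind(r, c)]
  i <- which(inside)
  val[i] <- (1 - fr[i]) * (1 - fc[i]) * at(r0[i], c0[i]) +
    (1 - fr[i]) * fc[i] * at(r0[i], c0[i] + 1) +
    fr[i] * (1 - fc[i]) * at(r0[i] + 1, c0[i]) +
    fr[i] * fc[i] * at(r0[i] + 1, c0[i] + 1)
  # nearest-neighbor mask transport
  rn <- round(sr); cn <- round(sc)
  okn <- rn >= 1 & cn >= 1 & rn <= d[1] & cn <= d[2]
  msk <- logical(nrow(grid))
  msk[okn] <- image$mask[cbind(rn[okn], cn[okn])]
  out <- matrix(0, out_dim[1], out_dim[2])
  out[cbind(grid$row, grid$col)] <- val
  outm <- matrix(FALSE, out_dim[1], out_dim[2])
  outm[cbind(grid$row, grid$col)] <- msk & inside
  planar_image(out, px_out, outm)
}

#' Section-to-layer lookup table
#'
#' Maps the index of a 40 um tangential section to a cortical layer label.
#' The default table reflects PV/Ctip2-calibrated flatmount sectioning:
#' sections 1-2 contain L1, 3-7 L2-4, 8-12 L5 and 13-16 L6.
#'
#' @param table Data frame with columns `first`, `last`, `layer` giving
#'   contiguous, non-overlapping 1-based section ranges.
#' @return The validated table, class `layer_assignment`.
#' @export
layer_assignment <- function(table = data.frame(
  first = c(1L, 3L, 8L, 13L),
  last = c(2L, 7L, 12L, 16L),
  layer = c("L1", "L2-4", "L5", "L6"))) {
  stopifnot(all(c("first", "last", "layer") %in% names(table)))
  o <- order(table$first)
  table <- table[o, , drop = FALSE]
  if (any(table$last < table$first))
    stop("layer table ranges must have last >= first")
  if (nrow(table) > 1 &&
      any(table$first[-1] <= table$last[-nrow(table)]))
    stop("layer table ranges must not overlap")
  structure(table, class = c("layer_assignment", "data.frame"))
}

#' Assign cortical layers to section indices
#'
#' Total function: indices beyond the table map to `"unknown"`.
#'
#' @param section_index Integer vector of section indices (>= 1).
#' @param assignment A [layer_assignment()] table.
#' @return Character vector of layer labels.
#' @export
assign_layer <- function(section_index, assignment = layer_assignment()) {
  if (any(section_index < 1, na.rm = TRUE))
    stop("section indices must be >= 1")
  out <- rep("unknown", length(section_index))
  for (i in seq_len(nrow(assignment))) {
    hit <- !is.na(section_index) &
      section_index >= assignment$first[i] &
      section_index <= assignment$last[i]
    out[hit] <- assignment$layer[i]
  }
  out
}

#' Propagate the L1 module map to deeper sections
#'
#' Transports patch/interpatch quantile labels from the reference (L1) frame
#' into each section's own frame using the inverse of that section's fitted
#' transform, with nearest-neighbor lookup so labels never blend. A section
#' pixel whose reference position falls outside the reference map becomes
#' background (label 0).
#'
#' @param module_map The reference-frame `module_map` (from L1).
#' @param transforms Named or indexed list of `projective_transform`s
#'   (section -> reference), one per section.
#' @param section_dims Optional list of `c(rows, cols)` per section;
#'   defaults to the reference map's dimension.
#' @return A list of `module_map`s, one per section, in section frames.
#' @export
propagate_modules <- function(module_map, transforms, section_dims = NULL) {
  stopifnot(inherits(module_map, "module_map"))
  bad <- which(!vapply(transforms, inherits, logical(1),
                       "projective_transform"))
  if (length(bad) > 0)
    stop("missing or invalid transform for section(s): ",
         paste(bad, collapse = ", "))
  ref_dim <- dim(module_map$quantile_label)
  px <- module_map$pixel_size_um
  lapply(seq_along(transforms), function(k) {
    tf <- transforms[[k]]
    d <- if (is.null(section_dims)) ref_dim else section_dims[[k]]
    grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
    ref <- map_points(tf$matrix, cbind((grid$col - 1) * px,
                                       (grid$row - 1) * px))
    rc <- points_to_pixels(ref[, 1], ref[, 2], ref_dim, px)
    lab <- integer(nrow(grid))
    ok <- !is.na(rc[, 1])
    lab[ok] <- module_map$quantile_label[rc[ok, , drop = FALSE]]
    out <- matrix(0L, d[1], d[2])
    out[cbind(grid$row, grid$col)] <- lab
    structure(list(quantile_label = out, n_quantiles = module_map$n_quantiles,
                   top_k = module_map$top_k, bottom_k = module_map$bottom_k,
                   pixel_size_um = px),
              class = "module_map")
  })
}
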