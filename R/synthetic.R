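# Deterministic sub-stream seeds: each sub-generator of a scene draws from
# its own seed so changing one component (e.g. landmark count) never
# perturbs another. Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + k * 1000003
  as.integer(s %% 2147483629 + 1)
}

#' Generate a quasi-periodic module intensity field
#'
#' Synthesizes a latent "M2 intensity" surface as band-pass filtered white
#' noise: Gaussian white noise is filtered in the Fourier domain with a
#' difference-of-Gaussians transfer function whose peak response sits at
#' spatial period `module_spacing_um`. The result is quasi-periodic and
#' non-crystalline, like the patch/interpatch mosaic of L1, with no lattice
#' placement heuristics. The ground-truth module map is the equal-count
#' sextile partition of the field within the mask; a strictly positive
#' affine copy of the field is returned as a fluorescence-like image.
#'
#' @param seed Integer RNG seed; the field is a pure function of
#'   `(parameters, seed)`.
#' @param field_size_um `c(width, height)` of the field in um.
#' @param pixel_size_um Grid pitch in um/pixel.
#' @param module_spacing_um Characteristic patch period (um); must exceed
#'   two pixels to be resolvable.
#' @param mask Optional logical analysis mask (default full frame).
#' @param n_quantiles,top_k,bottom_k Partition parameters for the ground
#'   truth map (defaults 6, 2, 2).
#' @return List with `field` (numeric matrix, zero-mean band-pass noise),
#'   `image` (a positive [planar_image()], monotone in the field),
#'   and `module_map` (ground-truth sextile partition).
#' @export
generate_module_field <- function(seed, field_size_um = c(2560, 2560),
                                  pixel_size_um = 5,
                                  module_spacing_um = 120, mask = NULL,
                                  n_quantiles = 6L, top_k = 2L,
                                  bottom_k = 2L) {
  if (module_spacing_um <= 2 * pixel_size_um)
    stop(sprintf("module spacing %g um is not resolvable at %g um/px",
                 module_spacing_um, pixel_size_um))
  nc <- round(field_size_um[1] / pixel_size_um)
  nr <- round(field_size_um[2] / pixel_size_um)
  if (!is.null(mask) && !any(mask)) stop("mask is empty")
  set.seed(sub_seed(seed, 1))
  w <- matrix(rnorm(nr * nc), nr, nc)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / (nr * pixel_size_um)
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / (nc * pixel_size_um)
  if (nr == 1) fr <- 0
  if (nc == 1) fc <- 0
  f2 <- outer(fr^2, fc^2, "+")
  # DoG transfer with sigma2 = 2 sigma1; peak response at period
  # lambda* = sigma1 * pi * sqrt(6 / log 4), hence:
  s1 <- module_spacing_um * sqrt(log(4) / 6) / pi
  s2 <- 2 * s1
  h <- exp(-2 * pi^2 * s1^2 * f2) - exp(-2 * pi^2 * s2^2 * f2)
  z <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / (nr * nc)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  # monotone positive affine copy: partition-equivalent to the raw field
  rng <- range(z[mask])
  img <- planar_image((z - rng[1]) / max(rng[2] - rng[1], 1e-12) * 1000 + 10,
                      pixel_size_um, mask)
  gt <- quantile_partition(planar_image(z - min(z) + 1, pixel_size_um, mask),
                           n_quantiles, top_k, bottom_k)
  list(field = z, image = img, module_map = gt)
}

#' Injection site descriptor
#'
#' @param center_xy_um `c(x, y)` of the injection centre in um.
#' @param core_radius_um Radius of the saturated core disc (um).
#' @return List of class `injection_site`.
#' @export
injection_site <- function(center_xy_um, core_radius_um) {
  stopifnot(length(center_xy_um) == 2, all(is.finite(center_xy_um)),
            is.finite(core_radius_um), core_radius_um > 0)
  structure(list(center_xy_um = as.numeric(center_xy_um),
                 core_radius_um = core_radius_um),
            class = "injection_site")
}

# elliptical distance from the injection centre: decay length along the
# major axis (angle `axis_angle_deg`, default elevation = y) is
# `anisotropy_a` times the minor-axis decay length
elliptical_distance <- function(image_dim, pixel_size_um, center_xy_um,
                                anisotropy_a, axis_angle_deg = 90) {
  nr <- image_dim[1]; nc <- image_dim[2]
  x <- matrix((seq_len(nc) - 1) * pixel_size_um, nr, nc, byrow = TRUE) -
    center_xy_um[1]
  y <- matrix((seq_len(nr) - 1) * pixel_size_um, nr, nc) - center_xy_um[2]
  th <- axis_angle_deg * pi / 180
  major <- x * cos(th) + y * sin(th)
  minor <- -x * sin(th) + y * cos(th)
  sqrt(major^2 + (anisotropy_a * minor)^2)
}

#' Generate a module-biased anisotropic axon density field
#'
#' Plants a known modular preference into a distance-decaying axon density:
#' `density = exp(-d_aniso / decay_length) * (1 + (rho - 1) * interpatch) *
#' speckle`, where `d_aniso` is the elliptical distance from the injection
#' centre (major/minor decay-length ratio `anisotropy_a`, major axis along
#' the elevation/y axis by default) and `rho` is the planted ratio of
#' interpatch to patch density at matched distance. Noise is multiplicative
#' log-normal speckle with unit mean (non-negative, signal-proportional,
#' like fluorescence). Pixels within the injection core are set to a
#' saturated constant, emulating the intensely fluorescent core.
#'
#' @param module_map Ground-truth `module_map` defining interpatch pixels.
#' @param injection An [injection_site()]; its centre must lie inside the
#'   field.
#' @param rho Interpatch preference ratio (>= 0); `rho = 1` plants no
#'   modular preference.
#' @param anisotropy_a Major/minor decay-length ratio (>= 1).
#' @param decay_length_um Major-axis exponential decay length (um).
#' @param noise_sigma Log-normal sigma of the speckle (0 disables noise).
#' @param seed Integer RNG seed.
#' @param axis_angle_deg Major-axis angle, degrees from +x (default 90,
#'   i.e. the elevation axis).
#' @return A `planar_image` of non-negative densities.
#' @export
generate_axon_field <- function(module_map, injection, rho = 2,
                                anisotropy_a = 1.4, decay_length_um = 500,
                                noise_sigma = 0.2, seed = 1,
                                axis_angle_deg = 90) {
  stopifnot(inherits(module_map, "module_map"),
            inherits(injection, "injection_site"))
  if (rho < 0) stop("`rho` must be >= 0")
  if (anisotropy_a < 1) stop("`anisotropy_a` must be >= 1")
  if (decay_length_um <= 0) stop("`decay_length_um` must be positive")
  d <- dim(module_map$quantile_label)
  px <- module_map$pixel_size_um
  ctr <- injection$center_xy_um
  if (ctr[1] < 0 || ctr[1] > (d[2] - 1) * px ||
      ctr[2] < 0 || ctr[2] > (d[1] - 1) * px)
    stop("injection centre lies outside the field")
  da <- elliptical_distance(d, px, ctr, anisotropy_a, axis_angle_deg)
  base <- exp(-da / decay_length_um)
  field <- base * (1 + (rho - 1) * interpatch_mask(module_map))
  if (noise_sigma > 0) {
    set.seed(sub_seed(seed, 2))
    field <- field * exp(stats::rnorm(length(field), -noise_sigma^2 / 2,
                                      noise_sigma))
  }
  # saturated core disc (euclidean radius), added on top
  xy <- pixel_coords_um(list(pixels = field, pixel_size_um = px))
  core <- (xy$x - ctr[1])^2 + (xy$y - ctr[2])^2 <= injection$core_radius_um^2
  if (any(core)) field[core] <- 10 * max(field[!core], 1e-12)
  planar_image(field, px, module_map$quantile_label > 0L)
}

#' Sample an inhomogeneous Poisson point pattern by thinning
#'
#' Draws a point process whose intensity is proportional to the supplied
#' density field, scaled so the expected total count is `expected_n`.
#' Candidates are generated as a homogeneous Poisson process at the field
#' maximum and thinned by the local density ratio (exact, no gridding bias);
#' the density at a continuous location is that of the nearest pixel. The
#' realized count is Poisson-distributed around `expected_n`.
#'
#' @param density A `planar_image` (or numeric matrix with `pixel_size_um`
#'   given) of non-negative relative densities; only masked pixels support
#'   points.
#' @param expected_n Expected number of points (> 0).
#' @param seed Integer RNG seed.
#' @param pixel_size_um Pixel size, required when `density` is a bare matrix.
#' @return Data frame with columns `x_um`, `y_um`.
#' @export
sample_points <- function(density, expected_n, seed, pixel_size_um = NULL) {
  if (is_planar_image(density)) {
    dm <- density$pixels
    dm[!density$mask] <- 0
    px <- density$pixel_size_um
  } else {
    dm <- density
    px <- pixel_size_um
    if (is.null(px)) stop("`pixel_size_um` required for matrix input")
  }
  if (expected_n <= 0) stop("`expected_n` must be positive")
  if (any(dm < 0)) stop("density must be non-negative")
  tot <- sum(dm)
  if (tot <= 0) stop("density is zero everywhere: nothing to sample")
  d <- dim(dm)
  lam <- dm * (expected_n / tot)        # expected points per pixel
  lam_max <- max(lam)
  w <- d[2] * px; h <- d[1] * px        # domain covers pixel extents
  set.seed(sub_seed(seed, 3))
  n_cand <- stats::rpois(1, lam_max * length(dm))
  if (n_cand == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  x <- stats::runif(n_cand, -px / 2, w - px / 2)
  y <- stats::runif(n_cand, -px / 2, h - px / 2)
  rc <- points_to_pixels(x, y, d, px)
  ok <- !is.na(rc[, 1])
  p <- numeric(n_cand)
  p[ok] <- lam[rc[ok, , drop = FALSE]] / lam_max
  keep <- stats::runif(n_cand) < p
  data.frame(x_um = x[keep], y_um = y[keep])
}

#' Simulate a complete modular scene with planted ground truth
#'
#' Builds, from one seed, every input the analysis pipeline consumes: a
#' quasi-periodic module field with its ground-truth sextile map, an
#' injection site at the field centre, an anisotropic distance-decaying
#' axon density with planted interpatch preference `rho` and saturated
#' core, and cell-body / apical-dendrite point sets sampled from
#' module-biased densities (points are suppressed inside the core, where
#' real counts are unresolvable). Sub-generators use split RNG streams, so
#' changing one component's parameters leaves the others untouched.
#'
#' Default geometry: a 2560 x 2560 um field at 5 um/pixel with 120 um
#' module spacing, giving 4-8 modules per 260 x 360 um point image.
#'
#' @param seed Integer master seed.
#' @param field_size_um,pixel_size_um,module_spacing_um Field geometry.
#' @param interpatch_preference_rho Planted interpatch/patch density ratio.
#' @param anisotropy_a Planted major/minor decay-length ratio.
#' @param decay_length_um Major-axis decay length (um).
#' @param noise_sigma Log-normal speckle sigma (default 0.2).
#' @param core_radius_um Saturated injection-core radius (default 200, i.e.
#'   a 400 um-wide core).
#' @param expected_cells,expected_dendrites Expected point counts.
#' @param mask Optional analysis mask.
#' @return An object of class `modular_scene`.
#' @export
simulate_scene <- function(seed, field_size_um = c(2560, 2560),
                           pixel_size_um = 5, module_spacing_um = 120,
                           interpatch_preference_rho = 2,
                           anisotropy_a = 1.4, decay_length_um = 500,
                           noise_sigma = 0.2, core_radius_um = 200,
                           expected_cells = 1000, expected_dendrites = 1000,
                           mask = NULL) {
  mf <- generate_module_field(seed, field_size_um, pixel_size_um,
                              module_spacing_um, mask)
  ctr <- c((dim(mf$field)[2] - 1), (dim(mf$field)[1] - 1)) / 2 * pixel_size_um
  inj <- injection_site(ctr, core_radius_um)
  ax <- generate_axon_field(mf$module_map, inj,
                            rho = interpatch_preference_rho,
                            anisotropy_a = anisotropy_a,
                            decay_length_um = decay_length_um,
                            noise_sigma = noise_sigma, seed = seed)
  # point densities share the modular bias and decay but exclude the core
  pd <- ax$pixels
  xy <- pixel_coords_um(ax)
  core <- (xy$x - ctr[1])^2 + (xy$y - ctr[2])^2 <= core_radius_um^2
  pd[core] <- 0
  pdens <- planar_image(pd, pixel_size_um, ax$mask)
  cells <- sample_points(pdens, expected_cells, sub_seed(seed, 11))
  dends <- sample_points(pdens, expected_dendrites, sub_seed(seed, 12))
  if (nrow(cells) > 0) {
    set.seed(sub_seed(seed, 13))
    cells$section_index <- sample(3:16, nrow(cells), replace = TRUE)
  } else cells$section_index <- integer(0)
  cells$kind <- rep("cell_body", nrow(cells))
  dends$section_index <- rep(1L, nrow(dends))
  dends$kind <- rep("apical_dendrite", nrow(dends))
  structure(list(
    seed = seed, field_size_um = field_size_um,
    pixel_size_um = pixel_size_um, module_spacing_um = module_spacing_um,
    m2_field = mf$field, m2_image = mf$image, gt_module_map = mf$module_map,
    injection = inj, interpatch_preference_rho = interpatch_preference_rho,
    anisotropy_a = anisotropy_a, decay_length_um = decay_length_um,
    noise_sigma = noise_sigma, axon_field = ax,
    cell_points = cells, dendrite_points = dends), class = "modular_scene")
}

#' @export
print.modular_scene <- function(x, ...) {
  cat(sprintf(paste0(
    "modular_scene (seed %d): %g x %g um at %g um/px, spacing %g um\n",
    "  rho = %g, anisotropy = %g, decay = %g um, noise sigma = %g\n",
    "  %d cell points, %d dendrite points\n"),
    x$seed, x$field_size_um[1], x$field_size_um[2], x$pixel_size_um,
    x$module_spacing_um, x$interpatch_preference_rho, x$anisotropy_a,
    x$decay_length_um, x$noise_sigma,
    nrow(x$cell_points), nrow(x$dendrite_points)))
  invisible(x)
}

#' Generate a distorted serial-section stack with shared landmarks
#'
#' Emulates serial tangential sections cut from one block: each section k
#' carries a known projective transform T_k (a small perturbation of the
#' identity, scale set by `distortion_scale_um`) mapping its own frame onto
#' the reference (L1) frame. Section images are the scene's axon field
#' resampled into each distorted frame; blood-vessel-like landmarks are
#' drawn once in the reference frame and their section coordinates are
#' exact correspondences under T_k. The true transforms are returned so
#' registration can be tested for exact recovery.
#'
#' @param scene A [simulate_scene()] result.
#' @param n_sections Number of sections (>= 1).
#' @param landmark_count Landmarks per section (>= 4; a projective fit is
#'   underdetermined below that).
#' @param distortion_scale_um Typical landmark displacement (um) induced by
#'   the distortion; 0 yields identity transforms.
#' @param seed Integer RNG seed.
#' @return List with `sections` (list of `planar_image`), `landmarks`
#'   (data frame: `section_index`, `x_ref_um`, `y_ref_um`, `x_sec_um`,
#'   `y_sec_um`) and `transforms` (list of true `projective_transform`s,
#'   section -> reference).
#' @export
generate_serial_stack <- function(scene, n_sections = 4, landmark_count = 8,
                                  distortion_scale_um = 10, seed = 1) {
  stopifnot(inherits(scene, "modular_scene"))
  if (n_sections < 1) stop("`n_sections` must be >= 1")
  if (landmark_count < 4)
    stop("`landmark_count` must be >= 4: a projective fit needs 4 pairs")
  d <- dim(scene$axon_field$pixels)
  px <- scene$pixel_size_um
  ext <- max((d[1] - 1), (d[2] - 1)) * px
  set.seed(sub_seed(seed, 4))
  transforms <- lapply(seq_len(n_sections), function(k) {
    m <- diag(3)
    if (distortion_scale_um > 0) {
      m[1:2, 3] <- stats::rnorm(2, 0, distortion_scale_um)
      m[1:2, 1:2] <- m[1:2, 1:2] +
        matrix(stats::rnorm(4, 0, distortion_scale_um / ext), 2, 2)
      m[3, 1:2] <- stats::rnorm(2, 0, distortion_scale_um / (10 * ext^2))
    } else {
      return(identity_transform())
    }
    projective_transform(m)
  })
  # vessel-like landmarks: shared positions in the central 80% of the frame
  set.seed(sub_seed(seed, 5))
  lm_ref <- cbind(
    stats::runif(landmark_count, 0.1, 0.9) * (d[2] - 1) * px,
    stats::runif(landmark_count, 0.1, 0.9) * (d[1] - 1) * px)
  landmarks <- do.call(rbind, lapply(seq_len(n_sections), function(k) {
    sec <- map_points(solve(transforms[[k]]$matrix), lm_ref)
    data.frame(section_index = k,
               x_ref_um = lm_ref[, 1], y_ref_um = lm_ref[, 2],
               x_sec_um = sec[, 1], y_sec_um = sec[, 2])
  }))
  sections <- lapply(seq_len(n_sections), function(k) {
    if (distortion_scale_um == 0) return(scene$axon_field)
    warp_image(invert_transform(transforms[[k]]), scene$axon_field)
  })
  list(sections = sections, landmarks = landmarks, transforms = transforms)
}
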