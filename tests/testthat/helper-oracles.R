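# Independent oracles and small fixture builders, all generated in code.

# explicit disc-enumeration mean filter: the reference for the FFT-based
# masked normalized convolution
bf_disc_mean <- function(pixels, mask, radius_px) {
  d <- dim(pixels)
  r <- floor(radius_px)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!mask[i, j]) next
    acc <- 0; n <- 0
    for (a in -r:r) for (b in -r:r) {
      if (a * a + b * b > radius_px^2) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || !mask[ii, jj]) next
      acc <- acc + pixels[ii, jj]; n <- n + 1
    }
    out[i, j] <- acc / n
  }
  out
}

rand_image <- function(seed, n = 32, px = 5) {
  set.seed(seed)
  planar_image(matrix(runif(n * n, 0.1, 1), n, n), px)
}

# a module_map built directly from a label matrix (bypasses partitioning)
raw_module_map <- function(labels, px = 5, n_quantiles = 6L,
                           top_k = 2L, bottom_k = 2L) {
  structure(list(quantile_label = labels, n_quantiles = n_quantiles,
                 top_k = top_k, bottom_k = bottom_k, pixel_size_um = px),
            class = "module_map")
}

# a known, mildly projective homography for recovery tests
known_homography <- function() {
  projective_transform(matrix(c(1.02, 0.03, 12,
                                -0.02, 0.98, -7,
                                1e-6, -2e-6, 1), 3, 3, byrow = TRUE))
}

# small scene used across tests: 1280 um field at 10 um/px
small_scene <- function(seed = 2, rho = 2, noise = 0.2, aniso = 1.4) {
  simulate_scene(seed, field_size_um = c(1280, 1280), pixel_size_um = 10,
                 interpatch_preference_rho = rho, anisotropy_a = aniso,
                 noise_sigma = noise, core_radius_um = 100,
                 expected_cells = 300, expected_dendrites = 300)
}

# reduced-scale null/power study: scene -> segment -> filter -> ROI class
# means -> KS decision; 22 ROI sampling units (the exact two-sample KS test
# at equal n = 22 has size 0.0494 at alpha = 0.05, the attainable level
# closest to nominal among small designs)
reduced_ks_run <- function(seed, rho, n_rois = 22) {
  sc <- simulate_scene(seed, field_size_um = c(1600, 1600),
                       pixel_size_um = 10, interpatch_preference_rho = rho,
                       core_radius_um = 100,
                       expected_cells = 50, expected_dendrites = 50)
  mm <- delineate_modules(sc$m2_image)
  ax <- blur_circular(normalize_local(sc$axon_field, 100), 30)
  rois <- place_rois(sc$axon_field, n = n_rois, width_um = 180,
                     height_um = 140, seed = seed,
                     avoid_center_xy_um = sc$injection$center_xy_um,
                     avoid_radius_um = 250)
  cm <- roi_class_means(ax, mm, rois)
  ks_compare(cm$patch_mean, cm$interpatch_mean)
}

# exact size of the equal-n two-sample KS test at a nominal level: the
# largest attainable rejection probability not exceeding alpha
exact_ks_size <- function(n, alpha = 0.05) {
  pv <- sapply((1:n) / n, function(d)
    1 - psmirnov(d - 1e-9, sizes = c(n, n), two.sided = TRUE))
  max(pv[pv <= alpha + 1e-12], 0)
}

# writes a small simulated study to disk and returns a ready config path
write_study <- function(dir, seed = 7, rho = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- small_scene(seed = seed, rho = rho)
  scale16 <- function(img)
    planar_image(round(img$pixels / max(img$pixels) * 65535),
                 img$pixel_size_um, img$mask)
  write_image(scale16(sc$m2_image), file.path(dir, "m2.tif"))
  write_image(scale16(sc$axon_field), file.path(dir, "axon.tif"))
  st <- generate_serial_stack(sc, n_sections = 2, landmark_count = 6,
                              distortion_scale_um = 8, seed = seed)
  write_landmarks(st$landmarks, file.path(dir, "landmarks.csv"))
  pts <- rbind(sc$cell_points, sc$dendrite_points)
  write_points(pts[c("x_um", "y_um", "section_index", "kind")],
               file.path(dir, "points.csv"))
  cfg <- list(m2_image = "m2.tif", axon_image = "axon.tif",
              landmarks = "landmarks.csv", points = "points.csv",
              out_dir = "out", pixel_size_um = 10, seed = 11,
              core_radius_um = 100,
              quantification = list(n_rois = 4, roi_width_um = 250,
                                    roi_height_um = 180,
                                    axon_exclusion_um = 250,
                                    point_exclusion_um = 300))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}
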