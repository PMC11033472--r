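test_that("injection centre detection finds the saturated core", {
  px <- matrix(1, 40, 40)
  px[13, 28] <- 1000
  img <- planar_image(px, 10)
  site <- detect_injection_center(img, 0.9999, core_radius_um = 100)
  expect_equal(site$center_xy_um, c(270, 120))
  # symmetric Gaussian blob: centroid at the mode within one pixel
  xg <- matrix((seq_len(81) - 1) * 10, 81, 81, byrow = TRUE)
  yg <- t(xg)
  blob <- planar_image(exp(-((xg - 400)^2 + (yg - 400)^2) / (2 * 90^2)), 10)
  site2 <- detect_injection_center(blob, 0.99, 100)
  expect_lt(max(abs(site2$center_xy_um - c(400, 400))), 10)
  # planted scene: within 10 um of the generator's centre
  sc <- small_scene(seed = 5)
  site3 <- detect_injection_center(sc$axon_field, 0.999, 100)
  expect_lt(sqrt(sum((site3$center_xy_um - sc$injection$center_xy_um)^2)),
            10)
})

test_that("ROI quantile densities follow their definition", {
  set.seed(8)
  n <- 60
  mm <- quantile_partition(planar_image(matrix(runif(n * n), n, n), 10))
  rois <- data.frame(roi = 1L, x_um = 50, y_um = 80, width_um = 200,
                     height_um = 150)
  uni <- planar_image(matrix(1, n, n), 10)
  qd <- roi_quantile_density(uni, mm, rois)
  expect_equal(qd$per_roi$mean_intensity, rep(1, 6))
  lab_img <- planar_image(matrix(as.numeric(mm$quantile_label), n, n), 10)
  qd2 <- roi_quantile_density(lab_img, mm, rois)
  expect_equal(qd2$per_roi$mean_intensity, as.numeric(1:6))
  # conservation: sum(mean * count) equals the ROI signal total
  sig <- planar_image(matrix(runif(n * n), n, n), 10)
  qd3 <- roi_quantile_density(sig, mm, rois)
  sel <- outer((seq_len(n) - 1) * 10 >= 80 & (seq_len(n) - 1) * 10 < 230,
               (seq_len(n) - 1) * 10 >= 50 & (seq_len(n) - 1) * 10 < 250,
               "&")
  expect_equal(sum(qd3$per_roi$mean_intensity * qd3$per_roi$pixel_count),
               sum(sig$pixels[sel]), tolerance = 1e-12)
  # brute-force per-pixel grouping oracle
  for (q in 1:6) {
    ref <- mean(sig$pixels[sel & mm$quantile_label == q])
    expect_equal(qd3$per_roi$mean_intensity[q], ref, tolerance = 1e-12)
  }
  # an absent quantile is missing, not zero
  mm2 <- mm
  mm2$quantile_label[sel & mm2$quantile_label == 4L] <- 3L
  qd4 <- roi_quantile_density(sig, mm2, rois)
  expect_true(is.na(qd4$per_roi$mean_intensity[4]))
  expect_equal(qd4$per_roi$pixel_count[4], 0L)
})

test_that("radial profiles match explicit annulus sums and normalize to 1", {
  set.seed(13)
  n <- 64
  px <- 10
  mm <- quantile_partition(planar_image(matrix(runif(n * n), n, n), px))
  sig <- planar_image(matrix(runif(n * n, 0.5, 2), n, n), px)
  ctr <- c(315, 315)
  prof <- radial_density_profile(sig, mm, ctr, bin_width_um = 40,
                                 exclusion_radius_um = 80)
  expect_equal(max(prof$density_norm, na.rm = TRUE), 1)
  # explicit pixel-loop oracle for one annulus and class
  xg <- matrix((seq_len(n) - 1) * px, n, n, byrow = TRUE)
  yg <- matrix((seq_len(n) - 1) * px, n, n)
  r <- sqrt((xg - ctr[1])^2 + (yg - ctr[2])^2)
  for (b in list(c(80, 120), c(200, 240))) {
    sel <- r >= b[1] & r < b[2] & patch_mask(mm)
    ref <- sum(sig$pixels[sel]) / (sum(sel) * px^2)
    got <- prof$density[prof$class == "patch" & prof$bin_lo_um == b[1]]
    expect_equal(got, ref, tolerance = 1e-9)
  }
  expect_error(radial_density_profile(sig, mm, c(-50, 315)),
               "outside the analysis frame")
})

test_that("a single-class uniform field gives flat unit profiles", {
  n <- 64
  mm <- raw_module_map(matrix(1L, n, n), px = 10)   # all interpatch
  uni <- planar_image(matrix(1, n, n), 10)
  prof <- radial_density_profile(uni, mm, c(315, 315), bin_width_um = 50,
                                 exclusion_radius_um = 0,
                                 max_radius_um = 300)
  i <- prof[prof$class == "interpatch", ]
  expect_true(all(abs(i$density_norm - 1) < 1e-12))
  expect_true(all(is.na(prof$density[prof$class == "patch"])))
})

test_that("planted preference appears bin-wise in noiseless profiles", {
  sc <- simulate_scene(31, field_size_um = c(1280, 1280), pixel_size_um = 10,
                       interpatch_preference_rho = 3, anisotropy_a = 1,
                       noise_sigma = 0, core_radius_um = 100,
                       expected_cells = 10, expected_dendrites = 10)
  prof <- radial_density_profile(sc$axon_field, sc$gt_module_map,
                                 sc$injection$center_xy_um,
                                 exclusion_radius_um = 150)
  p <- prof[prof$class == "patch", ]
  i <- prof[prof$class == "interpatch", ]
  ok <- is.finite(p$density) & is.finite(i$density) &
    p$area_um2 > 1e4 & i$area_um2 > 1e4
  expect_true(all(abs(i$density[ok] / p$density[ok] - 3) < 0.15))
  # estimated rho is nondecreasing in the planted rho
  est <- sapply(c(1, 2, 3, 4), function(rho) {
    s <- simulate_scene(31, field_size_um = c(1280, 1280),
                        pixel_size_um = 10,
                        interpatch_preference_rho = rho, anisotropy_a = 1,
                        noise_sigma = 0.2, core_radius_um = 100,
                        expected_cells = 10, expected_dendrites = 10)
    estimate_preference_ratio(radial_density_profile(
      s$axon_field, s$gt_module_map, s$injection$center_xy_um,
      exclusion_radius_um = 150))
  })
  expect_true(all(diff(est) > 0))
})

test_that("points inside the exclusion radius leave all bins at zero", {
  n <- 64
  mm <- raw_module_map(matrix(1L, n, n), px = 10)
  pts <- data.frame(x_um = runif(50, 280, 350), y_um = runif(50, 280, 350))
  prof <- radial_density_profile(pts, mm, c(315, 315), bin_width_um = 50,
                                 exclusion_radius_um = 100,
                                 max_radius_um = 300)
  expect_true(all(prof$density[is.finite(prof$density)] == 0))
})

test_that("point module densities and ratios follow their definitions", {
  n <- 100                                 # 1000 x 1000 um at 10 um/px
  lab <- matrix(1L, n, n)
  lab[, 51:100] <- 6L                      # left half interpatch, right patch
  mm <- raw_module_map(lab, px = 10)
  # 10 points in one 1 mm^2 ROI, all interpatch
  pts <- data.frame(x_um = runif(10, 0, 490), y_um = runif(10, 0, 990))
  pd <- point_module_density(pts, mm)
  expect_equal(pd$per_roi$interpatch_density, 10 / 0.5, tolerance = 1e-9)
  expect_equal(pd$per_roi$patch_density, 0)
  expect_equal(pd$ratio, 0)
  # homogeneous points: ratio near 1
  set.seed(2)
  ratios <- replicate(20, {
    h <- data.frame(x_um = runif(4000, 0, 990), y_um = runif(4000, 0, 990))
    point_module_density(h, mm)$ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
  expect_gt(mean(abs(ratios - 1) < 0.1), 0.9)
  # layer stratification keeps per-layer counts
  pts$layer <- rep(c("L2-4", "L5"), 5)
  pdl <- point_module_density(pts, mm)
  expect_equal(sum(pdl$by_layer$interpatch_n), 10)
})

test_that("KS comparison matches its definition and exact calibration", {
  x <- c(0.1, 0.4, 0.7)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_compare(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(disjoint$statistic, 1)
  expect_error(ks_compare(numeric(0), x), "non-empty")
  # null rejection rate equals the exact discrete size of the n = 12 test
  size12 <- exact_ks_size(12)          # independent oracle: 0.0314
  set.seed(99)
  rej <- replicate(2000, ks_compare(rnorm(12), rnorm(12))$reject)
  half <- 2.576 * sqrt(size12 * (1 - size12) / 2000)
  expect_gt(mean(rej), size12 - half)
  expect_lt(mean(rej), size12 + half)
})

test_that("moment-based anisotropy is exact, rotation and scale invariant", {
  # isotropic disc of ones
  n <- 101
  xg <- matrix(seq_len(n) - 51, n, n, byrow = TRUE)
  yg <- t(xg)
  disc <- planar_image((xg^2 + yg^2 <= 40^2) * 1 + 1e-6, 10)
  expect_lt(abs(anisotropy_aspect_ratio(disc, 0.9)$aspect_ratio - 1), 0.02)
  # anisotropic Gaussian with sigma ratio 1.4, rotated
  gauss <- function(theta) {
    u <- xg * cos(theta) + yg * sin(theta)
    v <- -xg * sin(theta) + yg * cos(theta)
    planar_image(exp(-u^2 / (2 * 28^2) - v^2 / (2 * 20^2)), 10)
  }
  a0 <- anisotropy_aspect_ratio(gauss(0), 0.75)
  expect_lt(abs(a0$aspect_ratio - 1.4), 0.05)
  a37 <- anisotropy_aspect_ratio(gauss(37 * pi / 180), 0.75)
  expect_lt(abs(a37$aspect_ratio - a0$aspect_ratio), 0.02)
  expect_lt(abs(a37$angle_deg - 37), 2)
  img <- gauss(0)
  scaled <- planar_image(img$pixels * 55, 10)
  expect_equal(anisotropy_aspect_ratio(scaled, 0.75)$aspect_ratio,
               a0$aspect_ratio, tolerance = 1e-12)
  # degenerate support
  expect_error(anisotropy_aspect_ratio(
    data.frame(x_um = c(1, 2, 3), y_um = c(2, 4, 6))), "collinear")
})
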