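test_that("module-field generation is deterministic and area-balanced", {
  a <- generate_module_field(42, c(640, 640), 10, 120)
  b <- generate_module_field(42, c(640, 640), 10, 120)
  expect_identical(a$field, b$field)
  expect_identical(a$module_map$quantile_label, b$module_map$quantile_label)
  frac <- mean(patch_mask(a$module_map))
  expect_equal(frac, 1 / 3, tolerance = 1e-3)
  expect_false(any(patch_mask(a$module_map) &
                     interpatch_mask(a$module_map)))
  counts <- tabulate(a$module_map$quantile_label, 6)
  expect_equal(sum(counts), sum(a$image$mask))
  expect_error(generate_module_field(1, c(640, 640), 10, 15),
               "not resolvable")
})

test_that("the module field's dominant spatial period matches the target", {
  spacing <- 120
  mf <- generate_module_field(7, c(2560, 2560), 5, spacing)
  z <- mf$field
  n <- nrow(z)
  p <- Mod(fft(z))^2
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * 5)
  f <- sqrt(outer(fx^2, fx^2, "+"))
  br <- seq(0, max(f), length.out = 200)
  pr <- tapply(as.vector(p), cut(as.vector(f), br), mean)
  peak_period <- 1 / ((br[-1] + br[-length(br)]) / 2)[which.max(pr)]
  expect_lt(abs(peak_period - spacing), 25)
})

test_that("axon field reduces to its formula without noise", {
  mf <- generate_module_field(5, c(640, 640), 10, 120)
  inj <- injection_site(c(320, 320), 60)
  # rho = 1: value depends only on elliptical distance
  f1 <- generate_axon_field(mf$module_map, inj, rho = 1, anisotropy_a = 1.4,
                            decay_length_um = 300, noise_sigma = 0, seed = 1)
  d <- dim(f1$pixels)
  xg <- matrix((seq_len(d[2]) - 1) * 10, d[1], d[2], byrow = TRUE) - 320
  yg <- matrix((seq_len(d[1]) - 1) * 10, d[1], d[2]) - 320
  da <- sqrt((1.4 * xg)^2 + yg^2)     # major axis along y
  core <- xg^2 + yg^2 <= 60^2
  expect_equal(f1$pixels[!core], exp(-da / 300)[!core], tolerance = 1e-12)
  expect_true(all(is.finite(f1$pixels)) && all(f1$pixels >= 0))
  # rho = 3: interpatch/patch ratio is exactly 3 at matched distance
  f3 <- generate_axon_field(mf$module_map, inj, rho = 3, anisotropy_a = 1.4,
                            decay_length_um = 300, noise_sigma = 0, seed = 1)
  ratio <- f3$pixels / f1$pixels
  ip <- interpatch_mask(mf$module_map)
  expect_true(all(abs(ratio[ip & !core] - 3) < 1e-12))
  expect_true(all(abs(ratio[!ip & !core] - 1) < 1e-12))
  expect_error(generate_axon_field(mf$module_map,
                                   injection_site(c(9000, 320), 60),
                                   seed = 1),
               "outside the field")
})

test_that("noisy annulus-wise preference estimates average the planted rho", {
  est <- sapply(1:4, function(s) {
    sc <- small_scene(seed = s, rho = 2, noise = 0.2, aniso = 1)
    prof <- radial_density_profile(sc$axon_field, sc$gt_module_map,
                                   sc$injection$center_xy_um,
                                   exclusion_radius_um = 150)
    estimate_preference_ratio(prof)
  })
  expect_lt(abs(mean(est) - 2), 0.2)
})

test_that("point sampling is an exact thinned Poisson process", {
  # degenerate support: every point lands on the hot pixel
  dens <- matrix(0, 20, 20)
  dens[7, 13] <- 5
  pts <- sample_points(dens, 200, seed = 3, pixel_size_um = 10)
  expect_gt(nrow(pts), 100)
  expect_true(all(abs(pts$x_um - 120) <= 5 & abs(pts$y_um - 60) <= 5))
  # uniform density: realized count within the Poisson 99% interval
  u <- planar_image(matrix(1, 50, 50), 10)
  n <- nrow(sample_points(u, 1000, seed = 11))
  expect_gte(n, qpois(0.005, 1000))
  expect_lte(n, qpois(0.995, 1000))
  # determinism and error paths
  expect_identical(sample_points(u, 500, seed = 4),
                   sample_points(u, 500, seed = 4))
  expect_error(sample_points(matrix(0, 5, 5), 10, 1, pixel_size_um = 10),
               "zero everywhere")
})

test_that("scene generation is seed-pure and streams are split", {
  a <- small_scene(seed = 17)
  b <- small_scene(seed = 17)
  expect_identical(a$axon_field$pixels, b$axon_field$pixels)
  expect_identical(a$cell_points, b$cell_points)
  c <- small_scene(seed = 18)
  expect_false(identical(a$m2_field, c$m2_field))
})

test_that("serial stacks carry exact landmark correspondences", {
  sc <- small_scene(seed = 2)
  st0 <- generate_serial_stack(sc, n_sections = 2, landmark_count = 5,
                               distortion_scale_um = 0, seed = 1)
  for (t in st0$transforms) expect_equal(t$matrix, diag(3))
  st <- generate_serial_stack(sc, n_sections = 3, landmark_count = 8,
                              distortion_scale_um = 15, seed = 9)
  for (k in 1:3) {
    lm <- st$landmarks[st$landmarks$section_index == k, ]
    mapped <- apply_transform(st$transforms[[k]],
                              cbind(lm$x_sec_um, lm$y_sec_um))
    expect_equal(mapped, unname(cbind(lm$x_ref_um, lm$y_ref_um)),
                 tolerance = 1e-9)
    # round trip through the registration module
    fit <- fit_projective(lm)
    probe <- cbind(runif(20, 0, 1200), runif(20, 0, 1200))
    expect_lt(max(abs(apply_transform(fit, probe) -
                        apply_transform(st$transforms[[k]], probe))), 1e-6)
  }
  expect_error(generate_serial_stack(sc, landmark_count = 3, seed = 1),
               ">= 4")
})
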