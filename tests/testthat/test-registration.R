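test_that("identity correspondences fit to the identity", {
  lm <- data.frame(x_ref_um = c(0, 100, 100, 0),
                   y_ref_um = c(0, 0, 100, 100))
  lm$x_sec_um <- lm$x_ref_um
  lm$y_sec_um <- lm$y_ref_um
  fit <- fit_projective(lm)
  expect_equal(fit$matrix, diag(3), tolerance = 1e-9)
  expect_lt(fit$residual_rms_um, 1e-9)
})

test_that("a known homography is recovered exactly from noiseless pairs", {
  h <- known_homography()
  set.seed(3)
  sec <- cbind(runif(6, 0, 2000), runif(6, 0, 2000))
  ref <- apply_transform(h, sec)
  fit <- fit_projective(data.frame(x_ref_um = ref[, 1], y_ref_um = ref[, 2],
                                   x_sec_um = sec[, 1], y_sec_um = sec[, 2]))
  expect_equal(fit$matrix, h$matrix, tolerance = 1e-9)
  expect_lt(fit$residual_rms_um, 1e-8)
})

test_that("underdetermined and degenerate landmark sets are rejected", {
  lm3 <- data.frame(x_ref_um = c(0, 1, 2), y_ref_um = c(0, 1, 0),
                    x_sec_um = c(0, 1, 2), y_sec_um = c(0, 1, 0))
  expect_error(fit_projective(lm3), "underdetermined")
  collinear <- data.frame(x_ref_um = 1:5, y_ref_um = 2 * (1:5),
                          x_sec_um = 1:5, y_sec_um = 2 * (1:5))
  expect_error(fit_projective(collinear), "degenerate")
})

test_that("point mapping: translation, round trip, composition", {
  tr <- projective_transform(matrix(c(1, 0, 30, 0, 1, -20, 0, 0, 1),
                                    3, 3, byrow = TRUE))
  expect_equal(apply_transform(tr, cbind(5, 7)), cbind(35, -13))
  h <- known_homography()
  set.seed(9)
  p <- cbind(runif(100, 0, 2500), runif(100, 0, 2500))
  back <- apply_transform(invert_transform(h), apply_transform(h, p))
  expect_lt(max(abs(back - p)), 1e-9)
  # fitting A->B and B->C then composing equals fitting A->C
  h2 <- projective_transform(matrix(c(0.99, -0.01, 5, 0.02, 1.01, 3,
                                      -1e-6, 1e-6, 1), 3, 3, byrow = TRUE))
  pa <- p[1:8, ]
  pb <- apply_transform(h, pa)
  pc <- apply_transform(h2, pb)
  fit_ab <- fit_projective(data.frame(x_ref_um = pb[, 1], y_ref_um = pb[, 2],
                                      x_sec_um = pa[, 1], y_sec_um = pa[, 2]))
  fit_bc <- fit_projective(data.frame(x_ref_um = pc[, 1], y_ref_um = pc[, 2],
                                      x_sec_um = pb[, 1], y_sec_um = pb[, 2]))
  fit_ac <- fit_projective(data.frame(x_ref_um = pc[, 1], y_ref_um = pc[, 2],
                                      x_sec_um = pa[, 1], y_sec_um = pa[, 2]))
  expect_equal(compose_transforms(fit_bc, fit_ab)$matrix, fit_ac$matrix,
               tolerance = 1e-6)
})

test_that("fit residual tracks landmark jitter", {
  h <- known_homography()
  set.seed(21)
  rms <- replicate(30, {
    sec <- cbind(runif(8, 0, 2000), runif(8, 0, 2000))
    ref <- apply_transform(h, sec) + matrix(rnorm(16, 0, 2), 8, 2)
    fit_projective(data.frame(x_ref_um = ref[, 1], y_ref_um = ref[, 2],
                              x_sec_um = sec[, 1],
                              y_sec_um = sec[, 2]))$residual_rms_um
  })
  expect_gt(mean(rms), 1)
  expect_lt(mean(rms), 4)
})

test_that("identity transform returns images unchanged", {
  img <- rand_image(14, n = 24, px = 10)
  out <- apply_transform(identity_transform(), img)
  interior <- matrix(FALSE, 24, 24); interior[2:23, 2:23] <- TRUE
  expect_equal(out$pixels[interior], img$pixels[interior], tolerance = 1e-12)
})

test_that("section indices map to cortical layers per the lookup table", {
  expect_equal(assign_layer(1), "L1")
  expect_equal(assign_layer(9), "L5")
  expect_equal(assign_layer(c(2, 3, 7, 8, 13, 16, 20, 100)),
               c("L1", "L2-4", "L2-4", "L5", "L6", "L6", "unknown",
                 "unknown"))
  expect_error(assign_layer(0), ">= 1")
  expect_error(layer_assignment(data.frame(first = c(1, 2), last = c(3, 4),
                                           layer = c("a", "b"))),
               "overlap")
})

test_that("module propagation transports labels without blending", {
  sc <- small_scene(seed = 6)
  # identity transforms: the reference map verbatim
  out <- propagate_modules(sc$gt_module_map,
                           list(identity_transform(), identity_transform()))
  expect_identical(out[[1]]$quantile_label, sc$gt_module_map$quantile_label)
  expect_identical(out[[2]]$quantile_label, sc$gt_module_map$quantile_label)
  # pure translation by whole pixels: an interpatch point stays interpatch
  px <- sc$pixel_size_um
  tr <- projective_transform(matrix(c(1, 0, 3 * px, 0, 1, 2 * px, 0, 0, 1),
                                    3, 3, byrow = TRUE))
  moved <- propagate_modules(sc$gt_module_map, list(tr))[[1]]
  ip <- which(interpatch_mask(sc$gt_module_map), arr.ind = TRUE)
  ip <- ip[ip[, 1] > 5 & ip[, 2] > 5, ]   # interior, so the shift stays in-frame
  p_ref <- ip[100, ]                      # a reference-frame interpatch pixel
  p_sec <- c(p_ref[1] - 2, p_ref[2] - 3)  # its location in the section frame
  expect_equal(moved$quantile_label[p_sec[1], p_sec[2]],
               sc$gt_module_map$quantile_label[p_ref[1], p_ref[2]])
  expect_error(propagate_modules(sc$gt_module_map, list(tr, NULL)),
               "section")
})

test_that("propagated labels match ground truth on a distorted stack", {
  sc <- small_scene(seed = 2)
  st <- generate_serial_stack(sc, n_sections = 3, landmark_count = 8,
                              distortion_scale_um = 15, seed = 9)
  fits <- lapply(split(st$landmarks, st$landmarks$section_index),
                 fit_projective)
  via_fit <- propagate_modules(sc$gt_module_map, fits)
  via_truth <- propagate_modules(sc$gt_module_map, st$transforms)
  for (k in 1:3) {
    expect_gte(mean(via_fit[[k]]$quantile_label ==
                      via_truth[[k]]$quantile_label), 0.99)
  }
})
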