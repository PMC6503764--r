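lambda <- electron_wavelength(200e3)

test_that("noiseless peaks are all assigned to their true rings", {
  scene <- synthetic_scene(ellipticity = 0, noise = "none")
  pk <- make_peaklist(scene, n_per_ring = 24)
  asg <- assign_peaks_to_rings(pk, c(508, 530), al_standard(), lambda,
                               distance_guess = 500, pixel_size = 0.075)
  expect_true(all(!is.na(asg$ring)))
  expect_equal(sort(unique(asg$ring)), sort(unique(pk$ring_true)))
  # assignment agrees with construction labels peak by peak
  merged <- dplyr::arrange(asg, .data$x, .data$y)
  truth <- dplyr::arrange(pk, .data$x, .data$y)
  expect_equal(merged$ring, truth$ring_true)
})

test_that("outliers and between-ring peaks stay unassigned", {
  scene <- synthetic_scene(ellipticity = 0, noise = "none")
  pk <- make_peaklist(scene, n_per_ring = 24, n_outliers = 10, seed = 99)
  asg <- assign_peaks_to_rings(pk, c(508, 530), al_standard(), lambda,
                               500, 0.075, tolerance = 0.02)
  # construction labels: every labelled peak right, most outliers dropped
  on_ring <- !is.na(pk$ring_true)
  expect_true(all(!is.na(asg$ring[match(
    paste(pk$x[on_ring], pk$y[on_ring]), paste(asg$x, asg$y))])))

  # peaks exactly halfway between rings 1 and 2, narrow tolerance
  r12 <- ring_radius(al_standard()$rings$d[1:2], lambda, 500, 0.075)
  rmid <- mean(r12)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  mid <- tibble::tibble(x = 508 + rmid * cos(th), y = 530 + rmid * sin(th),
                        frame = 1, intensity = 10)
  asg_mid <- suppressWarnings(
    assign_peaks_to_rings(mid, c(508, 530), al_standard(), lambda,
                          500, 0.075, tolerance = 0.01,
                          refine_scale = FALSE))
  expect_true(all(is.na(asg_mid$ring)))

  expect_error(assign_peaks_to_rings(mid[0, ], c(508, 530), al_standard(),
                                     lambda, 500, 0.075),
               class = "edcal_invalid_input")
  expect_error(assign_peaks_to_rings(mid, c(508, 530), al_standard(),
                                     lambda, 500, 0.075, tolerance = 0.7),
               class = "edcal_invalid_input")
})

test_that("undistorted rings calibrate to the true distance from both axes", {
  scene <- synthetic_scene(ellipticity = 0, noise = "none")
  pk <- make_peaklist(scene, n_per_ring = 36)
  asg <- assign_peaks_to_rings(pk, c(508, 530), al_standard(), lambda,
                               500, 0.075)
  cal <- calibrate_distance(asg, lambda, 0.075)
  expect_gt(nrow(cal), 3)
  expect_equal(cal$distance_from_A, rep(500, nrow(cal)), tolerance = 1e-6)
  expect_equal(cal$distance_from_B, rep(500, nrow(cal)), tolerance = 1e-6)
  s <- attr(cal, "summary")
  expect_equal(s$mean_distance, c(500, 500), tolerance = 1e-6)
  expect_false(attr(cal, "spread_flag"))
})

test_that("distortion splits the two distances by exactly A/B", {
  scene <- synthetic_scene(ellipticity = 0.023, noise = "none")
  pk <- make_peaklist(scene, n_per_ring = 36)
  asg <- assign_peaks_to_rings(pk, c(508, 530), al_standard(), lambda,
                               500, 0.075)
  cal <- calibrate_distance(asg, lambda, 0.075)
  # generator keeps the minor axis at the true radius
  expect_equal(cal$distance_from_B, rep(500, nrow(cal)), tolerance = 1e-4)
  expect_equal(cal$distance_from_A, rep(511.5, nrow(cal)), tolerance = 1e-3)
  # algebraic identity: distance ratio equals axis ratio
  expect_equal(cal$distance_from_A / cal$distance_from_B, cal$axis_ratio,
               tolerance = 1e-9)
  expect_match(attr(cal, "ambiguity"), "known unit-cell")
})

test_that("a mislabelled ring d-spacing trips the spread flag", {
  scene <- synthetic_scene(ellipticity = 0, noise = "none")
  pk <- make_peaklist(scene, n_per_ring = 36)
  asg <- assign_peaks_to_rings(pk, c(508, 530), al_standard(), lambda,
                               500, 0.075)
  # swap the d of ring 1 for ring 2's: its distances become inconsistent
  asg$d[asg$ring == 1 & !is.na(asg$ring)] <- al_standard()$rings$d[2]
  cal <- calibrate_distance(asg, lambda, 0.075)
  expect_true(attr(cal, "spread_flag"))
  gl <- glance(cal)
  expect_true(gl$spread_flag)
  expect_error(calibrate_distance(asg[0, ], lambda, 0.075),
               class = "edcal_invalid_input")
})
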