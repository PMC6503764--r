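test_that("generators are deterministic for a fixed seed", {
  sc <- small_scene()
  expect_identical(make_peaklist(sc, 12, jitter_sd = 0.3, seed = 4),
                   make_peaklist(sc, 12, jitter_sd = 0.3, seed = 4))
  expect_identical(make_powder_frames(sc, 2, seed = 4)$frames,
                   make_powder_frames(sc, 2, seed = 4)$frames)
  expect_identical(make_angle_log(2.95, 10, time_jitter_sd = 0.05, seed = 4),
                   make_angle_log(2.95, 10, time_jitter_sd = 0.05, seed = 4))
})

test_that("peak lists respect the planted ring geometry", {
  sc0 <- small_scene(ellipticity = 0)
  pk <- make_peaklist(sc0, 24)
  radii <- sqrt((pk$x - 200)^2 + (pk$y - 210)^2)
  # constant radius per ring when e = 0 and no jitter
  spread <- tapply(radii, pk$ring_true, function(r) diff(range(r)))
  expect_true(all(spread < 1e-9))

  # planted distortion is recovered by the ellipse fitter to 4 d.p.
  sc <- small_scene(ellipticity = 0.0273)
  pk1 <- dplyr::filter(make_peaklist(sc, 36), .data$ring_true == 1)
  fit <- fit_ellipse(pk1)
  expect_equal(round(fit$semi_major / fit$semi_minor, 4), 1.0273)

  # jittered fit residual matches the planted sigma
  pkj <- dplyr::filter(make_peaklist(sc, 100, jitter_sd = 0.3, seed = 42),
                       .data$ring_true == 1)
  expect_equal(fit_ellipse(pkj)$rms_residual, 0.3, tolerance = 0.3)
  expect_error(make_peaklist(sc, 3), class = "edcal_invalid_input")
})

test_that("powder frames carry modulation, saturation and noise as planted", {
  # no modulation -> axis finder must refuse
  flat <- small_scene(modulation_depth = 0, noise = "none")
  r0 <- small_r0(flat)
  img <- sum_frames(make_powder_frames(flat, 1))
  expect_error(find_axis(azimuthal_profile(img, flat$geometry$origin,
                                           r0 - 5, r0 + 5)),
               class = "edcal_no_modulation")

  # direct-beam core pixels clip exactly at the saturation count
  sc <- small_scene(noise = "none")
  st <- make_powder_frames(sc, 1)
  f <- st$frames[[1]]
  expect_equal(max(f), sc$geometry$detector$saturation_count)
  ctr <- f[round(sc$geometry$origin[2]) + 1, round(sc$geometry$origin[1]) + 1]
  expect_equal(ctr, sc$geometry$detector$saturation_count)

  # Poisson axis recovery inside the accuracy envelope
  stn <- make_powder_frames(small_scene(), 1, seed = 14)
  est <- find_axis(azimuthal_profile(sum_frames(stn), c(200, 210),
                                     r0 - 5, r0 + 5))
  expect_lte(fold_err(est$azimuth, 37), 5)
})

test_that("angle-log generator produces the documented record structure", {
  # no jitter, no duplicates: exact recovery
  log <- make_angle_log(2.95, 20, time_jitter_sd = 0, seed = 1)
  expect_true(all(log$t_after > log$t_before))
  fit <- fit_rate(log)
  expect_equal(fit$rate, 2.95, tolerance = 1e-9)

  # duplicate pairs: consecutive records share the angle
  dup <- make_angle_log(2.95, 20, duplicate_pairs = TRUE, seed = 2)
  a <- dup$alpha
  pairs <- seq(1, length(a) - 1, by = 2)
  expect_true(all(a[pairs] == a[pairs + 1]))

  # reverse rotation fits negative
  neg <- make_angle_log(-2.9, 20, duplicate_pairs = TRUE,
                        time_jitter_sd = 0.02, seed = 3)
  expect_lt(fit_rate(neg)$rate, 0)
  expect_error(make_angle_log(2.95, 0.1, sample_interval = 0.5),
               class = "edcal_invalid_input")
})

test_that("full synthetic round trip recovers every calibration parameter", {
  scene <- small_scene() # Poisson noise, e = 0.023, psi0 = 37, D = 250
  lambda <- scene$geometry$beam$wavelength
  px <- scene$geometry$detector$pixel_size

  pk <- make_peaklist(scene, 48, jitter_sd = 0.2, seed = 61)
  asg <- assign_peaks_to_rings(pk, scene$geometry$origin, scene$standard,
                               lambda, 1.3 * scene$geometry$distance, px)
  cal <- calibrate_distance(asg, lambda, px)
  expect_equal(mean(cal$distance_from_B), 250, tolerance = 0.005)
  expect_lt(abs(mean(cal$ellipticity) - 0.023), 0.003)

  r0 <- small_r0(scene)
  img <- sum_frames(make_powder_frames(scene, 4, seed = 62))
  est <- find_axis(azimuthal_profile(img, scene$geometry$origin,
                                     r0 - 5, r0 + 5))
  expect_lte(fold_err(est$azimuth, 37), 5)

  log <- make_angle_log(2.95, 40, duplicate_pairs = TRUE,
                        time_jitter_sd = 0.05, seed = 63)
  fit <- fit_rate(log)
  expect_lt(abs(fit$rate - 2.95), 2 * fit$rate_se)
  expect_equal(fit$oscillation_width, fit$rate / 100, tolerance = 1e-12)
})
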