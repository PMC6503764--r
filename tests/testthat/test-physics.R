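test_that("electron wavelength matches the closed-form relativistic oracle", {
  expect_equal(signif(electron_wavelength(200e3), 4), 0.02508)
  expect_equal(signif(electron_wavelength(300e3), 5), 0.019687)
  expect_equal(electron_wavelength(100e3), oracle_wavelength(100e3),
               tolerance = 1e-12)
  expect_equal(signif(electron_wavelength(100e3), 4), 0.03701)
  volts <- 10^seq(2, 6, length.out = 40)
  expect_equal(electron_wavelength(volts), oracle_wavelength(volts),
               tolerance = 1e-12)
  expect_true(all(diff(electron_wavelength(volts)) < 0))
  expect_error(electron_wavelength(0), class = "edcal_invalid_input")
  expect_error(electron_wavelength(-5), class = "edcal_invalid_input")
})

test_that("fcc d-spacings reproduce the aluminium calibrant ring list", {
  rings <- fcc_dspacings(4.0495, 0.8)
  expect_equal(nrow(rings), 9)
  # direct formula over allowed hkl as independent check
  expect_equal(rings$d, 4.0495 / sqrt(rings$s2), tolerance = 1e-12)
  expect_equal(round(rings$d[1], 3), 2.338)
  expect_equal(round(rings$d, 2),
               c(2.34, 2.02, 1.43, 1.22, 1.17, 1.01, 0.93, 0.91, 0.83))
  expect_equal(round(rings$d[5], 4), 1.1690)
  expect_equal(round(rings$d[9], 4), 0.8266)
  # parity rule: all even or all odd, strictly decreasing d
  par <- cbind(rings$h, rings$k, rings$l) %% 2
  expect_true(all(rowSums(par) %in% c(0, 3)))
  expect_true(all(diff(rings$d) < 0))
  # mixed-parity (1,0,0) must be absent
  expect_false(any(rings$h == 1 & rings$k == 0 & rings$l == 0))
})

test_that("degenerate d merging keeps every allowed family", {
  # 333 and 511 share s2 = 27: one ring, multiplicity 2
  rings <- fcc_dspacings(4.0495, 0.75)
  deg <- rings[rings$s2 == 27, ]
  expect_equal(nrow(deg), 1)
  expect_equal(deg$multiplicity, 2)
  # simple cube: d(111) = 1/sqrt(3)
  r1 <- fcc_dspacings(1, 0.5)
  expect_equal(r1$d[1], 1 / sqrt(3), tolerance = 1e-12)
  expect_warning(empty <- fcc_dspacings(4.0495, 5), "no fcc reflection")
  expect_equal(nrow(empty), 0)
})

test_that("ring radius follows exact scattering geometry", {
  # oracle: the two-line trigonometric formula evaluated independently
  two_theta <- 2 * asin(0.02508 / (2 * 2.338))
  expect_equal(ring_radius(2.338, 0.02508, 500, 0.075),
               500 * tan(two_theta) / 0.075, tolerance = 1e-12)
  expect_equal(round(ring_radius(2.338, 0.02508, 500, 0.075), 2), 71.52)
  # forward beam limit and linearity in D
  expect_lt(ring_radius(1e8, 0.02508, 500, 0.075), 1e-4)
  expect_equal(ring_radius(2.338, 0.02508, 1000, 0.075),
               2 * ring_radius(2.338, 0.02508, 500, 0.075), tolerance = 1e-12)
  expect_error(ring_radius(0.01, 0.02508, 500, 0.075),
               class = "edcal_no_diffraction")
})

test_that("distance_from_radius inverts ring_radius", {
  expect_equal(distance_from_radius(71.52, 2.338, 0.02508, 0.075), 500,
               tolerance = 1e-4)
  set.seed(5)
  d <- runif(100, 0.8, 3); D <- runif(100, 100, 2000)
  r <- vapply(seq_along(d),
              function(i) ring_radius(d[i], 0.02508, D[i], 0.075), numeric(1))
  D2 <- vapply(seq_along(d),
               function(i) distance_from_radius(r[i], d[i], 0.02508, 0.075),
               numeric(1))
  expect_equal(D2, D, tolerance = 1e-9)
  expect_error(distance_from_radius(0, 2.338, 0.02508, 0.075),
               class = "edcal_invalid_input")
  expect_error(distance_from_radius(-3, 2.338, 0.02508, 0.075),
               class = "edcal_invalid_input")
})

test_that("beam, detector and geometry constructors validate their fields", {
  b <- beam_spec(200e3)
  expect_equal(b$wavelength, electron_wavelength(200e3))
  expect_equal(b$incident_direction, c(0, 0, 1))
  expect_error(beam_spec(200e3, c(1, 1, 0)), class = "edcal_invalid_input")
  expect_error(detector_spec(pixel_size = -1), class = "edcal_invalid_input")
  al <- al_standard()
  expect_equal(al$a, 4.0495)
  g <- geometry_model(500, c(508, 530), 197, 0.0295, b, detector_spec())
  expect_equal(g$axis_azimuth, 17) # folded mod 180
  expect_error(
    geometry_model(500, c(5000, 530), 10, 0.0295, b, detector_spec()),
    class = "edcal_invalid_input")
  expect_error(
    geometry_model(500, c(508, 530), 10, 0, b, detector_spec()),
    class = "edcal_invalid_input")
})
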