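test_that("angle-log parsing validates records and reports line numbers", {
  ok <- parse_angle_log(c("# header", "0.0 0.1 1.0", "0.5 0.6 2.5",
                          "1.0 1.1 4.0"))
  expect_equal(nrow(ok), 3)
  expect_equal(ok$alpha, c(1.0, 2.5, 4.0))

  expect_error(parse_angle_log(c("0.0 0.1 1.0", "1.0 0.5 10.0")),
               regexp = "line 2", class = "edcal_validation_error")
  expect_error(parse_angle_log(c("0.0 0.1 1.0", "garbage here")),
               regexp = "line 2", class = "edcal_parse_error")
  expect_error(parse_angle_log("0.0 0.1 1.0"),
               class = "edcal_insufficient_data")

  # duplicated-angle readout parses unchanged: dedup is a fit-time option
  dup <- parse_angle_log(c("0.0 0.02 1.0", "0.5 0.52 1.0",
                           "1.0 1.02 2.0", "1.5 1.52 2.0"))
  expect_equal(dup$alpha, c(1, 1, 2, 2))
})

test_that("an exact line is recovered to machine precision, dedup or not", {
  t <- seq(0, 40, by = 0.5)
  log <- tibble::tibble(t_before = t, t_after = t, alpha = 1.0 + 2.95 * t)
  for (dd in c(FALSE, TRUE)) {
    fit <- fit_rate(log, frame_rate = 100, dedup = dd)
    expect_equal(fit$rate, 2.95, tolerance = 1e-9)
    expect_equal(fit$intercept, 1.0, tolerance = 1e-9)
    expect_equal(fit$oscillation_width, 0.0295, tolerance = 1e-9)
    expect_lt(fit$rate_se, 1e-9)
  }
})

test_that("jittered duplicate-pair logs recover the true rate", {
  log <- make_angle_log(2.95, 40, duplicate_pairs = TRUE,
                        time_jitter_sd = 0.05, seed = 7)
  f1 <- fit_rate(log)
  f2 <- fit_rate(log, dedup = TRUE)
  expect_lt(abs(f1$rate - 2.95), 2 * f1$rate_se)
  expect_true(f2$dedup_applied)
  expect_lt(abs(f1$rate - f2$rate), f1$rate_se)
  expect_equal(f2$n_used, ceiling(f1$n_used / 2))
})

test_that("reverse rotation gives a negative rate and width", {
  log <- make_angle_log(-2.9, 30, duplicate_pairs = TRUE,
                        time_jitter_sd = 0.02, seed = 12)
  fit <- fit_rate(log)
  expect_lt(fit$rate, 0)
  expect_lt(fit$oscillation_width, 0)
  expect_gt(fit$phi_total, 0)
  expect_equal(sign(fit$oscillation_width), sign(fit$rate))
})

test_that("degenerate and mixed-direction logs warn", {
  t <- seq(0, 5, by = 0.5)
  const <- tibble::tibble(t_before = t, t_after = t + 0.01, alpha = 10)
  expect_warning(fit0 <- fit_rate(const), "zero-rate")
  expect_equal(fit0$rate, 0)
  expect_equal(fit0$rate_se, 0)

  updown <- tibble::tibble(t_before = t, t_after = t + 0.01,
                           alpha = c(0, 2, 4, 6, 8, 10, 8, 6, 4, 2, 0))
  expect_warning(fit_rate(updown), "mixed-direction")
})

test_that("rate estimator is unbiased and its stderr is calibrated", {
  fits <- lapply(1:200, function(s) {
    fit_rate(make_angle_log(2.95, 40, duplicate_pairs = TRUE,
                            time_jitter_sd = 0.05, seed = 5000 + s))
  })
  rates <- vapply(fits, `[[`, numeric(1), "rate")
  ses <- vapply(fits, `[[`, numeric(1), "rate_se")
  expect_lt(abs(mean(rates) - 2.95), 0.01)
  expect_equal(sd(rates), mean(ses), tolerance = 0.3)
})

test_that("width and total-rotation identities hold", {
  set.seed(3)
  for (i in 1:5) {
    nu <- runif(1, 10, 500)
    log <- make_angle_log(runif(1, -4, 4), 20, time_jitter_sd = 0.01,
                          seed = 200 + i)
    fit <- fit_rate(log, frame_rate = nu)
    expect_equal(fit$oscillation_width * nu, fit$rate, tolerance = 1e-12)
  }
  # constant-rate log: phi_total matches rate x span within one step's angle
  log <- make_angle_log(2.95, 40, sample_interval = 0.5)
  fit <- fit_rate(log)
  span <- max(log$t_after + log$t_before) / 2 - min(log$t_after + log$t_before) / 2
  expect_lt(abs(fit$phi_total - 2.95 * span), 2.95 * 0.5)
  expect_lt(abs(fit$phi_range_raw - fit$phi_total), 2.95 * 0.5)
})

test_that("screenshot arithmetic gives the rate-over-frequency width", {
  expect_equal(width_from_screenshots(53.3, 1.26, 111.6, 26.45, 100),
               (111.6 - 53.3) / (26.45 - 1.26) / 100, tolerance = 1e-12)
  expect_equal(round(width_from_screenshots(53.3, 1.26, 111.6, 26.45, 100), 6),
               0.023144)
  expect_equal(width_from_screenshots(0, 0, 2.95, 1, 100), 0.0295)
  # reversed rotation (angles exchanged at the same times) flips the sign
  expect_equal(width_from_screenshots(111.6, 1.26, 53.3, 26.45, 100),
               -width_from_screenshots(53.3, 1.26, 111.6, 26.45, 100))
  expect_error(width_from_screenshots(0, 1, 5, 1, 100),
               class = "edcal_invalid_input")
})

test_that("rate_fit tidy/glance/autoplot behave", {
  log <- make_angle_log(2.95, 20, duplicate_pairs = TRUE,
                        time_jitter_sd = 0.03, seed = 77)
  fit <- fit_rate(log)
  expect_equal(tidy(fit)$estimate[2], fit$rate)
  gl <- glance(fit)
  expect_named(gl, c("rate", "rate_se", "oscillation_width", "phi_total",
                     "phi_range_raw", "rms_residual", "n_used",
                     "dedup_applied"))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_gt(nrow(fit$segments), 1) # piecewise-slope diagnostic present
})
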