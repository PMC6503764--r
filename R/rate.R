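#' Parse a goniometer angle log
#'
#' Reads the three-column ASCII dialect written by a stage-angle recording
#' script: one record per line, `t_before t_after alpha`, whitespace
#' separated, `#` starting a comment. `t_before` and `t_after` bracket the
#' call for the stage angle, so the angle's true timestamp lies between
#' them; the half-width of that bracket is the x-uncertainty used by
#' [fit_rate()]. Some readout loops report each angle twice on consecutive
#' records; such logs parse unchanged — deduplication is a fit-time option.
#'
#' @param source Path to a log file, or a character vector of lines.
#' @return A tibble of class `angle_log` with columns `t_before`, `t_after`,
#'   `alpha` (degrees).
#' @export
parse_angle_log <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source)
  } else {
    as.character(source)
  }
  raw <- sub("#.*$", "", lines)
  keep <- which(trimws(raw) != "")
  parse_one <- function(i) {
    tok <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(tok) != 3 || any(is.na(vals))) {
      rlang::abort(sprintf("malformed angle-log record at line %d: %s",
                           i, trimws(lines[i])),
                   class = "edcal_parse_error")
    }
    if (vals[2] < vals[1]) {
      rlang::abort(sprintf("t_after < t_before at line %d.", i),
                   class = "edcal_validation_error")
    }
    vals
  }
  recs <- t(vapply(keep, parse_one, numeric(3)))
  if (nrow(recs) < 2) {
    rlang::abort("need at least 2 angle records.",
                 class = "edcal_insufficient_data")
  }
  out <- tibble::tibble(t_before = recs[, 1], t_after = recs[, 2],
                        alpha = recs[, 3])
  structure(out, class = c("angle_log", class(out)))
}

#' Write an angle log
#'
#' Inverse of [parse_angle_log()]; deterministic formatting.
#'
#' @param log A tibble with columns `t_before`, `t_after`, `alpha`.
#' @param path Output file.
#' @export
write_angle_log <- function(log, path) {
  lines <- sprintf("%.6f %.6f %.6f", log$t_before, log$t_after, log$alpha)
  writeLines(c("# t_before t_after alpha", lines), path)
  invisible(path)
}

#' Fit the goniometer rotation rate
#'
#' Straight-line fit of stage angle versus time. The abscissa of each
#' record is the bracket midpoint `(t_before + t_after)/2` with
#' x-uncertainty `0.5 (t_after - t_before)`; the x-errors are propagated
#' into weights through the slope in a two-pass scheme: an ordinary
#' least-squares fit gives a slope estimate, the x-variances are converted
#' to y-variances via that slope, and the line is refit with
#' inverse-variance weights. With equal x-errors this reduces exactly to
#' ordinary least squares. The oscillation width per detector frame is the
#' fitted rate divided by the readout frequency nu. A negative rate (and
#' hence a negative width) denotes reverse rotation.
#'
#' Also reported: `phi_total` = |rate| times the time span (total rotation
#' covered), the raw angular range max - min of alpha, the residual RMS,
#' and a piecewise-slope diagnostic (`segments`) that makes a non-constant
#' rotation rate — e.g. from an unbalanced load on the stage — visible
#' without modelling it.
#'
#' @param log An `angle_log` (from [parse_angle_log()] or
#'   [make_angle_log()]).
#' @param frame_rate Detector readout frequency nu, Hz.
#' @param dedup Collapse consecutive duplicate-angle pairs (an artefact of
#'   readout loops that report each angle twice) to their midpoint record
#'   before fitting. Default `FALSE`: the duplicates carry real timing
#'   information.
#' @param n_segments Number of equal-time segments for the piecewise-slope
#'   diagnostic (default 4).
#' @return Object of class `rate_fit`: `rate` and `rate_se` (deg/s),
#'   `intercept`, `oscillation_width` (deg/frame at `frame_rate`),
#'   `phi_total`, `phi_range_raw`, `rms_residual`, `n_used`,
#'   `dedup_applied`, `segments` (tibble of per-segment slopes),
#'   `frame_rate`, `data` (the fitted x/y table).
#' @export
fit_rate <- function(log, frame_rate = 100, dedup = FALSE, n_segments = 4) {
  log <- tibble::as_tibble(log)
  stopifnot(all(c("t_before", "t_after", "alpha") %in% names(log)))
  if (frame_rate <= 0) {
    rlang::abort("`frame_rate` must be positive.",
                 class = "edcal_invalid_input")
  }
  if (dedup) log <- dedup_pairs(log)
  x <- (log$t_before + log$t_after) / 2
  sx <- 0.5 * (log$t_after - log$t_before)
  y <- log$alpha
  if (length(unique(x)) < 2) {
    rlang::abort("need >= 2 records with distinct midpoint times.",
                 class = "edcal_insufficient_data")
  }
  if (all(y == y[1])) {
    rlang::warn("all angles identical: zero-rate degenerate fit.")
    return(new_rate_fit(0, 0, y[1], frame_rate, x, y, dedup, n_segments))
  }

  fit0 <- stats::lm(y ~ x)
  slope0 <- unname(stats::coef(fit0)[2])
  varx <- (slope0 * sx)^2
  if (diff(range(varx)) < 1e-300) {
    fit <- fit0 # equal x-errors: plain least squares
  } else {
    w <- 1 / pmax(varx, max(varx) * 1e-6) # floor protects zero-width brackets
    fit <- stats::lm(y ~ x, weights = w)
  }
  co <- suppressWarnings(summary(fit))$coefficients # noiseless logs are fine
  rate <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]

  # mixed-direction check: both signs well represented among the large
  # angle steps means the stage reversed, not just readout noise
  dy <- diff(y[order(x)])
  big <- dy[abs(dy) > 0.25 * max(abs(dy))]
  if (length(big) > 0) {
    minority <- min(mean(big > 0), mean(big < 0))
    if (minority > 0.1) {
      rlang::warn("angle sequence changes direction beyond noise: mixed-direction log.")
    }
  }
  new_rate_fit(rate, se, unname(stats::coef(fit)[1]), frame_rate, x, y,
               dedup, n_segments, resid = stats::resid(fit))
}

dedup_pairs <- function(log) {
  n <- nrow(log)
  drop <- logical(n)
  out <- log
  i <- 1
  rows <- list()
  while (i <= n) {
    if (i < n && log$alpha[i + 1] == log$alpha[i]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        t_before = (log$t_before[i] + log$t_before[i + 1]) / 2,
        t_after = (log$t_after[i] + log$t_after[i + 1]) / 2,
        alpha = log$alpha[i]
      )
      i <- i + 2
    } else {
      rows[[length(rows) + 1]] <- log[i, c("t_before", "t_after", "alpha")]
      i <- i + 1
    }
  }
  dplyr::bind_rows(rows)
}

new_rate_fit <- function(rate, se, intercept, frame_rate, x, y,
                         dedup, n_segments, resid = rep(0, length(x))) {
  seg_id <- cut(x, breaks = max(2, n_segments), labels = FALSE)
  segments <- purrr::map_dfr(split(seq_along(x), seg_id), function(idx) {
    if (length(idx) < 2 || length(unique(x[idx])) < 2) return(NULL)
    tibble::tibble(
      t_mid = mean(x[idx]),
      slope = unname(stats::coef(stats::lm(y[idx] ~ x[idx]))[2]),
      n = length(idx)
    )
  })
  structure(
    list(rate = rate, rate_se = se, intercept = intercept,
         oscillation_width = rate / frame_rate,
         phi_total = abs(rate) * (max(x) - min(x)),
         phi_range_raw = max(y) - min(y),
         rms_residual = sqrt(mean(resid^2)),
         n_used = length(x), dedup_applied = dedup,
         segments = segments, frame_rate = frame_rate,
         data = tibble::tibble(t = x, alpha = y)),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit>\n")
  cat(sprintf("  rate              %.4f +/- %.4f deg/s (n = %d%s)\n",
              x$rate, x$rate_se, x$n_used,
              if (x$dedup_applied) ", dedup" else ""))
  cat(sprintf("  oscillation width %.6f deg/frame at %g Hz\n",
              x$oscillation_width, x$frame_rate))
  cat(sprintf("  phi_total         %.1f deg (raw range %.1f deg)\n",
              x$phi_total, x$phi_range_raw))
  invisible(x)
}

#' @describeIn fit_rate Coefficient-style tidy output.
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "rate"),
    estimate = c(x$intercept, x$rate),
    std.error = c(NA_real_, x$rate_se)
  )
}

#' @describeIn fit_rate One-row fit summary.
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    rate = x$rate, rate_se = x$rate_se,
    oscillation_width = x$oscillation_width,
    phi_total = x$phi_total, phi_range_raw = x$phi_range_raw,
    rms_residual = x$rms_residual, n_used = x$n_used,
    dedup_applied = x$dedup_applied
  )
}

#' @describeIn fit_rate Angle-versus-time plot with the fitted line.
#' @param object A `rate_fit`.
#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$alpha)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$rate,
                         colour = "red") +
    ggplot2::labs(x = "time (s)", y = expression(alpha ~ "(deg)"),
                  title = sprintf("rate %.4f +/- %.4f deg/s",
                                  object$rate, object$rate_se))
}

#' Oscillation width from two movie screenshots
#'
#' Fallback for microscopes without a digital angle readout: the stage
#' display is filmed, two screenshots give two (angle, time) pairs, and the
#' oscillation width per frame is the implied rotation rate divided by the
#' detector readout frequency.
#'
#' @param alpha1,alpha2 Stage angles on the two screenshots, degrees.
#' @param t1,t2 Movie timestamps of the screenshots, s.
#' @param frame_rate Detector readout frequency nu, Hz.
#' @return Oscillation width, degrees per frame (signed).
#' @examples
#' width_from_screenshots(53.3, 1.26, 111.6, 26.45, 100) # 0.023144
#' @export
width_from_screenshots <- function(alpha1, t1, alpha2, t2, frame_rate = 100) {
  if (t2 == t1) {
    rlang::abort("screenshots have identical timestamps.",
                 class = "edcal_invalid_input")
  }
  ((alpha2 - alpha1) / (t2 - t1)) / frame_rate
}
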