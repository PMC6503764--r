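#' Assign found peaks to powder rings
#'
#' Sorts a peak list by radial distance from the direct-beam position and
#' assigns each peak to the calibrant ring whose predicted radius (from the
#' ring's d-spacing, the wavelength and a detector-distance guess) is
#' nearest, provided the relative radial deviation is within a tolerance.
#' Peaks outside every tolerance window stay unassigned. The distance guess
#' only needs to be right within roughly a factor of two for the nearest
#' predicted ring to be the correct one at the default tolerance.
#'
#' @param peaks Tibble/data frame with columns `x`, `y` (px) and optionally
#'   `frame`, `intensity` — the format read by [read_peaks()].
#' @param center Direct-beam position `c(fast, slow)` in px.
#' @param standard An [fcc_standard()] giving the ring d-spacings.
#' @param wavelength Electron wavelength, Angstrom.
#' @param distance_guess Approximate detector distance, mm.
#' @param pixel_size Pixel pitch, mm.
#' @param tolerance Maximum relative radial deviation for assignment,
#'   in (0, 0.5); default 0.05.
#' @param refine_scale Refine the distance guess by a global radial scale
#'   search in \[0.5, 2\] before assigning (default `TRUE`); with it the
#'   guess only needs to be right within a factor of two.
#' @return The peak tibble with added columns `r` (measured radius, px),
#'   `ring` (1-based ring index or `NA`), `d` (assigned d-spacing or `NA`)
#'   and `r_pred` (predicted ring radius or `NA`).
#' @export
assign_peaks_to_rings <- function(peaks, center, standard, wavelength,
                                  distance_guess, pixel_size,
                                  tolerance = 0.05, refine_scale = TRUE) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) {
    rlang::abort("empty peak list.", class = "edcal_invalid_input")
  }
  if (tolerance <= 0 || tolerance >= 0.5) {
    rlang::abort("`tolerance` must be in (0, 0.5).",
                 class = "edcal_invalid_input")
  }
  stopifnot(inherits(standard, "fcc_standard"))
  r_pred <- ring_radius(standard$rings$d, wavelength, distance_guess,
                        pixel_size)
  r <- sqrt((peaks$x - center[1])^2 + (peaks$y - center[2])^2)
  if (refine_scale) {
    # adjacent calibrant rings can sit within a few percent of each other in
    # radius, so a rough distance guess must first be refined globally: pick
    # the scale in [0.5, 2] that lets the most peaks match a predicted ring
    scales <- exp(seq(log(0.5), log(2), length.out = 561))
    score <- vapply(scales, function(s) {
      dev <- vapply(r, function(ri) min(abs(s * r_pred - ri) / (s * r_pred)),
                    numeric(1))
      sum(dev <= tolerance) - mean(pmin(dev, tolerance))
    }, numeric(1))
    r_pred <- scales[which.max(score)] * r_pred
  }
  nearest <- vapply(r, function(ri) which.min(abs(r_pred - ri)), integer(1))
  dev <- abs(r - r_pred[nearest]) / r_pred[nearest]
  ok <- dev <= tolerance
  out <- peaks |>
    dplyr::mutate(
      r = r,
      ring = ifelse(ok, nearest, NA_integer_),
      d = ifelse(ok, standard$rings$d[nearest], NA_real_),
      r_pred = ifelse(ok, r_pred[nearest], NA_real_)
    ) |>
    dplyr::arrange(.data$r)
  counts <- table(out$ring)
  if (length(counts) == 0 || max(counts) < 5) {
    rlang::warn("no ring received >= 5 peaks; check the distance guess and beam center.")
  }
  out
}

#' Per-ring ellipse fits and effective detector distances
#'
#' The full ring-calibration workflow: for each powder ring with enough
#' assigned peaks, fit an ellipse, report the axis ratio and ellipticity,
#' and convert both semi-axes into effective detector distances via the
#' exact Bragg geometry. Because the elliptical distortion makes A and B
#' differ, the two distances per ring differ by the factor A/B; which one
#' is the true camera length cannot be decided from the powder standard
#' alone and must be resolved against a sample with known unit-cell
#' parameters. The distortion itself is reported, not corrected.
#'
#' @param assigned Output of [assign_peaks_to_rings()], or any tibble with
#'   columns `x`, `y`, `ring`, `d`.
#' @param wavelength Electron wavelength, Angstrom.
#' @param pixel_size Pixel pitch, mm.
#' @param min_peaks Minimum peaks per ring to attempt a fit (default 5).
#' @return A tibble of class `ring_calibration`, one row per fitted ring:
#'   `ring`, `d`, `n_points`, `center_x`, `center_y`, `semi_major`,
#'   `semi_minor`, `axis_ratio`, `ellipticity`, `orientation`,
#'   `rms_residual`, `distance_from_A`, `distance_from_B`. Attributes:
#'   `summary` (means and standard deviations of the distances),
#'   `ambiguity` (note on resolving A vs B), `spread_flag` (TRUE when the
#'   per-ring distance spread exceeds 1 percent of the mean, which usually
#'   signals a mis-assigned d value).
#' @export
calibrate_distance <- function(assigned, wavelength, pixel_size,
                               min_peaks = 5) {
  assigned <- tibble::as_tibble(assigned)
  if (nrow(assigned) == 0) {
    rlang::abort("empty ring list.", class = "edcal_invalid_input")
  }
  rings <- assigned |>
    dplyr::filter(!is.na(.data$ring)) |>
    dplyr::group_by(.data$ring, .data$d) |>
    dplyr::filter(dplyr::n() >= min_peaks) |>
    dplyr::group_split()
  if (length(rings) == 0) {
    rlang::abort("no ring has enough assigned peaks to fit.",
                 class = "edcal_insufficient_data")
  }
  rows <- purrr::map_dfr(rings, function(g) {
    fit <- fit_ellipse(cbind(g$x, g$y))
    tibble::tibble(
      ring = g$ring[1],
      d = g$d[1],
      n_points = fit$n_points,
      center_x = fit$center[1],
      center_y = fit$center[2],
      semi_major = fit$semi_major,
      semi_minor = fit$semi_minor,
      axis_ratio = fit$semi_major / fit$semi_minor,
      ellipticity = fit$ellipticity,
      orientation = fit$orientation,
      rms_residual = fit$rms_residual,
      distance_from_A = distance_from_radius(fit$semi_major, g$d[1],
                                             wavelength, pixel_size),
      distance_from_B = distance_from_radius(fit$semi_minor, g$d[1],
                                             wavelength, pixel_size)
    )
  })
  smry <- tibble::tibble(
    axis = c("A", "B"),
    mean_distance = c(mean(rows$distance_from_A), mean(rows$distance_from_B)),
    sd_distance = c(stats::sd(rows$distance_from_A),
                    stats::sd(rows$distance_from_B))
  )
  spread <- with(smry, sd_distance / mean_distance)
  spread_flag <- any(is.finite(spread) & spread > 0.01)
  structure(
    rows,
    summary = smry,
    spread_flag = spread_flag,
    ambiguity = paste(
      "distance_from_A and distance_from_B differ by the distortion ratio",
      "A/B; resolve the ambiguity with a sample of known unit-cell",
      "parameters."),
    class = c("ring_calibration", class(rows))
  )
}

#' @describeIn calibrate_distance One-row summary across rings.
#' @param x A `ring_calibration`.
#' @param ... Unused.
#' @method glance ring_calibration
#' @export
glance.ring_calibration <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(
    n_rings = nrow(x),
    mean_distance_A = s$mean_distance[1],
    sd_distance_A = s$sd_distance[1],
    mean_distance_B = s$mean_distance[2],
    sd_distance_B = s$sd_distance[2],
    mean_ellipticity = mean(x$ellipticity),
    spread_flag = attr(x, "spread_flag")
  )
}

#' @describeIn calibrate_distance Per-ring distances and ellipticities.
#' @param object A `ring_calibration`.
#' @method autoplot ring_calibration
#' @export
autoplot.ring_calibration <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("distance_from_A", "distance_from_B"),
                        names_to = "axis", values_to = "distance") |>
    dplyr::mutate(axis = sub("distance_from_", "", .data$axis))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$distance,
                                   colour = .data$axis)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "ring d-spacing (Å)",
                  y = "effective detector distance (mm)",
                  colour = "semi-axis")
}
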