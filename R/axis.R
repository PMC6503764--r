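#' Frame stack container
#'
#' An ordered set of equally shaped pixel-count images with per-frame
#' metadata, as produced by an area detector recording an oscillating
#' powder standard (or by [make_powder_frames()]).
#'
#' Frames are stored as `n_slow x n_fast` matrices: the first array index
#' is the slow axis, the second the fast axis, both 0-based in all pixel
#' coordinates used by this package.
#'
#' @param frames List of numeric matrices, all the same shape, counts >= 0.
#' @param detector A [detector_spec()]; inferred from the first frame's
#'   shape if omitted.
#' @param exposure Per-frame exposure in seconds (recycled).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, detector = NULL, exposure = NA_real_) {
  if (!is.list(frames) || length(frames) == 0) {
    rlang::abort("`frames` must be a non-empty list of matrices.",
                 class = "edcal_invalid_input")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rlang::abort("all frames must have the same shape.",
                 class = "edcal_shape_mismatch")
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    rlang::abort("counts must be >= 0.", class = "edcal_invalid_input")
  }
  if (is.null(detector)) {
    detector <- detector_spec(n_fast = dims[2, 1], n_slow = dims[1, 1])
  }
  structure(
    list(frames = frames,
         meta = tibble::tibble(frame = seq_along(frames) - 1L,
                               exposure = rep_len(exposure, length(frames))),
         detector = detector),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  invisible(x)
}

#' Sum frames of a stack
#'
#' Element-wise sum over a frame range. Summing at least one full
#' oscillation period of a wobbled powder standard produces the image in
#' which reflections on the rotation axis, which stay in diffracting
#' condition throughout the oscillation, appear as intensity maxima on each
#' ring — and a reflection-free segment on the axis as the easier-to-spot
#' minimum. Sums are accumulated in doubles, so 16-bit frames cannot
#' overflow for any realistic stack length.
#'
#' @param stack A [frame_stack()].
#' @param frame_range Integer indices (1-based into the stack) to sum;
#'   default all frames.
#' @return A numeric matrix of summed counts.
#' @export
sum_frames <- function(stack, frame_range = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(frame_range)) frame_range <- seq_along(stack$frames)
  if (length(frame_range) == 0) {
    rlang::abort("empty frame range.", class = "edcal_invalid_input")
  }
  if (any(frame_range < 1) || any(frame_range > length(stack$frames))) {
    rlang::abort("frame range exceeds the stack.",
                 class = "edcal_invalid_input")
  }
  Reduce(`+`, lapply(stack$frames[frame_range], function(f) f * 1.0))
}

#' Azimuthal intensity profile of an annulus
#'
#' Averages pixel values in an annulus around a centre into azimuthal bins.
#' Azimuth is measured from the +fast axis towards the +slow axis (i.e.
#' counter-clockwise in array index space), in degrees in [0, 360). Bins
#' that receive no pixel are marked invalid (`NA`), not zero.
#'
#' @param image Numeric matrix (`n_slow x n_fast`).
#' @param center `c(fast, slow)` pixel position of the direct beam (0-based).
#' @param r_inner,r_outer Annulus radii, px, `0 < r_inner < r_outer`.
#' @param n_bins Number of azimuthal bins (>= 36, default 180).
#' @return A tibble of class `azimuthal_profile` with columns `bin`,
#'   `azimuth` (bin centre, degrees) and `intensity` (mean counts/pixel);
#'   attributes `annulus`, `center`, `n_bins`.
#' @export
azimuthal_profile <- function(image, center, r_inner, r_outer,
                              n_bins = 180) {
  stopifnot(is.matrix(image))
  if (!(r_inner > 0 && r_outer > r_inner)) {
    rlang::abort("need 0 < r_inner < r_outer.", class = "edcal_invalid_input")
  }
  if (n_bins < 36) {
    rlang::abort("`n_bins` must be >= 36.", class = "edcal_invalid_input")
  }
  ns <- nrow(image); nf <- ncol(image)
  # 0-based pixel-centre coordinates
  fast <- matrix(rep(0:(nf - 1), each = ns), ns, nf)
  slow <- matrix(rep(0:(ns - 1), times = nf), ns, nf)
  dx <- fast - center[1]; dy <- slow - center[2]
  r <- sqrt(dx^2 + dy^2)
  sel <- r >= r_inner & r <= r_outer
  if (!any(sel)) {
    rlang::abort("annulus lies fully outside the image.",
                 class = "edcal_invalid_input")
  }
  az <- (atan2(dy[sel], dx[sel]) * 180 / pi) %% 360
  bin <- pmin(floor(az / (360 / n_bins)) + 1L, n_bins)
  sums <- tapply(image[sel], bin, mean)
  intensity <- rep(NA_real_, n_bins)
  intensity[as.integer(names(sums))] <- as.numeric(sums)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    azimuth = (seq_len(n_bins) - 0.5) * 360 / n_bins,
    intensity = intensity
  )
  structure(out,
            annulus = c(r_inner = r_inner, r_outer = r_outer),
            center = center, n_bins = n_bins,
            class = c("azimuthal_profile", class(out)))
}

#' Rotation-axis azimuth from an azimuthal profile
#'
#' Formalises the by-eye procedure of drawing a line through the ring
#' minimum and the direct-beam position: the profile is smoothed with a
#' circular moving average, the two lowest local minima are located, their
#' antipodality (180 deg apart within a tolerance) is verified, and the
#' axis azimuth is the circular mean of the folded pair, reported mod 180.
#' The twofold direction ambiguity is deliberately left unresolved (both
#' directed candidates are returned); resolving it requires indexing
#' statistics from the downstream integration program. The minimum is used
#' rather than the maximum because a reflection-free segment on the axis is
#' easier to detect; the smoothed maximum is reported too.
#'
#' @param profile An [azimuthal_profile()].
#' @param smoothing_window Odd circular moving-average width in bins,
#'   default 5.
#' @param antipodal_tol Allowed deviation of the two minima from 180 deg
#'   separation, degrees (default 10).
#' @param min_contrast Minimum profile contrast (max-min)/(max+min) below
#'   which the pattern is considered unmodulated (default 0.05), e.g. a
#'   static, non-oscillated powder pattern.
#' @return Object of class `axis_estimate`: `azimuth` (deg, mod 180),
#'   `candidates` (c(psi, psi+180)), `contrast`, `max_azimuth` (smoothed
#'   argmax), `annulus`, `center`.
#' @export
find_axis <- function(profile, smoothing_window = 5, antipodal_tol = 10,
                      min_contrast = 0.05) {
  stopifnot(inherits(profile, "azimuthal_profile"))
  v <- profile$intensity
  ok <- is.finite(v)
  if (sum(ok) < 36) {
    rlang::abort("need >= 36 valid bins.", class = "edcal_insufficient_data")
  }
  if (smoothing_window %% 2 != 1 || smoothing_window < 1) {
    rlang::abort("`smoothing_window` must be odd and positive.",
                 class = "edcal_invalid_input")
  }
  n <- length(v)
  # circular moving average, NA bins interpolated from neighbours
  vv <- v
  if (any(!ok)) {
    az <- profile$azimuth
    vv[!ok] <- stats::approx(az[ok], v[ok], xout = az[!ok],
                             rule = 2)$y
  }
  k <- (smoothing_window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    idx <- ((i - k - 1):(i + k - 1)) %% n + 1
    mean(vv[idx])
  }, numeric(1))
  contrast <- (max(sm) - min(sm)) / (max(sm) + min(sm))
  if (!is.finite(contrast) || contrast < min_contrast) {
    rlang::abort(
      sprintf("profile contrast %.4f below %.2f: no azimuthal modulation (is the pattern oscillated?).",
              contrast, min_contrast),
      class = "edcal_no_modulation")
  }
  # local minima on the circle
  left <- sm[c(n, 1:(n - 1))]; right <- sm[c(2:n, 1)]
  is_min <- sm <= left & sm <= right
  minima <- order(sm)[order(sm) %in% which(is_min)]
  if (length(minima) < 2) {
    rlang::abort("fewer than two local minima found.",
                 class = "edcal_ambiguous_profile")
  }
  i1 <- minima[1]
  az1 <- profile$azimuth[i1]
  # deepest local minimum in the antipodal window; if none lies within the
  # tolerance, fall back to the deepest one beyond 90 deg so the error
  # message can report how far from antipodal it is
  sep <- abs(((profile$azimuth[minima] - az1 + 180) %% 360) - 180)
  anti <- minima[sep >= 180 - antipodal_tol]
  far <- minima[sep > 90]
  if (length(far) == 0) {
    rlang::abort("second minimum not found opposite the first.",
                 class = "edcal_ambiguous_profile")
  }
  i2 <- if (length(anti) > 0) anti[1] else far[1]
  az2 <- profile$azimuth[i2]
  gap <- abs(abs(((az2 - az1 + 180) %% 360) - 180) - 180) # deviation from 180
  if (gap > antipodal_tol) {
    rlang::abort(
      sprintf("minima are %.1f deg from antipodal (tol %.1f): ambiguous profile.",
              gap, antipodal_tol),
      class = "edcal_ambiguous_profile")
  }
  # fold both minima to [0, 180) and average on the half-circle
  f1 <- az1 %% 180; f2 <- az2 %% 180
  dfold <- ((f2 - f1 + 90) %% 180) - 90
  psi_argmin <- (f1 + dfold / 2) %% 180
  # sub-bin refinement: phase of the second circular harmonic, which is
  # exact for a cos^2 modulation and orthogonal both to the flat background
  # and to the 4-theta pixel-sampling artifact of square-grid binning
  th2 <- 2 * profile$azimuth * pi / 180
  psi_h <- (0.5 * atan2(-sum(vv * sin(th2)), -sum(vv * cos(th2))) *
              180 / pi) %% 180
  dis <- abs(((psi_h - psi_argmin + 90) %% 180) - 90)
  if (dis > 15) {
    rlang::warn(sprintf(
      "harmonic phase (%.1f deg) and folded argmin (%.1f deg) disagree by %.1f deg; profile may not be cos^2-like.",
      psi_h, psi_argmin, dis))
  }
  psi <- psi_h
  structure(
    list(azimuth = psi,
         candidates = c(psi, psi + 180),
         contrast = contrast,
         max_azimuth = profile$azimuth[which.max(sm)],
         annulus = attr(profile, "annulus"),
         center = attr(profile, "center")),
    class = "axis_estimate"
  )
}

#' @export
print.axis_estimate <- function(x, ...) {
  cat("<axis_estimate>\n")
  cat(sprintf("  azimuth    %.2f deg (mod 180)\n", x$azimuth))
  cat(sprintf("  candidates %.2f / %.2f deg (twofold ambiguity unresolved)\n",
              x$candidates[1], x$candidates[2]))
  cat(sprintf("  contrast   %.3f\n", x$contrast))
  invisible(x)
}

#' Directed rotation-axis vectors
#'
#' Both directed unit 3-vectors compatible with an azimuth estimate, in the
#' laboratory frame with the beam along (0, 0, 1): `(cos psi, sin psi, 0)`
#' and its negation. Which of the two is correct is resolved downstream.
#'
#' @param est An `axis_estimate` (or a bare azimuth in degrees).
#' @return A 2 x 3 matrix; rows are the two candidates.
#' @export
axis_vector <- function(est) {
  psi <- if (inherits(est, "axis_estimate")) est$azimuth else est
  p <- psi * pi / 180
  v <- c(cos(p), sin(p), 0)
  rbind(v, -v, deparse.level = 0)
}

#' @describeIn azimuthal_profile Plot the profile with any axis estimate.
#' @param object An `azimuthal_profile`.
#' @param axis Optional `axis_estimate` to mark.
#' @param ... Unused.
#' @method autoplot azimuthal_profile
#' @export
autoplot.azimuthal_profile <- function(object, axis = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$azimuth, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "azimuth (deg from +fast axis)",
                  y = "mean counts / pixel")
  if (!is.null(axis)) {
    p <- p + ggplot2::geom_vline(xintercept = axis$candidates %% 360,
                                 linetype = "dashed")
  }
  p
}
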