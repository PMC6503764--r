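#' Synthetic calibration scene
#'
#' Ground-truth description of a simulated calibration session: an
#' aluminium powder standard oscillated on the stage of a 200 kV microscope
#' and recorded on an EIGER-style 75 micrometre hybrid pixel detector at
#' 100 Hz. Every estimator in the package can be exercised against the
#' known truth stored here. Defaults reproduce the conditions of a typical
#' calibration: effective detector distance 500 mm, elliptical distortion
#' of 2.3 percent, azimuthal modulation depth 0.5 from a +/-15 degree
#' oscillation, direct beam near the detector centre.
#'
#' @param distance True effective detector distance, mm.
#' @param origin Direct-beam position `c(fast, slow)`, px.
#' @param axis_azimuth True rotation-axis azimuth, degrees.
#' @param oscillation_width True oscillation width, deg/frame.
#' @param ellipticity True distortion e = A/B - 1.
#' @param distortion_orientation Major-axis azimuth of the distortion, deg.
#' @param modulation_depth Depth m of the azimuthal ring modulation
#'   `1 - m cos^2(theta - psi0)`, in [0, 1).
#' @param background Flat background, counts/pixel (per summed image).
#' @param peak_amplitude Ring amplitude at its crest, counts/pixel.
#' @param ring_sigma Radial Gaussian width of the drawn rings, px.
#' @param noise `"poisson"` or `"none"`.
#' @param voltage Accelerating voltage, V.
#' @param standard An [fcc_standard()].
#' @param detector A [detector_spec()].
#' @return A list of class `synthetic_scene` with the above plus the
#'   derived `geometry` ([geometry_model()]).
#' @export
synthetic_scene <- function(distance = 500,
                            origin = c(508, 530),
                            axis_azimuth = 37,
                            oscillation_width = 0.0295,
                            ellipticity = 0.023,
                            distortion_orientation = 20,
                            modulation_depth = 0.5,
                            background = 10,
                            peak_amplitude = 100,
                            ring_sigma = 2,
                            noise = c("poisson", "none"),
                            voltage = 200e3,
                            standard = al_standard(),
                            detector = detector_spec()) {
  noise <- match.arg(noise)
  if (modulation_depth < 0 || modulation_depth >= 1) {
    rlang::abort("`modulation_depth` must be in [0, 1).",
                 class = "edcal_invalid_input")
  }
  if (background < 0 || peak_amplitude < 0) {
    rlang::abort("amplitudes must be >= 0.", class = "edcal_invalid_input")
  }
  beam <- beam_spec(voltage)
  geometry <- geometry_model(distance, origin, axis_azimuth %% 180,
                             oscillation_width, beam, detector)
  structure(
    list(geometry = geometry, standard = standard,
         ellipticity = ellipticity,
         distortion_orientation = distortion_orientation %% 180,
         axis_azimuth = axis_azimuth %% 180,
         modulation_depth = modulation_depth,
         background = background, peak_amplitude = peak_amplitude,
         ring_sigma = ring_sigma, noise = noise),
    class = "synthetic_scene"
  )
}

# ellipse radius at detector azimuth theta (radians) for a ring whose
# undistorted radius r0 is the semi-minor axis and whose major axis
# r0 * (1 + e) lies at orientation phi_d
.distorted_radius <- function(r0, e, phi_d, theta) {
  A <- r0 * (1 + e); B <- r0
  A * B / sqrt((B * cos(theta - phi_d))^2 + (A * sin(theta - phi_d))^2)
}

#' Simulate a calibrant peak list
#'
#' Places peaks exactly on each powder ring's distorted ellipse (radius per
#' azimuth set by the scene's ellipticity and distortion orientation),
#' optionally with isotropic Gaussian jitter. Rings whose radius falls
#' outside the detector are skipped. The returned tibble carries the true
#' ring membership in `ring_true`, so assignment and fitting can be scored
#' against construction labels.
#'
#' @param scene A [synthetic_scene()].
#' @param n_per_ring Peaks per ring (>= 5).
#' @param jitter_sd Gaussian positional jitter per coordinate, px.
#' @param n_outliers Uniform-random outlier peaks to add (label `NA`).
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with `x`, `y`, `frame`, `intensity`, `ring_true`, `d_true`.
#' @export
make_peaklist <- function(scene, n_per_ring = 36, jitter_sd = 0,
                          n_outliers = 0, seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (n_per_ring < 5) {
    rlang::abort("`n_per_ring` must be >= 5.", class = "edcal_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  g <- scene$geometry
  det <- g$detector
  r0 <- ring_radius(scene$standard$rings$d, g$beam$wavelength,
                    g$distance, det$pixel_size)
  max_r <- min(g$origin[1], det$n_fast - 1 - g$origin[1],
               g$origin[2], det$n_slow - 1 - g$origin[2])
  keep <- which(r0 * (1 + scene$ellipticity) < max_r)
  phi_d <- scene$distortion_orientation * pi / 180
  psi0 <- scene$axis_azimuth * pi / 180
  rings <- purrr::map_dfr(keep, function(i) {
    th <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
    r <- .distorted_radius(r0[i], scene$ellipticity, phi_d, th)
    x <- g$origin[1] + r * cos(th)
    y <- g$origin[2] + r * sin(th)
    if (jitter_sd > 0) {
      x <- x + stats::rnorm(n_per_ring, 0, jitter_sd)
      y <- y + stats::rnorm(n_per_ring, 0, jitter_sd)
    }
    tibble::tibble(
      x = x, y = y, frame = 1,
      intensity = scene$peak_amplitude *
        (1 - scene$modulation_depth * cos(th - psi0)^2) + scene$background,
      ring_true = i, d_true = scene$standard$rings$d[i]
    )
  })
  if (n_outliers > 0) {
    rings <- dplyr::bind_rows(rings, tibble::tibble(
      x = stats::runif(n_outliers, 0, det$n_fast - 1),
      y = stats::runif(n_outliers, 0, det$n_slow - 1),
      frame = 1,
      intensity = scene$background,
      ring_true = NA_integer_, d_true = NA_real_
    ))
  }
  rings
}

#' Simulate oscillating powder frames
#'
#' Draws each frame as a flat background plus Gaussian-profile elliptical
#' annuli at the calibrant ring radii, with azimuthal intensity
#' `1 - m cos^2(theta - psi0)`. This mimics the summed appearance of a
#' powder pattern recorded while the stage oscillates: reflections on or
#' near the rotation axis stay in diffracting condition and pile up there,
#' while a reflection-free segment on the axis stays reflection-free — the
#' minimum the axis finder locates. The cosine-squared form of the
#' modulation is a modelling choice; only the existence and position of the
#' extrema matter to the estimator. A direct-beam blob is added and clipped at
#' the detector saturation count. Expected intensity is split evenly across
#' frames so the sum over the stack carries the scene's nominal amplitudes;
#' Poisson noise, when enabled, is sampled per frame.
#'
#' @param scene A [synthetic_scene()].
#' @param n_frames Number of frames (>= 1).
#' @param rings Indices into the standard's ring list to draw; default the
#'   strongest (largest-d) ring that fits the detector.
#' @param seed Optional integer seed.
#' @return A [frame_stack()].
#' @export
make_powder_frames <- function(scene, n_frames = 1, rings = NULL,
                               seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- scene$geometry
  det <- g$detector
  ns <- det$n_slow; nf <- det$n_fast
  r0 <- ring_radius(scene$standard$rings$d, g$beam$wavelength,
                    g$distance, det$pixel_size)
  max_r <- min(g$origin[1], nf - 1 - g$origin[1],
               g$origin[2], ns - 1 - g$origin[2])
  fitting <- which(r0 * (1 + scene$ellipticity) < max_r)
  if (is.null(rings)) rings <- fitting[1]
  fast <- matrix(rep(0:(nf - 1), each = ns), ns, nf)
  slow <- matrix(rep(0:(ns - 1), times = nf), ns, nf)
  dx <- fast - g$origin[1]; dy <- slow - g$origin[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  phi_d <- scene$distortion_orientation * pi / 180
  psi0 <- scene$axis_azimuth * pi / 180
  expected <- matrix(scene$background, ns, nf)
  for (i in rings) {
    re <- .distorted_radius(r0[i], scene$ellipticity, phi_d, theta)
    expected <- expected + scene$peak_amplitude *
      exp(-(r - re)^2 / (2 * scene$ring_sigma^2)) *
      (1 - scene$modulation_depth * cos(theta - psi0)^2)
  }
  # direct beam: bright Gaussian blob, far above saturation at its core
  beam <- 50 * det$saturation_count * exp(-r^2 / (2 * 1.5^2))
  expected <- expected + beam
  per_frame <- expected / n_frames
  sat <- det$saturation_count
  frames <- lapply(seq_len(n_frames), function(k) {
    f <- if (scene$noise == "poisson") {
      matrix(stats::rpois(length(per_frame), per_frame), ns, nf)
    } else {
      per_frame
    }
    pmin(f, sat)
  })
  frame_stack(frames, det, exposure = 1 / det$frame_rate)
}

#' Simulate a goniometer angle log
#'
#' Emulates the stage-angle recording script: the angle is sampled at a
#' fixed cadence, each readout brackets the call with `t_before`/`t_after`
#' separated by a small positive latency, the true read time can carry
#' Gaussian jitter, and (optionally) every angle value is reported twice on
#' consecutive records, as real readout loops do.
#'
#' @param rate True rotation rate, deg/s (negative = reverse rotation).
#' @param duration Log duration, s.
#' @param sample_interval Readout cadence, s (default 0.5).
#' @param alpha0 Starting angle, degrees.
#' @param duplicate_pairs Report each angle on two consecutive records.
#' @param time_jitter_sd Gaussian jitter of the true read times, s.
#' @param latency Mean call latency `t_after - t_before`, s.
#' @param seed Optional integer seed.
#' @return An `angle_log` tibble (`t_before`, `t_after`, `alpha`).
#' @export
make_angle_log <- function(rate, duration, sample_interval = 0.5,
                           alpha0 = 0, duplicate_pairs = FALSE,
                           time_jitter_sd = 0, latency = 0.02,
                           seed = NULL) {
  if (duration <= sample_interval || sample_interval <= 0) {
    rlang::abort("need duration > sample_interval > 0.",
                 class = "edcal_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  t_nom <- seq(0, duration, by = sample_interval)
  n <- length(t_nom)
  t_true <- t_nom + if (time_jitter_sd > 0) {
    stats::rnorm(n, 0, time_jitter_sd)
  } else 0
  lat <- abs(stats::rnorm(n, latency, latency / 5)) + 1e-4
  alpha_src <- if (duplicate_pairs) {
    t_true[(seq_len(n) - 1) %/% 2 * 2 + 1] # pair start's read time
  } else {
    t_true
  }
  out <- tibble::tibble(
    t_before = t_true - lat / 2,
    t_after = t_true + lat / 2,
    alpha = alpha0 + rate * alpha_src
  )
  structure(out, class = c("angle_log", class(out)))
}
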