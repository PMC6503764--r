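#' Beam specification
#'
#' Bundles the accelerating voltage, the derived relativistic wavelength and
#' the incident-beam direction. The beam direction is (0, 0, 1) by default:
#' for a well aligned microscope the incident beam is close to orthogonal to
#' the detector plane and integration programs refine it from there.
#'
#' @param voltage Accelerating voltage, volts.
#' @param incident_direction Unit 3-vector; default `c(0, 0, 1)`.
#' @return An object of class `beam_spec`: a list with `voltage`,
#'   `wavelength` (Angstrom) and `incident_direction`.
#' @examples
#' beam_spec(200e3)$wavelength
#' @export
beam_spec <- function(voltage, incident_direction = c(0, 0, 1)) {
  lambda <- electron_wavelength(voltage) # validates voltage
  if (length(incident_direction) != 3 ||
      abs(sqrt(sum(incident_direction^2)) - 1) > 1e-9) {
    rlang::abort("`incident_direction` must be a unit 3-vector.",
                 class = "edcal_invalid_input")
  }
  structure(
    list(voltage = voltage, wavelength = lambda,
         incident_direction = as.numeric(incident_direction)),
    class = "beam_spec"
  )
}

#' Detector specification
#'
#' Pixel geometry and timing of the area detector. Defaults describe an
#' EIGER X 1M style hybrid pixel detector: 75 micrometre pixels,
#' 1030 x 1065 pixel grid, 100 Hz frame rate, 16-bit dynamic range.
#'
#' @param pixel_size Pixel pitch in mm (isotropic).
#' @param n_fast,n_slow Pixel counts along the fast and slow axes.
#' @param frame_rate Readout frequency nu, Hz.
#' @param saturation_count Full-well count value.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(pixel_size = 0.075, n_fast = 1030, n_slow = 1065,
                          frame_rate = 100, saturation_count = 65535) {
  if (pixel_size <= 0 || frame_rate <= 0 || n_fast < 1 || n_slow < 1) {
    rlang::abort("detector parameters must be positive; pixel counts >= 1.",
                 class = "edcal_invalid_input")
  }
  structure(
    list(pixel_size = pixel_size, n_fast = as.integer(n_fast),
         n_slow = as.integer(n_slow), frame_rate = frame_rate,
         saturation_count = saturation_count),
    class = "detector_spec"
  )
}

#' Powder calibration standard (fcc)
#'
#' A named fcc calibrant with its lattice constant and derived ring list.
#' `al_standard()` is the aluminium powder standard commonly used to
#' calibrate electron diffractometers; its first nine rings lie at 2.338,
#' 2.025, 1.432, 1.221, 1.169, 1.012, 0.929, 0.905 and 0.827 Angstrom.
#'
#' @param name Calibrant name.
#' @param a Cubic lattice constant, Angstrom.
#' @param d_min Smallest ring d-spacing to tabulate, Angstrom.
#' @return An object of class `fcc_standard` with fields `name`, `a` and
#'   `rings` (the tibble from [fcc_dspacings()]).
#' @examples
#' al_standard()$rings$d
#' @export
fcc_standard <- function(name, a, d_min = 0.8) {
  rings <- fcc_dspacings(a, d_min)
  structure(list(name = name, a = a, rings = rings), class = "fcc_standard")
}

#' @rdname fcc_standard
#' @export
al_standard <- function(d_min = 0.8) {
  # standard room-temperature lattice constant of aluminium
  fcc_standard("aluminium", 4.0495, d_min)
}

#' Experiment geometry model
#'
#' The five experimental parameters a rotation-method integration program
#' needs: rotation-axis orientation, oscillation width per frame, detector
#' distance, detector origin (direct-beam position) and incident-beam
#' direction. The calibration workflow in this package exists to fill in
#' this record; [write_xds_template()] serialises it.
#'
#' @param distance Effective detector distance, mm.
#' @param origin Direct-beam position `c(fast, slow)` in pixels (0-based).
#' @param axis_azimuth Rotation-axis azimuth in the detector plane, degrees
#'   in `[0, 180)`, measured from the +fast axis towards the +slow axis.
#' @param oscillation_width Rotation angle per frame, degrees (signed;
#'   negative means reverse rotation).
#' @param beam A [beam_spec()].
#' @param detector A [detector_spec()].
#' @return An object of class `geometry_model`.
#' @export
geometry_model <- function(distance, origin, axis_azimuth,
                           oscillation_width, beam, detector) {
  stopifnot(inherits(beam, "beam_spec"), inherits(detector, "detector_spec"))
  if (distance <= 0) {
    rlang::abort("`distance` must be positive.", class = "edcal_invalid_input")
  }
  if (length(origin) != 2 || any(origin < 0) ||
      origin[1] > detector$n_fast || origin[2] > detector$n_slow) {
    rlang::abort("`origin` must lie within detector bounds.",
                 class = "edcal_invalid_input")
  }
  if (oscillation_width == 0) {
    rlang::abort("`oscillation_width` must be nonzero.",
                 class = "edcal_invalid_input")
  }
  axis_azimuth <- axis_azimuth %% 180
  structure(
    list(distance = distance, origin = as.numeric(origin),
         axis_azimuth = axis_azimuth, oscillation_width = oscillation_width,
         beam = beam, detector = detector),
    class = "geometry_model"
  )
}

#' @export
print.geometry_model <- function(x, ...) {
  cat("<geometry_model>\n")
  cat(sprintf("  distance          %.4g mm\n", x$distance))
  cat(sprintf("  origin            (%.2f, %.2f) px\n", x$origin[1], x$origin[2]))
  cat(sprintf("  axis azimuth      %.3f deg (mod 180)\n", x$axis_azimuth))
  cat(sprintf("  oscillation width %.6g deg/frame\n", x$oscillation_width))
  cat(sprintf("  wavelength        %.6g A (%.0f kV)\n",
              x$beam$wavelength, x$beam$voltage / 1e3))
  cat(sprintf("  detector          %d x %d px @ %.3g mm, %g Hz\n",
              x$detector$n_fast, x$detector$n_slow,
              x$detector$pixel_size, x$detector$frame_rate))
  invisible(x)
}
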