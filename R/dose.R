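#' Dose per STEM image
#'
#' Electron dose delivered by one HAADF-STEM raster: the probe delivers
#' `I * dwell / e` electrons into each scan pixel, and dividing by the
#' pixel's area on the sample gives the dose in electrons per square
#' Angstrom. The result is independent of the image size (a uniform raster
#' doses every pixel equally) but scales with the square of the
#' magnification, since that sets the scan pixel size on the sample.
#'
#' @param beam_current Probe current, amperes.
#' @param dwell_time Dwell time per scan pixel, seconds.
#' @param scan_pixel_size Scan pixel size on the sample, nm. Alternatively
#'   supply `magnification` together with `reference`.
#' @param magnification Optional magnification; converted to a pixel size
#'   via the instrument `reference` pair.
#' @param reference Instrument calibration pair `c(magnification, nm_per_px)`
#'   such as `c(1500, 194)`; required when `magnification` is given.
#' @return Dose in e-/A^2 per image.
#' @examples
#' stem_dose(25e-12, 4e-6, 194) # ~1.66e-4 e-/A^2
#' @export
stem_dose <- function(beam_current, dwell_time, scan_pixel_size = NULL,
                      magnification = NULL, reference = NULL) {
  if (is.null(scan_pixel_size)) {
    if (is.null(magnification) || is.null(reference)) {
      rlang::abort("supply `scan_pixel_size`, or `magnification` with `reference`.",
                   class = "edcal_invalid_input")
    }
    # pixel size on sample scales inversely with magnification
    scan_pixel_size <- reference[2] * reference[1] / magnification
  }
  if (beam_current <= 0 || dwell_time <= 0 || scan_pixel_size <= 0) {
    rlang::abort("current, dwell time and pixel size must be positive.",
                 class = "edcal_invalid_input")
  }
  electrons_per_px <- beam_current * dwell_time / .const$e
  electrons_per_px / (scan_pixel_size * 10)^2 # nm -> Angstrom
}

#' Beam current from the spot-size index
#'
#' On instruments where the screen-current reading bottoms out, the current
#' at small spot sizes is extrapolated from a measurable reference using
#' the halving rule: each spot-size increment halves the current.
#'
#' @param current_ref Measured current at `spot_ref`, amperes.
#' @param spot_ref,spot Integer spot-size indices.
#' @return Estimated current at `spot`, amperes.
#' @examples
#' spot_current(50e-12, 8, 9) # 25 pA
#' @export
spot_current <- function(current_ref, spot_ref, spot) {
  stopifnot(spot_ref == round(spot_ref), spot == round(spot))
  current_ref * 2^(spot_ref - spot)
}

#' Imaging fluence per detector frame
#'
#' A frame recorded at flux `f` (e-/A^2/s) with readout frequency `nu`
#' carries `f / nu` electrons per square Angstrom.
#'
#' @param flux Incident fluence rate, e-/A^2/s.
#' @param frame_rate Detector readout frequency, Hz.
#' @return Fluence per frame, e-/A^2.
#' @export
fluence_per_frame <- function(flux, frame_rate) {
  if (any(flux < 0) || any(frame_rate <= 0)) {
    rlang::abort("`flux` must be >= 0 and `frame_rate` > 0.",
                 class = "edcal_invalid_input")
  }
  flux / frame_rate
}

#' Magnification calibration from a cross-grating
#'
#' A standard cross-grating replica (e.g. gold, 2160 lines per millimetre,
#' i.e. a 463 nm box width) imaged on the detector calibrates the
#' magnification: the box width divided by its extent in pixels gives the
#' sample-plane pixel size, and the detector pixel pitch divided by that
#' gives the magnification.
#'
#' @param pixels_per_box Measured box width on the image, pixels.
#' @param lines_per_mm Grating pitch, lines per millimetre.
#' @param detector_pixel_size Detector pixel pitch, mm (default 0.075).
#' @return Tibble with `box_width_nm`, `nm_per_pixel`, `magnification`.
#' @examples
#' grating_pixel_size(100, 2160)
#' @export
grating_pixel_size <- function(pixels_per_box, lines_per_mm,
                               detector_pixel_size = 0.075) {
  if (pixels_per_box <= 0 || lines_per_mm <= 0 || detector_pixel_size <= 0) {
    rlang::abort("inputs must be positive.", class = "edcal_invalid_input")
  }
  box <- 1e6 / lines_per_mm # nm
  nm_px <- box / pixels_per_box
  tibble::tibble(
    box_width_nm = box,
    nm_per_pixel = nm_px,
    magnification = detector_pixel_size * 1e6 / nm_px
  )
}
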