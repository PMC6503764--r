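# CODATA-2018 constants, SI units
.const <- list(
  h  = 6.62607015e-34,   # Planck, J s
  m0 = 9.1093837015e-31, # electron rest mass, kg
  e  = 1.602176634e-19,  # elementary charge, C
  c  = 299792458         # speed of light, m/s
)

#' Relativistic electron wavelength
#'
#' Computes the de Broglie wavelength of an electron accelerated through a
#' potential, with the relativistic correction that matters at TEM energies:
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}}
#' At 200 kV this gives 0.02508 Angstrom, the working wavelength of a
#' typical electron diffractometer.
#'
#' @param voltage Accelerating voltage in volts. May be a vector.
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(200e3) # 0.02508
#' electron_wavelength(300e3) # 0.019687
#' @export
electron_wavelength <- function(voltage) {
  if (!is.numeric(voltage) || any(!is.finite(voltage)) || any(voltage <= 0)) {
    rlang::abort("`voltage` must be a positive finite number (volts).",
                 class = "edcal_invalid_input")
  }
  lambda_m <- .const$h / sqrt(
    2 * .const$m0 * .const$e * voltage *
      (1 + .const$e * voltage / (2 * .const$m0 * .const$c^2))
  )
  lambda_m * 1e10
}

#' Allowed fcc powder d-spacings
#'
#' Enumerates the symmetry-distinct reflections of a face-centred cubic
#' lattice (h, k, l all even or all odd) with d-spacing
#' \eqn{d = a / \sqrt{h^2 + k^2 + l^2}} down to `d_min`, merging families
#' with equal d and sorting by decreasing d. For aluminium
#' (a = 4.0495 Angstrom) the first nine rings are the calibrant rings at
#' 2.338 ... 0.8266 Angstrom used for detector-distance calibration.
#'
#' @param a Cubic lattice constant in Angstrom.
#' @param d_min Smallest d-spacing to keep, Angstrom.
#' @param merge_tol Absolute tolerance in Angstrom below which two d values
#'   are treated as one ring (degenerate families such as 333/511).
#' @return A tibble with columns `h`, `k`, `l` (representative indices,
#'   sorted descending), `s2` (= h^2+k^2+l^2), `d` (Angstrom),
#'   `multiplicity` (number of distinct families merged into the ring).
#' @examples
#' fcc_dspacings(4.0495, 0.8)
#' @export
fcc_dspacings <- function(a, d_min, merge_tol = 1e-6) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0) {
    rlang::abort("`a` must be a positive lattice constant (Angstrom).",
                 class = "edcal_invalid_input")
  }
  if (!is.numeric(d_min) || length(d_min) != 1 || d_min <= 0) {
    rlang::abort("`d_min` must be positive (Angstrom).",
                 class = "edcal_invalid_input")
  }
  if (d_min >= a) {
    rlang::warn("`d_min` >= `a`: no fcc reflection satisfies d >= d_min.")
    return(tibble::tibble(h = integer(), k = integer(), l = integer(),
                          s2 = integer(), d = numeric(),
                          multiplicity = integer()))
  }
  hmax <- ceiling(a / d_min)
  grid <- expand.grid(h = 0:hmax, k = 0:hmax, l = 0:hmax)
  grid <- grid[rowSums(grid) > 0, ]
  # fcc selection rule: h, k, l all even or all odd
  par <- grid %% 2
  allowed <- (rowSums(par) == 0) | (rowSums(par) == 3)
  grid <- grid[allowed, ]
  # one representative per symmetry-distinct family: sorted |h| >= |k| >= |l|
  key <- t(apply(as.matrix(grid), 1, function(v) sort(v, decreasing = TRUE)))
  fam <- !duplicated(key)
  fams <- tibble::tibble(h = key[fam, 1], k = key[fam, 2], l = key[fam, 3])
  fams$s2 <- fams$h^2 + fams$k^2 + fams$l^2
  fams$d <- a / sqrt(fams$s2)
  fams <- dplyr::filter(fams, .data$d >= d_min - merge_tol)
  fams <- dplyr::arrange(fams, dplyr::desc(.data$d), .data$h, .data$k, .data$l)
  # merge rings whose d coincide within tolerance (keep lowest-index family)
  ring_id <- cumsum(c(TRUE, diff(fams$d) < -merge_tol))
  out <- fams |>
    dplyr::mutate(ring = ring_id) |>
    dplyr::group_by(.data$ring) |>
    dplyr::summarise(
      h = dplyr::first(.data$h), k = dplyr::first(.data$k),
      l = dplyr::first(.data$l), s2 = dplyr::first(.data$s2),
      d = dplyr::first(.data$d), multiplicity = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"ring")
  out
}

#' Predicted powder-ring radius on the detector
#'
#' Exact scattering geometry: the Bragg angle is
#' \eqn{\theta = \arcsin(\lambda / 2d)} and the ring radius on a flat
#' detector at distance D is \eqn{r = D \tan(2\theta)}. No small-angle
#' approximation is used, although at electron wavelengths the difference
#' from \eqn{r \approx D\lambda/d} is below 0.01 percent.
#'
#' @param d Lattice-plane spacing, Angstrom. Vectorised.
#' @param wavelength Electron wavelength, Angstrom.
#' @param distance Detector distance, mm.
#' @param pixel_size Detector pixel pitch, mm.
#' @return Ring radius in pixels.
#' @examples
#' ring_radius(2.338, 0.02508, 500, 0.075) # 71.52 px
#' @export
ring_radius <- function(d, wavelength, distance, pixel_size) {
  stopifnot(is.numeric(d), is.numeric(wavelength), length(wavelength) == 1)
  if (any(d <= 0)) {
    rlang::abort("`d` must be positive.", class = "edcal_invalid_input")
  }
  if (distance <= 0 || pixel_size <= 0) {
    rlang::abort("`distance` and `pixel_size` must be positive.",
                 class = "edcal_invalid_input")
  }
  if (any(wavelength >= 2 * d)) {
    rlang::abort("wavelength >= 2d: Bragg condition has no solution.",
                 class = "edcal_no_diffraction")
  }
  theta <- asin(wavelength / (2 * d))
  distance * tan(2 * theta) / pixel_size
}

#' Detector distance from a measured ring radius
#'
#' Exact inverse of [ring_radius()]: given the pixel radius of a powder ring
#' of known d-spacing, returns the effective detector distance
#' \eqn{D = r \, p / \tan(2\theta)}. During calibration this is applied to
#' both the major and minor semi-axes of the fitted ellipse; the two
#' distances differ by the distortion ratio A/B and the ambiguity must be
#' resolved against a sample of known unit cell.
#'
#' @param radius Ring radius in pixels (vectorised).
#' @param d Lattice-plane spacing, Angstrom.
#' @param wavelength Electron wavelength, Angstrom.
#' @param pixel_size Detector pixel pitch, mm.
#' @return Detector distance in mm.
#' @examples
#' distance_from_radius(71.52, 2.338, 0.02508, 0.075) # ~500 mm
#' @export
distance_from_radius <- function(radius, d, wavelength, pixel_size) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    rlang::abort("`radius` must be positive.", class = "edcal_invalid_input")
  }
  if (any(d <= 0) || wavelength <= 0 || pixel_size <= 0) {
    rlang::abort("`d`, `wavelength`, `pixel_size` must be positive.",
                 class = "edcal_invalid_input")
  }
  if (any(wavelength >= 2 * d)) {
    rlang::abort("wavelength >= 2d: Bragg condition has no solution.",
                 class = "edcal_no_diffraction")
  }
  theta <- asin(wavelength / (2 * d))
  radius * pixel_size / tan(2 * theta)
}
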