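# Independent oracles and small utilities shared by the tests. These stay
# deliberately separate from the package's own code paths.

# closed-form relativistic wavelength, written from scratch with CODATA
# constants (momentum form: p = sqrt(2 m0 E (1 + E / (2 m0 c^2))))
oracle_wavelength <- function(voltage) {
  h <- 6.62607015e-34; m0 <- 9.1093837015e-31
  qe <- 1.602176634e-19; cc <- 299792458
  E <- qe * voltage
  p <- sqrt(2 * m0 * E * (1 + E / (2 * m0 * cc^2)))
  (h / p) * 1e10
}

# circular distance of two azimuths folded to the half-circle
fold_err <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# conic (4ac - b^2 = 1 normalisation) from geometric ellipse parameters
geo_to_conic_unit <- function(cx, cy, A, B, phi_deg) {
  phi <- phi_deg * pi / 180
  cs <- cos(phi); sn <- sin(phi)
  a <- cs^2 / A^2 + sn^2 / B^2
  b <- 2 * cs * sn * (1 / A^2 - 1 / B^2)
  c <- sn^2 / A^2 + cs^2 / B^2
  d <- -2 * a * cx - b * cy
  e <- -b * cx - 2 * c * cy
  f <- a * cx^2 + b * cx * cy + c * cy^2 - 1
  k <- c(a, b, c, d, e, f)
  k / sqrt(4 * a * c - b^2)
}

algebraic_residual <- function(k, pts) {
  g <- k[1] * pts[, 1]^2 + k[2] * pts[, 1] * pts[, 2] + k[3] * pts[, 2]^2 +
    k[4] * pts[, 1] + k[5] * pts[, 2] + k[6]
  sum(g^2)
}

# brute-force oracle: minimise the same algebraic residual (under the same
# ellipse normalisation) over geometric parameters — coarse grid around the
# point cloud, then hard local refinement
oracle_ellipse_residual <- function(pts) {
  cx0 <- mean(pts[, 1]); cy0 <- mean(pts[, 2])
  r0 <- mean(sqrt((pts[, 1] - cx0)^2 + (pts[, 2] - cy0)^2))
  obj <- function(p) {
    if (p[3] <= 0 || p[4] <= 0) return(Inf)
    algebraic_residual(geo_to_conic_unit(p[1], p[2], p[3], p[4], p[5]), pts)
  }
  grid <- expand.grid(
    cx = cx0 + c(-1, 0, 1), cy = cy0 + c(-1, 0, 1),
    A = r0 * c(0.9, 1, 1.1), B = r0 * c(0.9, 1, 1.1),
    phi = seq(0, 160, by = 20)
  )
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  for (i in 1:3) {
    o1 <- stats::optim(best, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-15))
    best <- o2$par
  }
  obj(best)
}

# residual of a fitted conic rescaled to the same unit normalisation
fit_residual_unit <- function(fit, pts) {
  k <- fit$conic
  k <- k / sqrt(4 * k[1] * k[3] - k[2]^2)
  algebraic_residual(k, pts)
}

# small detector scene: same physics as the default EIGER-sized scene but
# quick to rasterise, for property loops
small_scene <- function(...) {
  synthetic_scene(
    distance = 250, origin = c(200, 210),
    detector = detector_spec(n_fast = 400, n_slow = 420),
    ...
  )
}

small_r0 <- function(scene) {
  ring_radius(scene$standard$rings$d[1], scene$geometry$beam$wavelength,
              scene$geometry$distance, scene$geometry$detector$pixel_size)
}

# write lines to a temp file and return the path
textConnection_file <- function(lines) {
  p <- tempfile()
  writeLines(lines, p)
  p
}
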