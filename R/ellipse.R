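#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse to scattered points by the
#' direct algebraic least-squares method (scatter-matrix eigenproblem with
#' the ellipse-enforcing normalisation 4AC - B^2 = 1, in the numerically
#' stable block form), then converts the conic to geometric parameters.
#' This is the operation behind powder-ring distortion analysis: a ring of
#' peaks from an fcc calibrant is fitted and the ratio of the semi-axes
#' measures the projector-lens distortion, while either axis yields an
#' effective detector distance.
#'
#' The reported `rms_residual` is the root-mean-square Sampson distance
#' (algebraic residual divided by its gradient norm), a first-order
#' approximation of the orthogonal point-to-ellipse distance, which has no
#' closed form.
#'
#' @param points A two-column matrix or data frame of (fast, slow) pixel
#'   coordinates, or a data frame with columns `x` and `y`.
#' @return An object of class `ellipse_fit`: list with `center` (length-2),
#'   `semi_major`, `semi_minor`, `orientation` (degrees of the major axis
#'   from the +fast axis, in `[0, 180)`; 0 by convention for a circle),
#'   `ellipticity` (A/B - 1), `rms_residual` (px), `n_points`, and the
#'   conic coefficients `conic` (a, b, c, d, e, f).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' fit <- fit_ellipse(cbind(508 + 100 * cos(th), 530 + 100 * sin(th)))
#' fit$semi_major # 100
#' @export
fit_ellipse <- function(points) {
  pts <- as_xy(points)
  if (nrow(pts) < 5) {
    rlang::abort("ellipse fitting needs at least 5 points.",
                 class = "edcal_insufficient_data")
  }
  if (nrow(unique(round(pts, 12))) < 5) {
    rlang::abort("points are coincident: fewer than 5 distinct points.",
                 class = "edcal_insufficient_data")
  }
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc == 0) {
    rlang::abort("points are degenerate (zero spread).",
                 class = "edcal_degenerate_fit")
  }
  xs <- (x - mx) / sc; ys <- (y - my) / sc

  # Halir-Flusser block decomposition of the constrained eigenproblem
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) rlang::abort(
                   "degenerate point configuration (collinear points?).",
                   class = "edcal_degenerate_fit"))
  M0 <- S1 + S2 %*% T3
  M <- rbind(M0[3, ] / 2, -M0[2, ], M0[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) {
    rlang::abort("fit is not an ellipse (hyperbolic/degenerate conic).",
                 class = "edcal_degenerate_fit")
  }
  a1 <- vecs[, ok[1]]
  conic_s <- c(a1, as.numeric(T3 %*% a1)) # in scaled, centred coords

  # undo scaling x -> (x - mx)/sc
  A <- conic_s[1] / sc^2
  B <- conic_s[2] / sc^2
  C <- conic_s[3] / sc^2
  D <- conic_s[4] / sc - 2 * A * mx - B * my
  E <- conic_s[5] / sc - 2 * C * my - B * mx
  FF <- conic_s[6] + A * mx^2 + B * mx * my + C * my^2 -
    (conic_s[4] / sc) * mx - (conic_s[5] / sc) * my
  conic <- c(A, B, C, D, E, FF)

  geo <- conic_to_geometric(conic)
  res <- sampson_distance(conic, pts)
  structure(
    c(geo, list(rms_residual = sqrt(mean(res^2)), n_points = nrow(pts),
                conic = conic)),
    class = "ellipse_fit"
  )
}

# conic (a,b,c,d,e,f) -> center, semi-axes, orientation, ellipticity
conic_to_geometric <- function(k) {
  a <- k[1]; b <- k[2]; c2 <- k[3]; d <- k[4]; e <- k[5]; f <- k[6]
  det2 <- 4 * a * c2 - b^2
  if (det2 <= 0) {
    rlang::abort("conic is not an ellipse.", class = "edcal_degenerate_fit")
  }
  cx <- (b * e - 2 * c2 * d) / det2
  cy <- (b * d - 2 * a * e) / det2
  f0 <- a * cx^2 + b * cx * cy + c2 * cy^2 + d * cx + e * cy + f
  Q <- matrix(c(a, b / 2, b / 2, c2), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values # decreasing; both same sign as -f0 for a real ellipse
  if (any(lam * (-f0) <= 0)) {
    rlang::abort("conic has no real ellipse points.",
                 class = "edcal_degenerate_fit")
  }
  axes <- sqrt(-f0 / lam)
  A <- max(axes); Bm <- min(axes)
  i_major <- which.max(axes) # direction of the larger semi-axis
  v <- eg$vectors[, i_major]
  orientation <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  if ((A - Bm) / A < 1e-10) orientation <- 0 # circle convention
  list(center = c(cx, cy), semi_major = A, semi_minor = Bm,
       orientation = orientation, ellipticity = A / Bm - 1)
}

# first-order orthogonal (Sampson) distance of points to a conic
sampson_distance <- function(conic, pts) {
  a <- conic[1]; b <- conic[2]; c2 <- conic[3]
  d <- conic[4]; e <- conic[5]; f <- conic[6]
  x <- pts[, 1]; y <- pts[, 2]
  g <- a * x^2 + b * x * y + c2 * y^2 + d * x + e * y + f
  gx <- 2 * a * x + b * y + d
  gy <- b * x + 2 * c2 * y + e
  abs(g) / sqrt(gx^2 + gy^2)
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      pts <- cbind(points$x, points$y)
    } else {
      pts <- as.matrix(points[, 1:2])
    }
  } else {
    pts <- as.matrix(points)
  }
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2 || any(!is.finite(pts))) {
    rlang::abort("`points` must be finite (x, y) pairs.",
                 class = "edcal_invalid_input")
  }
  pts
}

#' Ring ellipticity
#'
#' The relative elongation e = A/B - 1 of a fitted ring: the standard
#' measure of projector-lens distortion of a diffraction pattern. Values
#' around 2-3 percent are typical and small enough that structure solution
#' succeeds without correcting them.
#'
#' @param fit An `ellipse_fit`.
#' @return Dimensionless ellipticity (>= 0).
#' @export
ring_ellipticity <- function(fit) {
  stopifnot(inherits(fit, "ellipse_fit"))
  fit$semi_major / fit$semi_minor - 1
}

#' Points on an ellipse
#'
#' Parametric points, used by the synthetic generators and in tests.
#'
#' @param n Number of points, equally spaced in the parametric angle.
#' @param center Length-2 centre.
#' @param semi_major,semi_minor Semi-axes (px).
#' @param orientation Major-axis angle from +fast axis, degrees.
#' @param jitter_sd Isotropic Gaussian jitter added to each coordinate, px.
#' @return Tibble with columns `x`, `y`.
#' @export
ellipse_points <- function(n, center, semi_major, semi_minor,
                           orientation = 0, jitter_sd = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- orientation * pi / 180
  x0 <- semi_major * cos(th); y0 <- semi_minor * sin(th)
  x <- center[1] + x0 * cos(phi) - y0 * sin(phi)
  y <- center[2] + x0 * sin(phi) + y0 * cos(phi)
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(n, 0, jitter_sd)
    y <- y + stats::rnorm(n, 0, jitter_sd)
  }
  tibble::tibble(x = x, y = y)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat("<ellipse_fit>\n")
  cat(sprintf("  center      (%.3f, %.3f) px\n", x$center[1], x$center[2]))
  cat(sprintf("  A, B        %.4f, %.4f px (A/B = %.5f)\n",
              x$semi_major, x$semi_minor, x$semi_major / x$semi_minor))
  cat(sprintf("  orientation %.3f deg\n", x$orientation))
  cat(sprintf("  rms resid   %.4g px over %d points\n",
              x$rms_residual, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_ellipse One row per geometric parameter.
#' @param x An `ellipse_fit`.
#' @param ... Unused.
#' @method tidy ellipse_fit
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_x", "center_y", "semi_major", "semi_minor",
             "orientation", "ellipticity"),
    estimate = c(x$center, x$semi_major, x$semi_minor,
                 x$orientation, x$ellipticity)
  )
}

#' @describeIn fit_ellipse One-row fit summary.
#' @method glance ellipse_fit
#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    axis_ratio = x$semi_major / x$semi_minor,
    ellipticity = x$ellipticity,
    rms_residual = x$rms_residual,
    n_points = x$n_points
  )
}

#' @describeIn fit_ellipse Plot the fitted ellipse.
#' @param object An `ellipse_fit`.
#' @method autoplot ellipse_fit
#' @export
autoplot.ellipse_fit <- function(object, ...) {
  outline <- ellipse_points(360, object$center, object$semi_major,
                            object$semi_minor, object$orientation)
  ggplot2::ggplot(outline, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = object$center[1], y = object$center[2],
                      shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fast (px)", y = "slow (px)",
                  title = sprintf("A/B = %.4f",
                                  object$semi_major / object$semi_minor))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
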