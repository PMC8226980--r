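## Analytic duct solutions and wall-shear estimators.
## User-facing units: Q in uL/min, lengths in um, viscosity in Pa s,
## velocities in mm/s, stress in Pa.

UL_MIN_TO_M3S <- 1e-9 / 60

#' Mean velocity in a rectangular duct
#'
#' @param Q flow rate (uL/min).
#' @param w,h cross-section width and height (um).
#' @return Q / (w h) in mm/s.
#' @export
duct_mean_velocity <- function(Q, w, h) {
  (Q * UL_MIN_TO_M3S) / (w * 1e-6 * h * 1e-6) * 1e3
}

#' Wall shear stress from the slit (parallel-plate) approximation
#'
#' For a shallow rectangular channel (w >> h) the wall shear stress of the
#' fully developed laminar flow is
#' \deqn{\tau = \eta\,\frac{\delta v}{\delta y}\Big|_{wall}
#'       = \frac{6\,\eta\,Q}{w\,h^2}.}
#' At Q = 0.5 uL/min through a 200 um x 50 um channel with eta = 1 mPa s
#' this gives 0.10 Pa, and 0.20 Pa at 1.0 uL/min -- venule/vein-level
#' stresses.
#'
#' @param Q flow rate (uL/min, >= 0).
#' @param w,h channel width and height (um).
#' @param eta dynamic viscosity (Pa s).
#' @return Wall shear stress in Pa.
#' @export
slit_wall_shear <- function(Q, w, h, eta) {
  if (Q < 0) stop("Q must be non-negative")
  if (w <= 0 || h <= 0 || eta <= 0) stop("w, h and eta must be positive")
  if (w / h < 2)
    warning("aspect ratio w/h < 2: slit approximation is inaccurate")
  6 * eta * (Q * UL_MIN_TO_M3S) / ((w * 1e-6) * (h * 1e-6)^2)
}

# cosh(x)/cosh(b) without overflow (b > 0)
cosh_ratio <- function(x, b) (exp(x - b) + exp(-x - b)) / (1 + exp(-2 * b))

# series pieces of the rectangular-duct Poiseuille solution, per unit G/eta
duct_series_mid <- function(y, w, h, nmax) {
  s <- 0
  for (n in seq(1, nmax, by = 2))
    s <- s + ((-1)^((n - 1) / 2) / n^3) *
      cosh_ratio(n * pi * abs(y - w / 2) / h, n * pi * w / (2 * h))
  h^2 / 8 - (4 * h^2 / pi^3) * s
}
duct_series_davg <- function(y, w, h, nmax) {
  s <- 0
  for (n in seq(1, nmax, by = 2))
    s <- s + (1 / n^4) *
      cosh_ratio(n * pi * abs(y - w / 2) / h, n * pi * w / (2 * h))
  h^2 / 12 - (8 * h^2 / pi^4) * s
}
duct_series_flux <- function(w, h, nmax) {
  s <- 0
  for (n in seq(1, nmax, by = 2))
    s <- s + (1 / n^5) * tanh(n * pi * w / (2 * h))
  w * h^3 / 12 - (16 * h^4 / pi^5) * s
}

# construct a velocity_profile object
velocity_profile_obj <- function(pos, v, span, counts = NULL, axis = "span",
                                 Q = NA_real_) {
  df <- data.frame(pos_um = pos, v_mm_s = v,
                   n = if (is.null(counts)) NA_integer_ else counts)
  structure(df, span = span, axis = axis, Q = Q,
            class = c("velocity_profile", "data.frame"))
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("Velocity profile: %d bins across %g um (%s axis)\n",
              nrow(x), attr(x, "span"), attr(x, "axis")))
  cat(sprintf("  peak %.3f mm/s, mean %.3f mm/s\n",
              max(x$v_mm_s, na.rm = TRUE), mean(x$v_mm_s, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.velocity_profile <- function(x, ...) {
  graphics::plot(x$pos_um, x$v_mm_s, type = "b", pch = 16,
                 xlab = "position (um)", ylab = "speed (mm/s)", ...)
  invisible(x)
}

#' Analytic laminar velocity profile of a rectangular duct
#'
#' Evaluates the exact series solution for fully developed pressure-driven
#' Newtonian flow in a rectangular duct, sampled across the width, either
#' at mid-height or depth-averaged, and scaled so the cross-section
#' integral equals `Q`. In the slit limit (w >> h) the mid-height
#' centerline-to-mean ratio tends to the parabolic value 1.5.
#'
#' @param Q flow rate (uL/min).
#' @param w,h width and height (um).
#' @param n_bins number of spanwise sample points.
#' @param at `"mid_height"` or `"depth_averaged"`.
#' @param nmax series truncation (odd terms up to `nmax`); the relative
#'   size of the last term is reported in attribute `truncation`.
#' @return A `velocity_profile` (positions across `[0, w]`, mm/s), with
#'   attributes `centerline_mid`, `centerline_davg`, `mean_mm_s` and
#'   `truncation`.
#' @export
rect_duct_profile <- function(Q, w, h, n_bins = 80,
                              at = c("mid_height", "depth_averaged"),
                              nmax = 399) {
  at <- match.arg(at)
  if (Q < 0 || w <= 0 || h <= 0) stop("Q, w, h must be positive (Q >= 0)")
  y <- (seq_len(n_bins) - 0.5) * w / n_bins
  scale <- (Q * UL_MIN_TO_M3S) / (duct_series_flux(w * 1e-6, h * 1e-6, nmax))
  f <- if (at == "mid_height") duct_series_mid else duct_series_davg
  v <- f(y * 1e-6, w * 1e-6, h * 1e-6, nmax) * scale * 1e3
  cl_mid <- duct_series_mid(w / 2 * 1e-6, w * 1e-6, h * 1e-6, nmax) *
    scale * 1e3
  cl_davg <- duct_series_davg(w / 2 * 1e-6, w * 1e-6, h * 1e-6, nmax) *
    scale * 1e3
  last <- nmax - (1 - nmax %% 2)
  trunc_rel <- (1 / last^3) *
    cosh_ratio(0, last * pi * w / (2 * h)) / (pi^3 / 32)
  p <- velocity_profile_obj(y, v, span = w, axis = "span", Q = Q)
  attr(p, "centerline_mid") <- cl_mid
  attr(p, "centerline_davg") <- cl_davg
  attr(p, "mean_mm_s") <- duct_mean_velocity(Q, w, h)
  attr(p, "truncation") <- trunc_rel
  p
}

#' Parabolic depth profile of the slit approximation
#'
#' The across-depth profile v(z) = 6 vbar z (h - z) / h^2 used for
#' wall-shear estimation, sampled at `n_bins` cell-centered points.
#'
#' @param Q flow rate (uL/min).
#' @param w,h width and height (um).
#' @param n_bins sample count across the depth.
#' @return A `velocity_profile` across `[0, h]`.
#' @export
slit_depth_profile <- function(Q, w, h, n_bins = 25) {
  z <- (seq_len(n_bins) - 0.5) * h / n_bins
  vbar <- duct_mean_velocity(Q, w, h)
  velocity_profile_obj(z, 6 * vbar * z * (h - z) / h^2, span = h,
                       axis = "depth", Q = Q)
}

#' Wall shear stress from a measured or analytic velocity profile
#'
#' Estimates the wall velocity gradient by a one-sided quadratic
#' (three-point) fit through the bins nearest each wall, evaluated at the
#' wall, and multiplies by the viscosity: tau = eta * dv/dy. For Carreau
#' fluids the viscosity is evaluated at the estimated wall shear rate. The
#' fit is exact for a parabolic profile, so the slit profile at
#' Q = 0.5 uL/min, eta = 1 mPa s returns 0.10 Pa up to rounding.
#'
#' @param profile a `velocity_profile` spanning wall to wall.
#' @param fluid a `fluid_model` (or a bare viscosity in Pa s).
#' @return Wall shear stress in Pa (mean of the two walls).
#' @export
shear_from_profile <- function(profile, fluid) {
  stopifnot(inherits(profile, "velocity_profile"))
  if (is.numeric(fluid))
    fluid <- fluid_model("ad-hoc", 1000, "newtonian", eta = fluid)
  ok <- is.finite(profile$v_mm_s)
  pos <- profile$pos_um[ok]; v <- profile$v_mm_s[ok]
  span <- attr(profile, "span")
  grad_at <- function(wall) {
    d <- abs(pos - wall)
    near <- order(d)[1:3]
    if (length(pos) < 3 || max(d[near]) > span / 2)
      stop("profile too sparse near the wall")
    fit <- stats::lm(v[near] ~ poly(pos[near], 2, raw = TRUE))
    b <- stats::coef(fit)
    abs(b[2] + 2 * b[3] * wall)   # mm/s per um = 1e3 / s
  }
  g <- c(grad_at(0), grad_at(span)) * 1e3  # 1/s
  tau <- vapply(g, function(gi) viscosity(fluid, gi) * gi, 0)
  mean(tau)
}
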