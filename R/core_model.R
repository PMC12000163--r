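#' Stokes terminal velocity
#'
#' Settling (or flotation) velocity of a rigid sphere in creeping flow,
#' where the net gravitational force balances the Stokes drag:
#' `v_T = 2 g r_P^2 (rho_B - rho_P) / (9 eta)`.
#' The value is signed: negative means the particle is denser than the
#' buffer and sediments downward, positive means it floats.
#'
#' @param p A [particle_spec()].
#' @param b A [buffer_spec()].
#' @param const A [model_constants()].
#' @return Signed vertical velocity in m/s.
#' @examples
#' terminal_velocity(particle_spec(5e-6, 1070),
#'                   buffer_spec(997, 1e-3))  # ~ -3.98e-6 m/s
#' @export
terminal_velocity <- function(p, b, const = model_constants()) {
  stopifnot(inherits(p, "particle_spec"), inherits(b, "buffer_spec"),
            inherits(const, "model_constants"))
  2 * const$g * p$radius^2 * (b$density - p$density) / (9 * b$viscosity)
}

#' Stokes velocity relaxation time
#'
#' Exponential time constant with which a sphere released at rest approaches
#' its terminal velocity, `tau = m / (6 pi eta r_P) = (2/9) rho_P r_P^2 / eta`.
#' For micron-scale particles in aqueous buffers tau is of order microseconds,
#' many orders of magnitude below the sedimentation timescale, which justifies
#' the inertialess advection used throughout: particles are assumed to move at
#' the local fluid velocity plus `v_T` at all times.
#'
#' @inheritParams terminal_velocity
#' @return Relaxation time in seconds.
#' @export
stokes_relaxation_time <- function(p, b) {
  stopifnot(inherits(p, "particle_spec"), inherits(b, "buffer_spec"))
  (2 / 9) * p$density * p$radius^2 / b$viscosity
}

#' Effective area: two-circle lens
#'
#' Area of the intersection of two circles of equal radius `R_S` whose
#' centres are `d_T` apart. As a uniformly seeded particle population
#' translates rigidly downward by `d_T`, the cross-section region still
#' occupied by particles is exactly this lens; it shrinks to zero when the
#' travelled distance reaches the barrel diameter.
#'
#' @param R_S Circle (barrel) radius in metres.
#' @param d_T Centre separation (sedimentation path `|v_T| t`) in metres,
#'   >= 0.
#' @return Lens area in m^2, clamped to 0 for `d_T >= 2 R_S`.
#' @export
effective_area_lens <- function(R_S, d_T) {
  stop_if_not_positive(R_S = R_S)
  if (any(!is.finite(d_T)) || any(d_T < 0))
    stop("`d_T` must be finite and >= 0", call. = FALSE)
  x <- pmin(d_T / (2 * R_S), 1)
  2 * R_S^2 * acos(x) - 0.5 * d_T * sqrt(pmax(4 * R_S^2 - d_T^2, 0))
}

#' Effective area: circular segment
#'
#' Area of the circular segment of a circle of radius `R_S` lying above a
#' chord at height `d_T` over the centre. This is the effective region when
#' only particles above the (concentric) outlet level can ever leave: the
#' initial effective area is the upper half disk and it vanishes once the
#' population has travelled one barrel radius.
#'
#' @inheritParams effective_area_lens
#' @return Segment area in m^2, clamped to 0 for `d_T >= R_S`.
#' @export
effective_area_segment <- function(R_S, d_T) {
  stop_if_not_positive(R_S = R_S)
  if (any(!is.finite(d_T)) || any(d_T < 0))
    stop("`d_T` must be finite and >= 0", call. = FALSE)
  x <- pmin(d_T / R_S, 1)
  R_S^2 * acos(x) - d_T * sqrt(pmax(R_S^2 - d_T^2, 0))
}

# shared dimensionless profile: (2/pi) (acos(u) - u sqrt(1 - u^2)),
# clamped to [0, 1]; both boundary curves reduce to it
concentration_profile <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  pmin(pmax((2 / pi) * (acos(u) - u * sqrt(1 - u^2)), 0), 1)
}

#' Boundary effective-concentration curves
#'
#' Closed-form effective concentration ratio `C_E(t)/C_0` for the two
#' limiting regimes of sedimentation in a horizontal syringe.
#'
#' `concentration_ratio_upper()` is the full-cross-section (lens) model:
#' every suspended particle counts as effective, the appropriate limit when
#' the flow near the nozzle lifts particles from any cross-sectional
#' position (high flow-rates). It equals
#' `effective_area_lens(R_S, v_T t) / (pi R_S^2)` and reaches 0 at
#' `t = 2 R_S / v_T`.
#'
#' `concentration_ratio_lower()` is the half-cross-section (segment) model:
#' particles below a concentric outlet can never leave (no lift, low
#' flow-rates). It equals
#' `effective_area_segment(R_S, v_T t) / (pi R_S^2 / 2)` and reaches 0 at
#' `t = R_S / v_T`.
#'
#' A zero terminal velocity is a meaningful degenerate case (no density
#' mismatch, no sedimentation): both functions then return 1 for every time.
#'
#' @param v_T_mag Magnitude of the terminal velocity in m/s, >= 0.
#' @param R_S Barrel radius in metres.
#' @param t Elapsed time(s) in seconds, >= 0.
#' @return Dimensionless ratio(s) in \[0, 1\].
#' @export
concentration_ratio_upper <- function(v_T_mag, R_S, t) {
  check_ratio_args(v_T_mag, R_S, t)
  if (v_T_mag == 0) return(rep(1, length(t)))
  concentration_profile(v_T_mag * t / (2 * R_S))
}

#' @rdname concentration_ratio_upper
#' @export
concentration_ratio_lower <- function(v_T_mag, R_S, t) {
  check_ratio_args(v_T_mag, R_S, t)
  if (v_T_mag == 0) return(rep(1, length(t)))
  concentration_profile(v_T_mag * t / R_S)
}

check_ratio_args <- function(v_T_mag, R_S, t) {
  if (!is.numeric(v_T_mag) || length(v_T_mag) != 1 || !is.finite(v_T_mag) ||
      v_T_mag < 0)
    stop("`v_T_mag` must be a finite non-negative scalar", call. = FALSE)
  stop_if_not_positive(R_S = R_S)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Analytic boundary curve as a concentration_curve object
#'
#' Evaluates one of the two boundary models over a time grid and wraps the
#' result with provenance, ready for half-life extraction, plotting or use
#' as the rate model of the synthetic trace generator.
#'
#' @inheritParams terminal_velocity
#' @param s A [syringe_spec()].
#' @param times Time grid in seconds.
#' @param boundary `"upper"` (lens model) or `"lower"` (segment model).
#' @return A [concentration_curve()] with source `analytic_upper` or
#'   `analytic_lower`.
#' @export
boundary_curve <- function(p, b, s, times, boundary = c("upper", "lower"),
                           const = model_constants()) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(s, "syringe_spec"))
  v <- abs(terminal_velocity(p, b, const))
  R_S <- s$barrel_radius
  ratio <- if (boundary == "upper")
    concentration_ratio_upper(v, R_S, times)
  else
    concentration_ratio_lower(v, R_S, times)
  area <- if (boundary == "upper")
    effective_area_lens(R_S, v * times)
  else
    effective_area_segment(R_S, pmin(v * times, R_S))
  concentration_curve(times, ratio,
                      source = paste0("analytic_", boundary),
                      effective_area = area,
                      meta = list(particle = p, buffer = b, syringe = s,
                                  v_T = terminal_velocity(p, b, const)))
}

#' Half-life boundary coefficients
#'
#' Solves `C_E/C_0 = 1/2` numerically for the two boundary curves and
#' returns the dimensionless coefficients `k` such that
#' `t_1/2 = k R_S / v_T`. Both curves share the profile
#' `(2/pi)(acos(u) - u sqrt(1-u^2))` in a scaled time variable, so the upper
#' (lens) coefficient is exactly twice the lower (segment) one. The root is
#' found by bisection on \[0, 1\] to an interval tolerance of 1e-12: the
#' profile is strictly decreasing there and bisection is robust at the
#' endpoints where the derivative vanishes.
#'
#' @return Named numeric vector `c(lower = ..., upper = ...)`,
#'   approximately `c(0.4040, 0.8079)`.
#' @export
half_life_boundary_coefficients <- function() {
  f <- function(u) concentration_profile(u) - 0.5
  lo <- 0; hi <- 1
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  u_star <- (lo + hi) / 2
  c(lower = u_star, upper = 2 * u_star)
}

#' Concentration half-life bounds
#'
#' The two limiting-case half-lives of the effective concentration,
#' `k_lower R_S / |v_T|` and `k_upper R_S / |v_T|` with
#' `k = c(0.4040, 0.8079)` (see [half_life_boundary_coefficients()]).
#' Real systems fall between the bounds, moving from the lower one toward
#' the upper one as the flow-rate increases. When the particle and buffer
#' densities match there is no sedimentation and both bounds are `Inf`.
#'
#' Floating particles (buffer denser than particle) are handled by symmetry:
#' the geometry is mirror-symmetric about the horizontal mid-plane, so only
#' `|v_T|` enters.
#'
#' @inheritParams boundary_curve
#' @return An object of class `half_life_estimate` with fields
#'   `lower_bound`, `upper_bound` (s), and unset `t_half`/`K_S`.
#' @export
half_life_bounds <- function(p, b, s, const = model_constants()) {
  stopifnot(inherits(s, "syringe_spec"))
  v <- abs(terminal_velocity(p, b, const))
  k <- half_life_boundary_coefficients()
  if (v == 0) {
    lb <- ub <- Inf
  } else {
    lb <- k[["lower"]] * s$barrel_radius / v
    ub <- k[["upper"]] * s$barrel_radius / v
  }
  structure(list(t_half = NA_real_, K_S = NA_real_,
                 lower_bound = lb, upper_bound = ub,
                 v_T = terminal_velocity(p, b, const),
                 R_S = s$barrel_radius),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf("<half_life_estimate> bounds = [%g, %g] s", x$lower_bound,
              x$upper_bound))
  if (!is.na(x$t_half)) cat(sprintf(", t_half = %g s (K_S = %g)",
                                    x$t_half, x$K_S))
  cat("\n")
  invisible(x)
}

#' Point estimate of the concentration half-life
#'
#' `t_1/2 = K_S R_S / |v_T|` for a chosen empirical sedimentation constant
#' `K_S`. The model constrains `K_S` to \[0.4, 0.8\]; values outside raise a
#' warning (not an error) since fitted constants from real or simulated data
#' can fall slightly outside.
#'
#' @inheritParams boundary_curve
#' @param K_S Dimensionless sedimentation constant (> 0).
#' @return Half-life in seconds (`Inf` when the densities match).
#' @examples
#' # bone-marrow stromal cells in PBS in a 1 ml syringe, low-flow boundary
#' half_life_estimate(particle_spec(10.3e-6, 1062), buffer_pbs(),
#'                    syringe_spec(2.3e-3, 40e-3, 0.5e-3, 5e-3), K_S = 0.4)
#' @export
half_life_estimate <- function(p, b, s, K_S, const = model_constants()) {
  stop_if_not_positive(K_S = K_S)
  stopifnot(inherits(s, "syringe_spec"))
  if (K_S < 0.4 - 1e-9 || K_S > 0.8 + 1e-9)
    warning(sprintf("K_S = %g is outside the model range [0.4, 0.8]", K_S),
            call. = FALSE)
  v <- abs(terminal_velocity(p, b, const))
  if (v == 0) return(Inf)
  K_S * s$barrel_radius / v
}

#' Sedimentation constant from a measured half-life
#'
#' Inverts `t_1/2 = K_S R_S / v_T`: `K_S = t_1/2 |v_T| / R_S`.
#'
#' @param t_half Measured or simulated half-life in seconds, >= 0.
#' @param v_T_mag Terminal velocity magnitude in m/s, > 0.
#' @param R_S Barrel radius in metres, > 0.
#' @return Dimensionless sedimentation constant.
#' @export
sedimentation_constant <- function(t_half, v_T_mag, R_S) {
  stop_if_not_positive(v_T_mag = v_T_mag, R_S = R_S)
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half < 0))
    stop("`t_half` must be finite and >= 0", call. = FALSE)
  t_half * v_T_mag / R_S
}

#' Fit a pooled sedimentation constant
#'
#' Least-squares fit of `t_1/2 = K_S (R_S / v_T)` through the origin across
#' conditions with different half-lives, radii and terminal velocities
#' (the model has no intercept). The coefficient of determination is
#' computed against the zero-intercept null model, as `lm(y ~ 0 + x)` does.
#'
#' @param points A data frame with columns `t_half` (s), `R_S` (m) and
#'   `v_T_mag` (m/s), one row per condition; at least 2 rows.
#' @return A list with `K_S`, `r_squared` and the fitted `lm` object.
#' @export
fit_sedimentation_constant <- function(points) {
  points <- as.data.frame(points)
  need <- c("t_half", "R_S", "v_T_mag")
  if (!all(need %in% names(points)))
    stop("`points` must have columns t_half, R_S, v_T_mag", call. = FALSE)
  if (nrow(points) < 2)
    stop("at least 2 points are required to fit K_S", call. = FALSE)
  predictor <- points$R_S / points$v_T_mag
  fit <- stats::lm(t_half ~ 0 + predictor, data =
                     data.frame(t_half = points$t_half, predictor = predictor))
  # summary.lm warns on exact (noise-free) fits; those are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(K_S = unname(stats::coef(fit)[1]),
       r_squared = r2,
       fit = fit)
}

#' Viscosity increment from suspended particles (Einstein relation)
#'
#' Dilute-suspension viscosity increase `delta_eta = 2.5 phi eta`, with
#' volume fraction `phi = n (4/3) pi r_P^3` for a number concentration `n`.
#' Used to verify that the particle load leaves the buffer viscosity
#' essentially unchanged (typical loads of ~1e6 particles/ml give increments
#' far below 1e-3 mPa s).
#'
#' @inheritParams terminal_velocity
#' @param number_concentration Particles per m^3, >= 0.
#' @return Viscosity increment in Pa s.
#' @export
einstein_viscosity_increment <- function(p, number_concentration, b) {
  stopifnot(inherits(p, "particle_spec"), inherits(b, "buffer_spec"))
  if (!is.numeric(number_concentration) || length(number_concentration) != 1 ||
      !is.finite(number_concentration) || number_concentration < 0)
    stop("`number_concentration` must be a finite non-negative scalar",
         call. = FALSE)
  phi <- number_concentration * (4 / 3) * pi * p$radius^3
  2.5 * phi * b$viscosity
}
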