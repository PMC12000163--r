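#' Particle specification
#'
#' Describes a rigid spherical particle by its radius and mass density.
#' All quantities are SI; convenience constructors in the customary laboratory
#' units are available through configuration files (see [load_config()]).
#'
#' @param radius Particle radius in metres (> 0).
#' @param density Particle mass density in kg/m^3 (> 0).
#' @return An object of class `particle_spec`.
#' @examples
#' ps5 <- particle_spec(radius = 5e-6, density = 1070)  # 5 um polystyrene
#' @export
particle_spec <- function(radius, density) {
  stop_if_not_positive(radius = radius, density = density)
  structure(list(radius = radius, density = density), class = "particle_spec")
}

#' Buffer specification
#'
#' Describes the suspending Newtonian fluid by its mass density and dynamic
#' viscosity.
#'
#' @param density Buffer mass density in kg/m^3 (> 0).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#' @return An object of class `buffer_spec`.
#' @seealso [buffer_water()], [buffer_pbs()] for common presets.
#' @export
buffer_spec <- function(density, viscosity) {
  stop_if_not_positive(density = density, viscosity = viscosity)
  structure(list(density = density, viscosity = viscosity),
            class = "buffer_spec")
}

#' Common buffer presets
#'
#' `buffer_water()` returns water at 25 degrees C (density 997 kg/m^3,
#' viscosity 0.89 mPa s), the usual "room temperature" working fluid of
#' flow simulations. `buffer_pbs()` returns phosphate-buffered saline
#' approximated as density 1000 kg/m^3 and viscosity 1 mPa s; PBS density is
#' within about 0.5% of water and its exact value is rarely reported, so the
#' round value is used and should be overridden when known, since the density
#' mismatch `rho_B - rho_P` enters the terminal velocity linearly and matters
#' for near-neutrally-buoyant particles.
#'
#' @return A [buffer_spec()].
#' @export
buffer_water <- function() buffer_spec(density = 997, viscosity = 0.89e-3)

#' @rdname buffer_water
#' @export
buffer_pbs <- function() buffer_spec(density = 1000, viscosity = 1e-3)

#' Syringe geometry specification
#'
#' A horizontal syringe is modelled as a cylindrical barrel of radius
#' `barrel_radius` and length `barrel_length`, closed at the downstream end
#' by a flat wall that carries a circular outlet of radius `outlet_radius`.
#' The outlet centre may be displaced vertically by `outlet_offset`:
#' 0 is a concentric outlet, `-(R_S - R_O)` places it flush with the bottom
#' edge and `+(R_S - R_O)` flush with the top edge.
#'
#' @param barrel_radius Barrel inner radius R_S in metres.
#' @param barrel_length Barrel length L_S in metres.
#' @param outlet_radius Outlet radius R_O in metres, 0 < R_O < R_S.
#' @param outlet_length Outlet tube length in metres (transit bookkeeping
#'   only; the tube interior is not simulated).
#' @param outlet_offset Signed vertical outlet-centre offset in metres,
#'   |offset| <= R_S - R_O.
#' @return An object of class `syringe_spec`.
#' @examples
#' # the 1 ml glass syringe barrel used with polymer beads
#' syr <- syringe_spec(barrel_radius = 2.3e-3, barrel_length = 40e-3,
#'                     outlet_radius = 0.5e-3, outlet_length = 5e-3)
#' @export
syringe_spec <- function(barrel_radius, barrel_length,
                         outlet_radius, outlet_length,
                         outlet_offset = 0) {
  stop_if_not_positive(barrel_radius = barrel_radius,
                       barrel_length = barrel_length,
                       outlet_radius = outlet_radius,
                       outlet_length = outlet_length)
  if (outlet_radius >= barrel_radius)
    stop("`outlet_radius` must be smaller than `barrel_radius`", call. = FALSE)
  if (!is.numeric(outlet_offset) || length(outlet_offset) != 1 ||
      !is.finite(outlet_offset))
    stop("`outlet_offset` must be a finite number", call. = FALSE)
  if (abs(outlet_offset) > barrel_radius - outlet_radius + 1e-12)
    stop("|outlet_offset| must not exceed barrel_radius - outlet_radius",
         call. = FALSE)
  structure(list(barrel_radius = barrel_radius,
                 barrel_length = barrel_length,
                 outlet_radius = outlet_radius,
                 outlet_length = outlet_length,
                 outlet_offset = outlet_offset),
            class = "syringe_spec")
}

#' Eccentric variant of a syringe
#'
#' Returns the same barrel with the outlet moved flush against the bottom
#' (`"bottom"`) or top (`"top"`) edge, or back on the axis (`"concentric"`).
#'
#' @param s A [syringe_spec()].
#' @param position One of `"concentric"`, `"bottom"`, `"top"`.
#' @return A [syringe_spec()].
#' @export
with_outlet <- function(s, position = c("concentric", "bottom", "top")) {
  stopifnot(inherits(s, "syringe_spec"))
  position <- match.arg(position)
  off <- switch(position,
                concentric = 0,
                bottom = -(s$barrel_radius - s$outlet_radius),
                top = s$barrel_radius - s$outlet_radius)
  syringe_spec(s$barrel_radius, s$barrel_length, s$outlet_radius,
               s$outlet_length, outlet_offset = off)
}

#' Physical constants
#'
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(g = 9.81) {
  stop_if_not_positive(g = g)
  structure(list(g = g), class = "model_constants")
}

#' Effective-concentration curve container
#'
#' Holds a time series of the effective concentration ratio `C_E(t)/C_0`
#' together with its provenance. Analytic sources are exact boundary-model
#' evaluations; `simulated` curves come from particle tracking and `measured`
#' curves from the detector signal chain.
#'
#' @param times Sample times in seconds, non-decreasing.
#' @param ratio Effective concentration ratio values.
#' @param source One of `"analytic_upper"`, `"analytic_lower"`, `"simulated"`,
#'   `"measured"`.
#' @param effective_area Optional series of effective cross-section areas in
#'   m^2 matching `times`.
#' @param meta Optional named list of provenance (specs, seeds, windows).
#' @return An object of class `concentration_curve`.
#' @export
concentration_curve <- function(times, ratio,
                                source = c("analytic_upper", "analytic_lower",
                                           "simulated", "measured"),
                                effective_area = NULL, meta = list()) {
  source <- match.arg(source)
  if (length(times) != length(ratio))
    stop("`times` and `ratio` must have the same length", call. = FALSE)
  if (length(times) && is.unsorted(times))
    stop("`times` must be non-decreasing", call. = FALSE)
  if (startsWith(source, "analytic") &&
      any(ratio < -1e-9 | ratio > 1 + 1e-9))
    stop("analytic concentration ratios must lie in [0, 1]", call. = FALSE)
  structure(list(times = as.numeric(times), ratio = as.numeric(ratio),
                 source = source, effective_area = effective_area,
                 meta = meta),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve> source=%s, %d samples, t in [%g, %g] s\n",
              x$source, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> radius=%g m, density=%g kg/m^3\n",
              x$radius, x$density))
  invisible(x)
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf("<buffer_spec> density=%g kg/m^3, viscosity=%g Pa s\n",
              x$density, x$viscosity))
  invisible(x)
}

#' @export
print.syringe_spec <- function(x, ...) {
  cat(sprintf(
    "<syringe_spec> R_S=%g m, L_S=%g m, R_O=%g m, offset=%g m\n",
    x$barrel_radius, x$barrel_length, x$outlet_radius, x$outlet_offset))
  invisible(x)
}

# shared validator: every named argument must be a positive finite scalar
stop_if_not_positive <- function(...) {
  vals <- list(...)
  bad <- vapply(vals, function(v)
    !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0, logical(1))
  if (any(bad))
    stop("invalid parameter(s), must be positive finite scalars: ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
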