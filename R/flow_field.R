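#' Poiseuille velocity in the barrel
#'
#' Fully developed laminar pipe-flow profile for the barrel far upstream of
#' the outlet: axial component `2 Q / (pi R_S^2) (1 - rho^2 / R_S^2)` with
#' `rho` the radial distance from the barrel axis, zero transverse
#' components. This is the far-field closure of the semi-analytic flow
#' backend; its cross-section integral is exactly `Q`.
#'
#' @param s A [syringe_spec()].
#' @param Q Volumetric flow-rate in m^3/s, >= 0.
#' @param point Numeric length-3 vector `(x, y, z)` in metres, or an n x 3
#'   matrix of points. `x` horizontal, `y` vertical (gravity is -y),
#'   `z` axial with the outlet wall at `z = barrel_length`.
#' @return Velocity vector(s) in m/s, same shape as `point`.
#' @export
poiseuille_velocity <- function(s, Q, point) {
  stopifnot(inherits(s, "syringe_spec"))
  check_flow_rate(Q)
  pts <- as_points(point)
  rho2 <- pts[, 1]^2 + pts[, 2]^2
  if (any(rho2 > s$barrel_radius^2 * (1 + 1e-9)) ||
      any(pts[, 3] < -1e-9) || any(pts[, 3] > s$barrel_length + 1e-9))
    stop("point outside the barrel domain", call. = FALSE)
  vz <- 2 * Q / (pi * s$barrel_radius^2) *
    pmax(1 - rho2 / s$barrel_radius^2, 0)
  out <- unname(cbind(rep(0, length(vz)), 0, vz))
  restore_shape(out, point)
}

#' Point-sink velocity toward the outlet
#'
#' Half-space point-sink field centred on the outlet: magnitude
#' `Q / (2 pi r^2)` at distance `r` from the outlet centre, directed toward
#' it. This is the near-outlet closure of the semi-analytic backend, the
#' leading-order converging-streamline field of flow through a small hole in
#' a wall. Inside one outlet radius of the centre the magnitude is clamped
#' to its value at `r = R_O`, removing the point singularity (particles at
#' that range exit within a step or two anyway).
#'
#' @param outlet_center Numeric length-3 vector, the outlet centre.
#' @param Q Volumetric flow-rate in m^3/s.
#' @param point Point(s) as in [poiseuille_velocity()].
#' @param cap_radius Clamp radius in metres (default: none, pass the outlet
#'   radius to enable the cap).
#' @return Velocity vector(s) in m/s.
#' @export
sink_velocity <- function(outlet_center, Q, point, cap_radius = 0) {
  check_flow_rate(Q)
  stopifnot(is.numeric(outlet_center), length(outlet_center) == 3)
  pts <- as_points(point)
  dx <- outlet_center[1] - pts[, 1]
  dy <- outlet_center[2] - pts[, 2]
  dz <- outlet_center[3] - pts[, 3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r_eff <- pmax(r, cap_radius)
  mag <- ifelse(r_eff > 0, Q / (2 * pi * r_eff^2), 0)
  scale <- ifelse(r > 0, mag / r, 0)
  out <- cbind(dx * scale, dy * scale, dz * scale)
  restore_shape(out, point)
}

#' Build a creeping-flow field for the barrel-plus-outlet geometry
#'
#' Constructs the steady velocity field used by the particle tracker.
#' Two backends are available:
#'
#' * `"superposition"` (default): a semi-analytic field that blends the
#'   Poiseuille far field into the point-sink near field over a transition
#'   zone of length `2 R_S` upstream of the outlet wall, using a smoothstep
#'   weight. The axial Poiseuille amplitude is rescaled station by station
#'   so that the net axial flux through every cross-section equals `Q`
#'   (the sink's share of the flux is pre-integrated numerically on a grid
#'   of axial stations and interpolated). Supports eccentric outlets: the
#'   sink sits at the offset outlet centre.
#' * `"stokes_axisym"`: a numerical solution of the axisymmetric
#'   creeping-flow stream-function equation `E^4 psi = 0` on an (r, z)
#'   grid, with no-slip walls, a Poiseuille inlet and Poiseuille outflow
#'   through the outlet hole. Concentric outlets only; used to validate the
#'   superposition field.
#'
#' The returned object's `evaluate` function maps an n x 3 matrix of points
#' to an n x 3 matrix of velocities. `Q = 0` yields the zero field.
#'
#' @param s A [syringe_spec()].
#' @param Q Volumetric flow-rate in m^3/s, >= 0.
#' @param backend `"superposition"` or `"stokes_axisym"`.
#' @param ... Backend options: `nr`, `nz` grid sizes for `stokes_axisym`
#'   (defaults 64 and 256).
#' @return An object of class `flow_field` with fields `syringe`, `Q`,
#'   `backend`, `evaluate`.
#' @export
build_flow_field <- function(s, Q, backend = c("superposition",
                                               "stokes_axisym"), ...) {
  stopifnot(inherits(s, "syringe_spec"))
  check_flow_rate(Q)
  backend <- match.arg(backend)
  if (backend == "stokes_axisym" && s$outlet_offset != 0)
    stop("the stokes_axisym backend supports concentric outlets only",
         call. = FALSE)
  evaluate <- if (Q == 0) {
    function(points) {
      pts <- as_points(points)
      matrix(0, nrow(pts), 3)
    }
  } else if (backend == "superposition") {
    superposition_evaluator(s, Q)
  } else {
    stokes_axisym_evaluator(s, Q, ...)
  }
  structure(list(syringe = s, Q = Q, backend = backend, evaluate = evaluate),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> backend=%s, Q=%g m^3/s, R_S=%g m\n",
              x$backend, x$Q, x$syringe$barrel_radius))
  invisible(x)
}

# Superposition backend ------------------------------------------------------

# smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

superposition_evaluator <- function(s, Q) {
  R_S <- s$barrel_radius
  L_S <- s$barrel_length
  centre <- c(0, s$outlet_offset, L_S)
  transition <- 2 * R_S
  z0 <- L_S - transition

  # Pre-integrate the sink's axial flux through cross-sections inside the
  # transition zone so the Poiseuille amplitude can absorb the difference
  # and keep flux(z) = Q exactly.
  z_grid <- seq(z0, L_S, length.out = 41)
  flux_grid <- vapply(z_grid, function(z)
    sink_axial_flux(s, Q, z, centre), numeric(1))
  sink_flux_at <- stats::approxfun(z_grid, flux_grid, rule = 2)

  two_q_over_piR2 <- 2 * Q / (pi * R_S^2)

  function(points) {
    pts <- as_points(points)
    z <- pts[, 3]
    w <- smoothstep((z - z0) / transition)
    a <- 1 - w * sink_flux_at(pmin(pmax(z, z0), L_S)) / Q
    a[z <= z0] <- 1
    rho2 <- pts[, 1]^2 + pts[, 2]^2
    vz_p <- two_q_over_piR2 * pmax(1 - rho2 / R_S^2, 0)
    vs <- sink_velocity(centre, Q, pts, cap_radius = s$outlet_radius)
    cbind(w * vs[, 1],
          w * vs[, 2],
          a * vz_p + w * vs[, 3])
  }
}

# numeric axial flux of the capped sink field through the cross-section at z
# (polar quadrature, equal-area rings)
sink_axial_flux <- function(s, Q, z, centre, n_r = 48, n_theta = 32) {
  R_S <- s$barrel_radius
  # equal-area annuli midpoints
  r_edges <- R_S * sqrt(seq(0, 1, length.out = n_r + 1))
  r_mid <- sqrt((r_edges[-1]^2 + r_edges[-(n_r + 1)]^2) / 2)
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  grid <- expand.grid(r = r_mid, th = theta)
  pts <- cbind(grid$r * cos(grid$th), grid$r * sin(grid$th), z)
  v <- sink_velocity(centre, Q, pts, cap_radius = s$outlet_radius)
  cell_area <- pi * R_S^2 / (n_r * n_theta)
  sum(v[, 3]) * cell_area
}

#' Net axial flux through a barrel cross-section
#'
#' Numerically integrates the axial velocity over the cross-section at
#' station `z` (equal-area polar quadrature). Used to verify mass
#' conservation of the flow backends: the result should equal the imposed
#' flow-rate `Q` at every station.
#'
#' @param f A [build_flow_field()] object.
#' @param z Axial station in metres within the barrel.
#' @param n_r,n_theta Quadrature resolution.
#' @return Volumetric flux in m^3/s.
#' @export
cross_section_flux <- function(f, z, n_r = 64, n_theta = 48) {
  stopifnot(inherits(f, "flow_field"))
  s <- f$syringe
  if (z < 0 || z > s$barrel_length)
    stop("`z` must lie within the barrel", call. = FALSE)
  R_S <- s$barrel_radius
  r_edges <- R_S * sqrt(seq(0, 1, length.out = n_r + 1))
  r_mid <- sqrt((r_edges[-1]^2 + r_edges[-(n_r + 1)]^2) / 2)
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  grid <- expand.grid(r = r_mid, th = theta)
  pts <- cbind(grid$r * cos(grid$th), grid$r * sin(grid$th), z)
  v <- f$evaluate(pts)
  cell_area <- pi * R_S^2 / (n_r * n_theta)
  sum(v[, 3]) * cell_area
}

#' Export a flow field on a regular grid
#'
#' Samples the field on a regular Cartesian grid restricted to the fluid
#' domain and writes one row per sample as tab-separated text with columns
#' `x y z vx vy vz` (SI units) and provenance header comments.
#'
#' @param f A [build_flow_field()] object.
#' @param path Output file path.
#' @param nx,ny,nz Grid resolution per axis.
#' @return Invisibly, the sampled data frame.
#' @export
export_flow_field <- function(f, path, nx = 9, ny = 9, nz = 33) {
  stopifnot(inherits(f, "flow_field"))
  s <- f$syringe
  g <- expand.grid(
    x = seq(-s$barrel_radius, s$barrel_radius, length.out = nx),
    y = seq(-s$barrel_radius, s$barrel_radius, length.out = ny),
    z = seq(0, s$barrel_length, length.out = nz))
  g <- g[g$x^2 + g$y^2 <= s$barrel_radius^2, , drop = FALSE]
  v <- f$evaluate(as.matrix(g))
  out <- data.frame(g, vx = v[, 1], vy = v[, 2], vz = v[, 3])
  header <- c(
    sprintf("# syrsed %s flow field export", package_version_string()),
    sprintf("# backend: %s, Q_m3_s: %g", f$backend, f$Q),
    sprintf("# barrel_radius_m: %g, barrel_length_m: %g, outlet_radius_m: %g, outlet_offset_m: %g",
            s$barrel_radius, s$barrel_length, s$outlet_radius,
            s$outlet_offset),
    paste(names(out), collapse = "\t"))
  writeLines(header, path)
  utils::write.table(out, path, append = TRUE, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out)
}

# helpers ---------------------------------------------------------------------

check_flow_rate <- function(Q) {
  if (!is.numeric(Q) || length(Q) != 1 || !is.finite(Q) || Q < 0)
    stop("`Q` must be a finite non-negative scalar flow-rate", call. = FALSE)
  invisible(TRUE)
}

as_points <- function(point) {
  if (is.matrix(point)) {
    if (ncol(point) != 3) stop("points must be n x 3", call. = FALSE)
    point
  } else if (is.numeric(point) && length(point) == 3) {
    matrix(point, 1, 3)
  } else stop("`point` must be a length-3 vector or an n x 3 matrix",
              call. = FALSE)
}

restore_shape <- function(out, point) {
  if (!is.matrix(point)) drop(out) else out
}

#' Convert the customary laboratory flow-rate unit
#'
#' @param ul_min Flow-rate in microlitres per minute.
#' @return Flow-rate in m^3/s.
#' @export
ul_min <- function(ul_min) ul_min * 1e-9 / 60

package_version_string <- function() {
  as.character(utils::packageVersion("syrsed"))
}
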