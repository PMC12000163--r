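# Axisymmetric creeping-flow backend.
#
# Solves E^4 psi = 0 on the (r, z) rectangle [0, R_S] x [0, L_S] for the
# Stokes stream function psi, where E^2 = d2/dr2 - (1/r) d/dr + d2/dz2,
# as the coupled second-order system  E^2 psi = chi,  E^2 chi = 0.
# Velocities: u_z = (1/r) dpsi/dr, u_r = -(1/r) dpsi/dz.
#
# Boundary conditions:
#   axis r = 0:        psi = 0, chi = 0 (regularity)
#   side wall r = R_S: psi = Q/(2 pi); no-slip du/dr = 0 imposed through a
#                      ghost-node (Thom-type) relation defining chi at the
#                      wall from the adjacent psi values
#   inlet z = 0:       Poiseuille profile, psi and chi prescribed in closed
#                      form (chi = -4 Q r^2 / (pi R^4))
#   end wall z = L_S:  psi = Q/(2 pi) on the solid annulus r > R_O with a
#                      ghost-node chi relation; Poiseuille outflow through
#                      the hole r <= R_O, psi and chi prescribed
#
# A direct sparse LU solve of the coupled system (2 * nr * nz unknowns) is
# used; at the default 64 x 256 grid this takes a few seconds.

stokes_axisym_evaluator <- function(s, Q, nr = 64, nz = 256) {
  sol <- solve_stokes_axisym(s, Q, nr = nr, nz = nz)
  R_S <- s$barrel_radius
  L_S <- s$barrel_length

  function(points) {
    pts <- as_points(points)
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    z <- pmin(pmax(pts[, 3], 0), L_S)
    uz <- bilinear(sol$r, sol$z, sol$uz, pmin(r, R_S), z)
    ur <- bilinear(sol$r, sol$z, sol$ur, pmin(r, R_S), z)
    safe_r <- ifelse(r > 0, r, 1)
    cx <- ifelse(r > 0, pts[, 1] / safe_r, 0)
    cy <- ifelse(r > 0, pts[, 2] / safe_r, 0)
    cbind(ur * cx, ur * cy, uz)
  }
}

solve_stokes_axisym <- function(s, Q, nr = 64, nz = 256) {
  R_S <- s$barrel_radius
  L_S <- s$barrel_length
  R_O <- s$outlet_radius
  r <- seq(0, R_S, length.out = nr)
  z <- seq(0, L_S, length.out = nz)
  dr <- r[2] - r[1]
  dz <- z[2] - z[1]
  psi_wall <- Q / (2 * pi)

  idx_psi <- function(i, j) (j - 1L) * nr + i
  idx_chi <- function(i, j) nr * nz + (j - 1L) * nr + i
  n_unk <- 2L * nr * nz

  # closed-form Poiseuille stream function / E^2 psi for flux Q in radius R
  psi_pois <- function(rr, R) (Q / pi) * (rr^2 / R^2 - rr^4 / (2 * R^4))
  chi_pois <- function(rr, R) -4 * Q * rr^2 / (pi * R^4)

  cap <- 12L * nr * nz
  trip_i <- integer(cap); trip_j <- integer(cap); trip_x <- numeric(cap)
  n_trip <- 0L
  rhs <- numeric(n_unk)
  eq <- 0L
  add <- function(cols, vals) {
    k <- seq_along(cols) + n_trip
    trip_i[k] <<- rep.int(eq, length(cols))
    trip_j[k] <<- cols
    trip_x[k] <<- vals
    n_trip <<- n_trip + length(cols)
  }

  inv_dr2 <- 1 / dr^2
  inv_dz2 <- 1 / dz^2

  for (j in seq_len(nz)) {
    for (i in seq_len(nr)) {
      ri <- r[i]
      on_axis <- i == 1L
      on_wall <- i == nr
      at_inlet <- j == 1L
      at_end <- j == nz
      in_hole <- at_end && ri <= R_O + 1e-12

      # --- psi equation ---
      eq <- idx_psi(i, j)
      if (on_axis) {
        add(idx_psi(i, j), 1); rhs[eq] <- 0
      } else if (at_inlet) {
        add(idx_psi(i, j), 1); rhs[eq] <- psi_pois(ri, R_S)
      } else if (in_hole) {
        add(idx_psi(i, j), 1); rhs[eq] <- psi_pois(ri, R_O)
      } else if (on_wall || at_end) {
        add(idx_psi(i, j), 1); rhs[eq] <- psi_wall
      } else {
        # E^2 psi - chi = 0
        a_e <- inv_dr2 - 1 / (2 * dr * ri)   # i+1
        a_w <- inv_dr2 + 1 / (2 * dr * ri)   # i-1
        add(c(idx_psi(i + 1L, j), idx_psi(i - 1L, j),
              idx_psi(i, j + 1L), idx_psi(i, j - 1L),
              idx_psi(i, j), idx_chi(i, j)),
            c(a_e, a_w, inv_dz2, inv_dz2,
              -2 * inv_dr2 - 2 * inv_dz2, -1))
        rhs[eq] <- 0
      }

      # --- chi equation ---
      eq <- idx_chi(i, j)
      if (on_axis) {
        add(idx_chi(i, j), 1); rhs[eq] <- 0
      } else if (at_inlet) {
        add(idx_chi(i, j), 1); rhs[eq] <- chi_pois(ri, R_S)
      } else if (in_hole) {
        add(idx_chi(i, j), 1); rhs[eq] <- chi_pois(ri, R_O)
      } else if (on_wall) {
        # no-slip du_z/... : dpsi/dr = 0 -> ghost psi(nr+1) = psi(nr-1)
        # chi = 2 (psi_{nr-1} - psi_nr)/dr^2 + z-part
        jm <- max(j - 1L, 1L); jp <- min(j + 1L, nz)
        add(c(idx_chi(i, j), idx_psi(i - 1L, j), idx_psi(i, j),
              idx_psi(i, jp), idx_psi(i, jm)),
            c(1, -2 * inv_dr2, 2 * inv_dr2 + 2 * inv_dz2,
              -inv_dz2, -inv_dz2))
        rhs[eq] <- 0
      } else if (at_end) {
        # solid end wall (r > R_O): u_r = 0 -> dpsi/dz = 0 -> ghost
        # chi = r-part + 2 (psi_{j-1} - psi_j)/dz^2
        a_e <- inv_dr2 - 1 / (2 * dr * ri)
        a_w <- inv_dr2 + 1 / (2 * dr * ri)
        im <- i - 1L; ip <- min(i + 1L, nr)
        add(c(idx_chi(i, j), idx_psi(ip, j), idx_psi(im, j),
              idx_psi(i, j), idx_psi(i, j - 1L)),
            c(1, -a_e, -a_w, 2 * inv_dr2 + 2 * inv_dz2, -2 * inv_dz2))
        rhs[eq] <- 0
      } else {
        # E^2 chi = 0
        a_e <- inv_dr2 - 1 / (2 * dr * ri)
        a_w <- inv_dr2 + 1 / (2 * dr * ri)
        add(c(idx_chi(i + 1L, j), idx_chi(i - 1L, j),
              idx_chi(i, j + 1L), idx_chi(i, j - 1L), idx_chi(i, j)),
            c(a_e, a_w, inv_dz2, inv_dz2, -2 * inv_dr2 - 2 * inv_dz2))
        rhs[eq] <- 0
      }
    }
  }

  A <- Matrix::sparseMatrix(i = trip_i[seq_len(n_trip)],
                            j = trip_j[seq_len(n_trip)],
                            x = trip_x[seq_len(n_trip)],
                            dims = c(n_unk, n_unk))
  # two-sided equilibration: Dirichlet rows are O(1) while PDE rows are
  # O(1/dr^2) and psi is orders of magnitude smaller than chi; rescaling
  # keeps the sparse LU condition estimate finite
  r_scale <- 1 / apply_abs_max(A, 1)
  A <- Matrix::Diagonal(x = r_scale) %*% A
  c_scale <- 1 / apply_abs_max(A, 2)
  A <- A %*% Matrix::Diagonal(x = c_scale)
  sol <- c_scale * as.numeric(Matrix::solve(A, r_scale * rhs))
  psi <- matrix(sol[seq_len(nr * nz)], nr, nz)

  # velocities by central differences; axis limit u_z = 2 psi(dr) / dr^2
  uz <- matrix(0, nr, nz)
  ur <- matrix(0, nr, nz)
  for (i in 2:(nr - 1)) {
    uz[i, ] <- (psi[i + 1, ] - psi[i - 1, ]) / (2 * dr * r[i])
  }
  uz[1, ] <- 2 * psi[2, ] / dr^2
  uz[nr, ] <- 0  # no-slip wall
  for (j in 2:(nz - 1)) {
    ur[2:nr, j] <- -(psi[2:nr, j + 1] - psi[2:nr, j - 1]) / (2 * dz * r[2:nr])
  }
  ur[, 1] <- 0
  ur[, nz] <- 0

  list(r = r, z = z, psi = psi, uz = uz, ur = ur)
}

# max |entry| per row (margin = 1) or column (margin = 2) of a sparse matrix
apply_abs_max <- function(A, margin) {
  T <- methods::as(A, "TsparseMatrix")
  idx <- if (margin == 1) T@i + 1L else T@j + 1L
  out <- numeric(dim(A)[margin])
  agg <- tapply(abs(T@x), idx, max)
  out[as.integer(names(agg))] <- agg
  out[out == 0] <- 1
  out
}

# bilinear interpolation of matrix f over grids x (rows), y (cols)
bilinear <- function(x, y, f, xq, yq) {
  nx <- length(x); ny <- length(y)
  ix <- findInterval(xq, x, rightmost.closed = TRUE)
  iy <- findInterval(yq, y, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  tx <- (xq - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (yq - y[iy]) / (y[iy + 1L] - y[iy])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  f00 <- f[cbind(ix, iy)]
  f10 <- f[cbind(ix + 1L, iy)]
  f01 <- f[cbind(ix, iy + 1L)]
  f11 <- f[cbind(ix + 1L, iy + 1L)]
  f00 * (1 - tx) * (1 - ty) + f10 * tx * (1 - ty) +
    f01 * (1 - tx) * ty + f11 * tx * ty
}
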