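# Geodesic shooting of diffeomorphisms from initial velocity fields.
#
# The EPDiff dynamical system is Euler-integrated over unit time: the initial
# momentum u0 = L^t L v0 is transported by the evolving inverse map (resampled,
# rescaled by the Jacobian determinant and multiplied by the transposed
# Jacobian), smoothed by the Green's function K to give the current velocity,
# and both the forward map phi and its inverse are updated by composition.
# Everything lives on the template grid in voxel units with circulant
# boundaries.

fd_jacobian <- function(disp, dims) {
  # J = I + central differences of the displacement, periodic wrap
  d <- length(dims)
  M <- prod(dims)
  J <- array(0, c(M, d, d))
  for (j in seq_len(d)) {
    A <- array(disp[, j], dims)
    for (l in seq_len(d)) {
      J[, j, l] <- as.numeric(shift_axis_wrap(A, l, 1L) -
                              shift_axis_wrap(A, l, -1L)) / 2
    }
    J[, j, j] <- J[, j, j] + 1
  }
  J
}

det_field <- function(J) {
  d <- dim(J)[2]
  if (d == 2L) {
    J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  } else {
    J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  }
}

sample_field_wrap <- function(fm, dims, P, degree = 1L) {
  # sample a multi-column field (stored as M x nc matrix) at voxel coords P
  nc <- ncol(fm)
  S <- spline_rep(array(fm, c(dims, nc)), degree, "wrap", channels = 1L)
  out <- spline_eval(S, P)$values
  if (nc == 1L) out <- matrix(out, ncol = 1L) else out
  out
}

deformation <- function(phi, J, detJ, dims) {
  structure(list(phi = phi, J = J, detJ = detJ, dims = dims),
            class = "deformation")
}

#' @export
print.deformation <- function(x, ...) {
  cat("<deformation> grid ", paste(x$dims, collapse = " x "),
      " | detJ in [", format(min(x$detJ), digits = 4), ", ",
      format(max(x$detJ), digits = 4), "]\n", sep = "")
  invisible(x)
}

shoot_steps <- function(T_units) as.integer(ceiling(3 * T_units) + 2L)

#' Geodesic shooting of an initial velocity field
#'
#' Integrates the EPDiff system with forward Euler over unit time, using
#' `ceiling(3 * T_units) + 2` steps, and returns the forward diffeomorphism
#' phi (template voxel coordinates to template voxel coordinates) together
#' with its inverse, Jacobian tensor fields, and determinants.  Momentum is
#' conserved along the trajectory up to integration error; the energy trace
#' is returned for diagnostics.
#'
#' @param v0 initial velocity, `prod(dims)` x d matrix in voxel units per unit
#'   time (an array of dim c(dims, d) is also accepted).
#' @param reg a [vel_reg()].
#' @param dims template grid dimensions.
#' @param T_units time interval controlling the Euler step count.
#' @param steps explicit step count override.
#' @param sym,K precomputed operator symbol / Green's function (optional).
#' @param degree interpolation degree used inside the integrator (cubic by
#'   default; linear is faster but its interpolation diffusion dominates the
#'   momentum-conservation error).
#' @return list with `fwd` and `inv` [deformation] objects and
#'   `energy_trace`, the per-step values of |L v_t|^2.
#' @export
geodesic_shoot_full <- function(v0, reg, dims, T_units = 1, steps = NULL,
                                sym = NULL, K = NULL, degree = 3L) {
  d <- length(dims)
  M <- prod(dims)
  v0 <- matrix(v0, M, d)
  stopifnot(all(is.finite(v0)))
  if (is.null(sym)) sym <- vel_operator_symbol(reg, dims)
  if (is.null(K)) K <- make_greens(sym)
  if (is.null(steps)) steps <- shoot_steps(T_units)
  dt <- 1 / steps
  X <- grid_coords(dims)
  u0 <- apply_LdagL(v0, sym)
  phi_disp <- matrix(0, M, d)
  psi_disp <- matrix(0, M, d)
  energy <- numeric(steps)
  for (s in seq_len(steps)) {
    if (s == 1L) {
      u_t <- u0
    } else {
      Jpsi <- fd_jacobian(psi_disp, dims)
      dpsi <- det_field(Jpsi)
      u0_at <- sample_field_wrap(u0, dims, X + psi_disp, degree)
      u_t <- matrix(0, M, d)
      for (j in seq_len(d)) {
        for (k in seq_len(d)) {
          u_t[, j] <- u_t[, j] + Jpsi[, k, j] * u0_at[, k]
        }
        u_t[, j] <- u_t[, j] * dpsi
      }
    }
    v_t <- apply_greens(u_t, K)
    energy[s] <- sum(v_t * u_t)
    # forward map: phi <- phi + dt * v_t(phi)
    v_at_phi <- sample_field_wrap(v_t, dims, X + phi_disp, degree)
    phi_disp <- phi_disp + dt * v_at_phi
    # inverse map: psi <- psi o (id - dt v_t)
    Pq <- X - dt * v_t
    psi_disp <- sample_field_wrap(psi_disp, dims, Pq, degree) - dt * v_t
  }
  Jf <- fd_jacobian(phi_disp, dims)
  detf <- det_field(Jf)
  Ji <- fd_jacobian(psi_disp, dims)
  deti <- det_field(Ji)
  if (any(detf <= 0) || any(deti <= 0)) {
    stop("non-positive Jacobian determinant during shooting: ",
         "regularization too weak or initial velocity too large ",
         "(min detJ = ", format(min(detf, deti), digits = 4), ")")
  }
  list(fwd = deformation(X + phi_disp, Jf, detf, dims),
       inv = deformation(X + psi_disp, Ji, deti, dims),
       energy_trace = energy)
}

#' @rdname geodesic_shoot_full
#' @export
geodesic_shoot <- function(v0, reg, dims, T_units = 1, steps = NULL,
                           sym = NULL, K = NULL) {
  geodesic_shoot_full(v0, reg, dims, T_units, steps, sym, K)$fwd
}

#' @rdname geodesic_shoot_full
#' @export
shoot_inverse <- function(v0, reg, dims, T_units = 1, steps = NULL,
                          sym = NULL, K = NULL) {
  geodesic_shoot_full(v0, reg, dims, T_units, steps, sym, K)$inv
}

#' Compose two deformations sampled on the template grid
#'
#' Returns a(b(x)) evaluated at the grid, i.e. the map applying `b` first.
#' Displacements are interpolated with periodic wrap.
#'
#' @param a,b [deformation] objects (or plain coordinate matrices).
#' @param dims grid dimensions.
#' @export
compose_maps <- function(a, b, dims) {
  X <- grid_coords(dims)
  pa <- if (inherits(a, "deformation")) a$phi else a
  pb <- if (inherits(b, "deformation")) b$phi else b
  da <- pa - X
  X <- X # identity coords
  disp_at <- sample_field_wrap(da, dims, pb)
  pb + disp_at
}

identity_error <- function(a, b, dims) {
  # max |a(b(x)) - x| in voxels
  X <- grid_coords(dims)
  max(abs(compose_maps(a, b, dims) - X))
}
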