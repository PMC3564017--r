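# Differential operators on fields.
#
# Velocity fields live on the template grid with circulant (periodic) boundary
# semantics, so the momentum operator L^t L and its Green's function K are
# applied spectrally via the FFT.  Log-inhomogeneity fields use a bending
# energy (squared Laplacian) with Neumann boundaries, applied as an explicit
# stencil.

#' Velocity-field regularizer
#'
#' The operator combines linear elasticity and bending energy:
#' omega1 penalizes stretching and shearing (symmetrized gradient), omega2
#' penalizes divergence (volume change of the velocity flow), omega3 the
#' bending energy (squared vector Laplacian), and omega0 absolute
#' displacements (zero by default; the rigid component accounts for global
#' translations).  `scale` multiplies the whole operator and implements the
#' per-scan acquisition-timing adjustment (energy per unit time).
#'
#' @param omega1,omega2,omega3 non-negative weights; `omega3` must be positive
#'   unless `omega0` is, so the Green's function stays bounded.
#' @param omega0 absolute-displacement weight.
#' @param vox voxel sizes in mm (velocities are stored in voxel units).
#' @param scale overall operator scale (1 / |t_n| for timed scans).
#' @export
vel_reg <- function(omega1 = 0.001, omega2 = 0.001, omega3 = 2,
                    omega0 = 0, vox = NULL, scale = 1) {
  stopifnot(omega1 >= 0, omega2 >= 0, omega3 >= 0, omega0 >= 0, scale > 0)
  if (omega3 <= 0 && omega0 <= 0) {
    stop("omega3 (bending energy) must be positive when omega0 is zero: ",
         "pure length-change or divergence penalties have singular kernels")
  }
  structure(list(omega = c(omega1, omega2, omega3), omega0 = omega0,
                 vox = vox, scale = scale), class = "vel_reg")
}

freq_diff <- function(n, h) {
  th <- 2 * pi * (0:(n - 1)) / n
  (exp(1i * th) - 1) / h
}

axis_array <- function(x, dims, k) {
  d <- length(dims)
  shape <- rep(1L, d); shape[k] <- dims[k]
  aperm(array(rep(x, prod(dims) / dims[k]), c(dims[k], dims[-k])),
        order(c(k, seq_len(d)[-k])))
}

#' Spectral symbol of the momentum operator L^t L
#'
#' Assembles, per spatial frequency, the d x d Hermitian matrix of the
#' self-adjoint operator built from forward-difference stencils under
#' periodic boundaries.  Velocities are in voxel units; anisotropic voxel
#' sizes enter through the per-axis spacing.
#'
#' @param reg a [vel_reg()].
#' @param dims template grid dimensions.
#' @return list-of-lists (d x d) of complex arrays plus attributes.
#' @export
vel_operator_symbol <- function(reg, dims) {
  d <- length(dims)
  vox <- reg$vox
  if (is.null(vox)) vox <- rep(1, d)
  dk <- vector("list", d)
  for (k in seq_len(d)) {
    dk[[k]] <- axis_array(freq_diff(dims[k], vox[k]), dims, k)
  }
  S <- array(0, dims)   # sum |d_k|^2
  for (k in seq_len(d)) S <- S + Re(dk[[k]] * Conj(dk[[k]]))
  l2 <- S^2             # squared (negated) Laplacian symbol
  o <- reg$omega
  A <- vector("list", d)
  for (j in seq_len(d)) {
    A[[j]] <- vector("list", d)
    for (l in seq_len(d)) {
      diagpart <- if (j == l) reg$omega0 + o[3] * l2 + (o[1] / 2) * S else 0
      off <- (o[1] / 2) * dk[[j]] * Conj(dk[[l]]) +
        o[2] * Conj(dk[[j]]) * dk[[l]]
      # conjugation by voxel sizes: stored velocities are in voxel units
      A[[j]][[l]] <- reg$scale * vox[j] * vox[l] * (diagpart + off)
    }
  }
  attr(A, "dims") <- dims
  attr(A, "d") <- d
  A
}

vf_fft <- function(vm, dims, inverse = FALSE) {
  d <- ncol(vm)
  out <- vector("list", d)
  for (j in seq_len(d)) {
    out[[j]] <- fft(array(vm[, j], dims), inverse = inverse)
  }
  out
}

vf_ifft_real <- function(vl, dims) {
  M <- prod(dims)
  d <- length(vl)
  out <- matrix(0, M, d)
  for (j in seq_len(d)) {
    out[, j] <- Re(fft(vl[[j]], inverse = TRUE)) / M
  }
  out
}

#' Apply the momentum operator: u = L^t L v
#'
#' @param v velocity field, `prod(dims)` x d matrix (voxel units).
#' @param sym symbol from [vel_operator_symbol()].
#' @return momentum field, same shape as `v`.
#' @export
apply_LdagL <- function(v, sym) {
  dims <- attr(sym, "dims")
  vh <- vf_fft(v, dims)
  uh <- mat_field_apply(sym, vh)
  vf_ifft_real(uh, dims)
}

#' Green's function of the momentum operator
#'
#' Spectral (pseudo-)inverse of the L^t L symbol with the DC coefficient
#' forced to zero: K (L^t L) v = v - mean(v).  Acts as a low-pass filter
#' turning momentum into velocity.
#'
#' @param sym symbol from [vel_operator_symbol()].
#' @param ridge added to the diagonal before inversion (0 for the exact
#'   Green's function; used when building preconditioners).
#' @return symbol-like structure usable with [apply_greens()].
#' @export
make_greens <- function(sym, ridge = 0) {
  dims <- attr(sym, "dims")
  d <- attr(sym, "d")
  A <- sym
  if (ridge > 0) {
    for (j in seq_len(d)) A[[j]][[j]] <- A[[j]][[j]] + ridge
  }
  # guard: the symbol must be invertible off DC
  K <- mat_field_inv(A)
  if (ridge == 0) {
    for (j in seq_len(d)) for (l in seq_len(d)) {
      K[[j]][[l]][1] <- 0
      if (any(!is.finite(K[[j]][[l]]))) {
        stop("singular operator symbol off DC; invalid regularization")
      }
    }
  }
  attr(K, "dims") <- dims
  attr(K, "d") <- d
  K
}

#' Apply a spectral kernel (Green's function) to a field
#'
#' @param u momentum-like field (`prod(dims)` x d matrix).
#' @param K kernel from [make_greens()].
#' @export
apply_greens <- function(u, K) {
  dims <- attr(K, "dims")
  uh <- vf_fft(u, dims)
  vh <- mat_field_apply(K, uh)
  vf_ifft_real(vh, dims)
}

# ---- scalar-field bending-energy operator (bias fields) ---------------------

#' Bias-field regularizer
#'
#' Bending energy of the log-inhomogeneity field:
#' `|L_b b|^2 = omega0 * sum((laplacian b)^2)` with Neumann boundaries (zero
#' gradient at the edge of the field of view).
#'
#' @param omega0 positive regularization weight.  The default makes fields
#'   with ~16 cm wavelength nearly free while crushing voxel-scale variation
#'   for typical MR intensity scales.
#' @param vox voxel sizes in mm.
#' @export
bias_reg <- function(omega0 = 1e6, vox = NULL) {
  stopifnot(omega0 > 0)
  structure(list(omega0 = omega0, vox = vox), class = "bias_reg")
}

shift_axis <- function(A, k, by) {
  # shift with edge replication (half-sample Neumann boundary)
  dims <- dim(A)
  n <- dims[k]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  args <- rep(list(quote(expr = )), length(dims))
  args[[k]] <- idx
  do.call(`[`, c(list(A), args, list(drop = FALSE)))
}

lap_neumann <- function(A, vox = NULL) {
  dims <- dim(A)
  d <- length(dims)
  if (is.null(vox)) vox <- rep(1, d)
  out <- array(0, dims)
  for (k in seq_len(d)) {
    out <- out + (shift_axis(A, k, 1L) + shift_axis(A, k, -1L) - 2 * A) /
      vox[k]^2
  }
  out
}

#' Apply the bias operator: L_b^t L_b b = omega0 * laplacian(laplacian(b))
#'
#' @param b scalar field (array of grid dims, or vector with `dims`).
#' @param reg a [bias_reg()].
#' @param dims grid dimensions when `b` is a plain vector.
#' @export
apply_bias_op <- function(b, reg, dims = dim(b)) {
  B <- array(as.numeric(b), dims)
  as.numeric(reg$omega0 * lap_neumann(lap_neumann(B, reg$vox), reg$vox))
}

#' Bending energy of a log-bias field
#'
#' `0.5 * omega0 * sum((laplacian b)^2)`, the penalty term of the
#' inhomogeneity objective.
#'
#' @inheritParams apply_bias_op
#' @export
bias_penalty <- function(b, reg, dims = dim(b)) {
  B <- array(as.numeric(b), dims)
  L <- lap_neumann(B, reg$vox)
  0.5 * reg$omega0 * sum(L^2)
}

# circulant symbol of the periodic analogue (used only as a preconditioner)
bias_precond_symbol <- function(reg, dims, c0) {
  d <- length(dims)
  vox <- reg$vox
  if (is.null(vox)) vox <- rep(1, d)
  S <- array(0, dims)
  for (k in seq_len(d)) {
    th <- 2 * pi * (0:(dims[k] - 1)) / dims[k]
    S <- S + axis_array((2 - 2 * cos(th)) / vox[k]^2, dims, k)
  }
  1 / (c0 + reg$omega0 * S^2)
}

# ---- preconditioned conjugate gradients -------------------------------------

#' Preconditioned conjugate gradients
#'
#' Generic PCG on flattened fields; both the bias and the velocity
#' Gauss-Newton systems (voxel-wise data terms coupled by a smooth
#' regularization operator) are solved with it, with spectral inverses of the
#' regularizer as preconditioners.
#'
#' @param applyA function(x) returning A x.
#' @param b right-hand side vector.
#' @param precond function(r) applying the preconditioner inverse.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return list(x, iterations, relres, converged).
#' @export
pcg <- function(applyA, b, precond = identity, tol = 1e-8, maxit = 500L) {
  x <- numeric(length(b))
  r <- b
  nb <- sqrt(sum(b * b))
  if (nb == 0) {
    return(list(x = x, iterations = 0L, relres = 0, converged = TRUE))
  }
  z <- precond(r)
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- applyA(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r * r)) / nb
    if (rel < tol) {
      return(list(x = x, iterations = it, relres = rel, converged = TRUE))
    }
    z <- precond(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, iterations = maxit, relres = sqrt(sum(r * r)) / nb,
       converged = FALSE)
}

#' Divergence of a velocity field
#'
#' Central differences with periodic wrap; the first-order rate of local
#' volume change of the flow, the longitudinal expansion/contraction readout.
#'
#' @param v `prod(dims)` x d velocity field (voxel units).
#' @param dims grid dimensions.
#' @export
divergence_field <- function(v, dims) {
  d <- length(dims)
  out <- numeric(prod(dims))
  for (k in seq_len(d)) {
    A <- array(v[, k], dims)
    n <- dims[k]
    fwd <- shift_axis_wrap(A, k, 1L)
    bwd <- shift_axis_wrap(A, k, -1L)
    out <- out + as.numeric(fwd - bwd) / 2
  }
  out
}

shift_axis_wrap <- function(A, k, by) {
  dims <- dim(A)
  n <- dims[k]
  idx <- ((seq_len(n) - 1L + by) %% n) + 1L
  args <- rep(list(quote(expr = )), length(dims))
  args[[k]] <- idx
  do.call(`[`, c(list(A), args, list(drop = FALSE)))
}

#' Central-difference spatial gradient of a template-grid field
#'
#' Periodic wrap; the exact negative adjoint of [divergence_field()] on the
#' discrete grid, which makes integration by parts exact in the discrete
#' objective.
#'
#' @param r vector over the grid.
#' @param dims grid dimensions.
#' @return `prod(dims)` x d matrix.
#' @export
central_gradient <- function(r, dims) {
  d <- length(dims)
  A <- array(r, dims)
  out <- matrix(0, prod(dims), d)
  for (k in seq_len(d)) {
    out[, k] <- as.numeric(shift_axis_wrap(A, k, 1L) -
                           shift_axis_wrap(A, k, -1L)) / 2
  }
  out
}
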