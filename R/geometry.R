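# Voxel-to-world affine handling, SE(2)/SE(3) Lie-group utilities, and the
# construction of the average-position template space.
#
# All operations are generic over d in {2, 3}.  A rigid transform is
# parameterized by a vector q in the Lie algebra: 3 translations then 3
# rotation parameters in 3D (6 total), 2 translations and 1 rotation in 2D.

se_dim <- function(nq) {
  if (nq == 6L) 3L else if (nq == 3L) 2L
  else stop("q must have length 6 (3D) or 3 (2D)")
}

#' Lie-algebra generators of SE(2)/SE(3)
#'
#' Generator i is the derivative of the rigid transform with respect to q_i at
#' the identity.  Translations occupy the last column; the rotation block is
#' antisymmetric.
#'
#' @param nq 6 for SE(3), 3 for SE(2).
#' @return list of (d+1) x (d+1) matrices.
#' @export
se_generators <- function(nq = 6L) {
  d <- se_dim(nq)
  G <- vector("list", nq)
  for (i in seq_len(d)) {
    g <- matrix(0, d + 1, d + 1)
    g[i, d + 1] <- 1
    G[[i]] <- g
  }
  if (d == 2L) {
    g <- matrix(0, 3, 3)
    g[1, 2] <- -1; g[2, 1] <- 1
    G[[3]] <- g
  } else {
    # rotation generators: antisymmetric block laid out with q4 coupling
    # axes (1,2), q5 axes (1,3), q6 axes (2,3)
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    signs <- c(1, -1, 1)
    for (i in 1:3) {
      g <- matrix(0, 4, 4)
      p <- pairs[[i]]
      g[p[1], p[2]] <- signs[i]
      g[p[2], p[1]] <- -signs[i]
      G[[3L + i]] <- g
    }
  }
  G
}

se_generator_sum <- function(q) {
  G <- se_generators(length(q))
  Q <- matrix(0, nrow(G[[1]]), ncol(G[[1]]))
  for (i in seq_along(q)) Q <- Q + q[i] * G[[i]]
  Q
}

#' Rigid-body transform from Lie-algebra parameters
#'
#' Matrix exponential of the SE(2)/SE(3) generator combination.  The result
#' has an orthonormal rotation block with determinant +1.
#'
#' @param q numeric vector of length 6 (3D) or 3 (2D).
#' @return (d+1) x (d+1) homogeneous rigid transform.
#' @export
se_exp <- function(q) {
  mat_exp(se_generator_sum(q))
}

#' Derivatives of the rigid transform with respect to its parameters
#'
#' Directional (Frechet) derivative of the matrix exponential along each
#' generator, computed exactly via the block-triangular augmented exponential
#' exp([Q, G; 0, Q]).
#'
#' @param q as in [se_exp()].
#' @return list of (d+1) x (d+1) matrices, the i-th being dR_q / dq_i.
#' @export
se_exp_derivatives <- function(q) {
  G <- se_generators(length(q))
  Q <- se_generator_sum(q)
  n <- nrow(Q)
  out <- vector("list", length(q))
  for (i in seq_along(q)) {
    Aug <- rbind(cbind(Q, G[[i]]), cbind(matrix(0, n, n), Q))
    out[[i]] <- mat_exp(Aug)[1:n, (n + 1):(2 * n)]
  }
  out
}

#' Exponential barycenter of a set of affine transforms
#'
#' Fixed-point iteration `B <- B %*% mat_exp(mean_n mat_log(solve(B) %*% M_n))`
#' until the Frobenius norm of the mean log falls below `tol`.  At the
#' barycenter the Lie-algebra discrepancies from the mean to all transforms
#' sum to zero (a bi-invariant group mean).
#'
#' @param maps list of invertible (d+1) x (d+1) matrices.
#' @param tol convergence tolerance on the Frobenius norm of the mean log.
#' @param max_iter iteration cap; non-convergence signals wildly inconsistent
#'   voxel-to-world headers.
#' @return the barycenter matrix.
#' @export
exponential_barycenter <- function(maps, tol = 1e-10, max_iter = 100L) {
  stopifnot(length(maps) >= 1L)
  n <- nrow(maps[[1]])
  for (M in maps) stopifnot(is.matrix(M), nrow(M) == n, ncol(M) == n)
  B <- maps[[1]]
  for (it in seq_len(max_iter)) {
    S <- matrix(0, n, n)
    Binv <- solve(B)
    for (M in maps) S <- S + mat_log(Binv %*% M)
    S <- S / length(maps)
    if (norm(S, "F") < tol) return(B)
    B <- B %*% mat_exp(S)
  }
  stop("exponential barycenter did not converge after ", max_iter,
       " iterations (inconsistent headers?)")
}

rot_param_dim <- function(d) if (d == 2L) 1L else 3L

# assemble T(translation) %*% R(rotation) %*% S(exp(log-scales))
trs_matrix <- function(tr, rot, logsc) {
  d <- length(tr)
  R <- se_exp(c(rep(0, d), rot))[1:d, 1:d, drop = FALSE]
  A <- R %*% diag(exp(logsc), d)
  M <- diag(d + 1)
  M[1:d, 1:d] <- A
  M[1:d, d + 1] <- tr
  M
}

#' Closest nine-parameter (translation-rotation-scale) transform
#'
#' Finds the product T R S (translation, rotation, axis-aligned positive
#' scaling; nine parameters in 3D, five in 2D) minimizing the Frobenius
#' distance to `target`, by Levenberg-Marquardt on (translation, rotation
#' Lie-algebra, log-scales).
#'
#' @param target invertible (d+1) x (d+1) affine.
#' @param start optional starting affine (defaults to a polar-decomposition
#'   initialization of `target`).
#' @return (d+1) x (d+1) matrix of the form T R S.
#' @export
closest_nine_param <- function(target, start = NULL) {
  d <- nrow(target) - 1L
  A <- target[1:d, 1:d, drop = FALSE]
  if (abs(det(A)) < 1e-12) stop("degenerate target affine (singular block)")
  if (det(A) < 0) {
    stop("target has negative determinant; cannot be matched by a ",
         "rotation with positive scales")
  }
  sv <- svd(A)
  R0 <- sv$u %*% t(sv$v)
  if (det(R0) < 0) { # flip smallest singular direction to stay in SO(d)
    u <- sv$u; u[, d] <- -u[, d]
    R0 <- u %*% t(sv$v)
  }
  s0 <- log(pmax(diag(t(R0) %*% A), 1e-8))
  r0 <- if (d == 2L) {
    atan2(R0[2, 1], R0[1, 1])
  } else {
    W <- mat_log(R0)
    c(W[1, 2], -W[1, 3], W[2, 3])
  }
  p0 <- c(target[1:d, d + 1], r0, s0)
  resid <- function(p) {
    tr <- p[1:d]
    rot <- p[(d + 1):(d + rot_param_dim(d))]
    logsc <- p[(d + rot_param_dim(d) + 1):length(p)]
    as.numeric(trs_matrix(tr, rot, logsc) - target)
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  p <- fit$par
  trs_matrix(p[1:d], p[(d + 1):(d + rot_param_dim(d))],
             p[(d + rot_param_dim(d) + 1):length(p)])
}

#' Scan image container
#'
#' One time-point: a scalar voxel grid, its voxel-to-world affine, a noise
#' precision, and an optional acquisition time.
#'
#' @param f numeric array (2D or 3D) of intensities.
#' @param M voxel-to-world affine ((d+1) x (d+1)); defaults to identity.
#' @param lam noise precision (1 / noise variance), must be positive.
#' @param t acquisition time in years, or `NA` when unused.
#' @export
scan_image <- function(f, M = NULL, lam = 1, t = NA_real_) {
  f <- as.array(f)
  d <- length(dim(f))
  stopifnot(d %in% c(2L, 3L), all(is.finite(f)), lam > 0)
  if (is.null(M)) M <- diag(d + 1)
  stopifnot(nrow(M) == d + 1, ncol(M) == d + 1,
            all(M[d + 1, ] == c(rep(0, d), 1)))
  structure(list(f = f, M = M, lam = lam, t = t, dims = dim(f)),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat("<scan_image> ", paste(x$dims, collapse = " x "),
      " | lam = ", format(x$lam), " | t = ", format(x$t), "\n", sep = "")
  invisible(x)
}

#' Template space definition
#'
#' @param dims integer grid dimensions.
#' @param M_mu voxel-to-world affine of the template grid (factors as
#'   translation . rotation . axis-aligned scaling).
#' @export
template_space <- function(dims, M_mu) {
  structure(list(dims = as.integer(dims), M_mu = M_mu),
            class = "template_space")
}

affine_points <- function(M, P) {
  d <- ncol(P)
  P %*% t(M[1:d, 1:d, drop = FALSE]) +
    matrix(M[1:d, d + 1], nrow(P), d, byrow = TRUE)
}

corner_coords <- function(dims) {
  d <- length(dims)
  as.matrix(do.call(expand.grid,
                    lapply(dims, function(n) c(0, n - 1))))
}

voxel_sizes <- function(M) {
  d <- nrow(M) - 1L
  sqrt(colSums(M[1:d, 1:d, drop = FALSE]^2))
}

#' Average-position template space for a group of scans
#'
#' The template's world mapping is the closest nine-parameter transform to the
#' exponential barycenter of the scans' voxel-to-world affines, with the
#' scales replaced by per-axis geometric means of the input voxel sizes and
#' the translation adjusted so the grid covers every projected image corner
#' with a margin.
#'
#' @param scans list of [scan_image()].
#' @param margin bounding-box margin in template voxels.
#' @return a [template_space()].
#' @export
compute_template_space <- function(scans, margin = 2) {
  stopifnot(length(scans) >= 1L)
  d <- length(scans[[1]]$dims)
  maps <- lapply(scans, `[[`, "M")
  B <- exponential_barycenter(maps)
  M9 <- closest_nine_param(B)
  # impose geometric-mean voxel sizes on the scale part
  vs <- exp(rowMeans(log(sapply(maps, voxel_sizes))))
  A <- M9[1:d, 1:d, drop = FALSE]
  Rpart <- A %*% diag(1 / voxel_sizes(M9), d)
  M9[1:d, 1:d] <- Rpart %*% diag(vs, d)
  Minv <- solve(M9)
  lo <- rep(Inf, d); hi <- rep(-Inf, d)
  for (s in scans) {
    pc <- affine_points(s$M, corner_coords(s$dims))
    pv <- affine_points(Minv, pc)
    lo <- pmin(lo, apply(pv, 2, min))
    hi <- pmax(hi, apply(pv, 2, max))
  }
  lo <- lo - margin
  hi <- hi + margin
  dims <- as.integer(ceiling(hi - lo) + 1L)
  # shift translation so template voxel 0 maps to the world point of `lo`
  M_new <- M9
  M_new[1:d, d + 1] <- M9[1:d, 1:d, drop = FALSE] %*% lo + M9[1:d, d + 1]
  template_space(dims, M_new)
}
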