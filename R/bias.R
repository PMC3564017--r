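# Group-wise intensity-inhomogeneity (bias) correction.
#
# Each aligned image is modeled as the template scaled by the exponential of
# a smooth log-field b_n, regularized by the bending energy of b_n.  Only
# N - 1 relative fields are identifiable; subtracting the voxel-wise mean of
# the b_n each iteration drives the geometric mean of the multiplicative
# fields to one.

#' Template update for inhomogeneity correction
#'
#' mu = sum_n lam_n f_n e^{b_n} / sum_n lam_n e^{2 b_n}, the exact minimizer
#' of the matching term with the fields held fixed.
#'
#' @param fs list of aligned image vectors/arrays (common grid).
#' @param biases list of log-field vectors (same grid).
#' @param lams numeric vector of noise precisions.
#' @return template intensity vector.
#' @export
update_template_bias <- function(fs, biases, lams) {
  num <- 0; den <- 0
  for (n in seq_along(fs)) {
    eb <- exp(as.numeric(biases[[n]]))
    num <- num + lams[n] * as.numeric(fs[[n]]) * eb
    den <- den + lams[n] * eb * eb
  }
  num / den
}

#' Derivatives of the inhomogeneity objective for one image
#'
#' Gradient `-a * mu + L_b^t L_b b` with `a = lam e^b (f - mu e^b)`, and the
#' diagonal Gauss-Newton data Hessian `w * mu^2` with `w = lam e^{2b}`.
#' Exact at voxel level: the field is parameterized by one value per voxel.
#'
#' @param f image vector; `mu` template vector; `b` log-field vector.
#' @param lam noise precision.
#' @param reg a [bias_reg()].
#' @param dims grid dimensions.
#' @return list(grad, hess_diag).
#' @export
bias_derivatives <- function(f, mu, b, lam, reg, dims) {
  f <- as.numeric(f); mu <- as.numeric(mu); b <- as.numeric(b)
  eb <- exp(b)
  a <- lam * eb * (f - mu * eb)
  grad <- -a * mu + apply_bias_op(b, reg, dims)
  hess <- lam * eb * eb * mu * mu
  list(grad = grad, hess_diag = hess)
}

#' Gauss-Newton update step for a bias field
#'
#' Solves `(diag(hess_diag) + L_b^t L_b) delta = -grad` by preconditioned
#' conjugate gradients with a circulant spectral preconditioner.
#'
#' @param grad gradient vector.
#' @param hess_diag diagonal data Hessian vector.
#' @param reg a [bias_reg()].
#' @param dims grid dimensions.
#' @param tol relative residual tolerance of the solve.
#' @return the update `delta` (to be added to `b`).
#' @export
bias_gn_step <- function(grad, hess_diag, reg, dims, tol = 1e-8) {
  c0 <- mean(hess_diag)
  pre_sym <- bias_precond_symbol(reg, dims, max(c0, 1e-12))
  M <- prod(dims)
  pre <- function(r) {
    as.numeric(Re(fft(fft(array(r, dims)) * pre_sym, inverse = TRUE))) / M
  }
  sol <- pcg(function(x) hess_diag * x + apply_bias_op(x, reg, dims),
             -grad, pre, tol = tol, maxit = 1000L)
  if (!sol$converged) {
    warning("bias Gauss-Newton solve did not reach tolerance (relres = ",
            format(sol$relres), ")")
  }
  sol$x
}

bias_objective_scan <- function(f, mu, b, lam, reg, dims) {
  eb <- exp(as.numeric(b))
  0.5 * lam * sum((as.numeric(f) - as.numeric(mu) * eb)^2) +
    bias_penalty(b, reg, dims)
}

#' Group-wise inhomogeneity field estimation
#'
#' Alternates the template update with per-image Gauss-Newton updates of the
#' log-fields (step-halving safeguarded), subtracting the voxel-wise mean
#' field after every round so that `sum_n b_n = 0` and the geometric mean of
#' the multiplicative fields is one.
#'
#' @param fs list of N >= 2 aligned images (vectors or arrays on one grid).
#' @param lams noise precisions.
#' @param reg a [bias_reg()].
#' @param dims grid dimensions.
#' @param max_iter,tol outer loop controls.
#' @param mean_correct subtract the mean field each iteration (the Algorithm 2
#'   constraint; the combined model disables it).
#' @return list(biases, mu, objective, converged).
#' @export
groupwise_bias <- function(fs, lams, reg, dims, max_iter = 30L, tol = 1e-8,
                           mean_correct = TRUE) {
  N <- length(fs)
  stopifnot(N >= 2L, length(lams) == N)
  M <- prod(dims)
  biases <- rep(list(numeric(M)), N)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- update_template_bias(fs, biases, lams)
    obj <- 0
    for (n in seq_len(N)) {
      obj <- obj + bias_objective_scan(fs[[n]], mu, biases[[n]], lams[n],
                                       reg, dims)
    }
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) <= tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- obj
    for (n in seq_len(N)) {
      der <- bias_derivatives(fs[[n]], mu, biases[[n]], lams[n], reg, dims)
      delta <- bias_gn_step(der$grad, der$hess_diag, reg, dims)
      f_old <- bias_objective_scan(fs[[n]], mu, biases[[n]], lams[n], reg,
                                   dims)
      step <- 1
      for (h in 0:8) {
        b_try <- biases[[n]] + step * delta
        f_new <- bias_objective_scan(fs[[n]], mu, b_try, lams[n], reg, dims)
        if (f_new <= f_old) {
          biases[[n]] <- b_try
          break
        }
        step <- step / 2
      }
    }
    if (mean_correct) {
      bbar <- Reduce(`+`, biases) / N
      biases <- lapply(biases, function(b) b - bbar)
    }
  }
  mu <- update_template_bias(fs, biases, lams)
  list(biases = biases, mu = mu, objective = trace, converged = converged)
}

#' Pairwise ratio-field estimation
#'
#' For two aligned images the zero-mean constraint reduces the model to a
#' single field with b_2 = -b_1; this minimizes that reduced objective
#' directly (Gauss-Newton with step halving) and agrees with the general
#' two-image group-wise solution at the fixed point.
#'
#' @param f1,f2 aligned images.
#' @param lam1,lam2 noise precisions.
#' @param reg a [bias_reg()].
#' @param dims grid dimensions.
#' @param max_iter,tol iteration controls.
#' @return list(b1, objective, converged); the second field is `-b1`.
#' @export
pairwise_ratio_field <- function(f1, f2, lam1, lam2, reg, dims,
                                 max_iter = 50L, tol = 1e-10) {
  f1 <- as.numeric(f1); f2 <- as.numeric(f2)
  M <- prod(dims)
  b <- numeric(M)
  # profiling the template out of the two-image objective under b2 = -b1
  # gives residual f1 e^{-b1} - f2 e^{b1} over D = lam1 e^{2b1} + lam2 e^{-2b1}
  objective <- function(b) {
    e <- exp(b)
    r <- f1 / e - f2 * e
    D <- lam1 * e^2 + lam2 / e^2
    0.5 * lam1 * lam2 * sum(r * r / D) + 2 * bias_penalty(b, reg, dims)
  }
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- exp(b)
    r <- f1 / e - f2 * e
    s <- f1 / e + f2 * e
    D <- lam1 * e^2 + lam2 / e^2
    Dp <- 2 * (lam1 * e^2 - lam2 / e^2)
    grad <- lam1 * lam2 * (-r * s / D - 0.5 * r * r * Dp / D^2) +
      2 * apply_bias_op(b, reg, dims)
    hess <- lam1 * lam2 * s * s / D
    reg2 <- reg; reg2$omega0 <- 2 * reg$omega0
    delta <- bias_gn_step(grad, hess, reg2, dims)
    f_old <- objective(b)
    trace <- c(trace, f_old)
    if (is.finite(prev) && abs(prev - f_old) <= tol * max(abs(prev), 1e-300)) {
      converged <- TRUE
      break
    }
    prev <- f_old
    step <- 1
    for (h in 0:8) {
      b_try <- b + step * delta
      if (objective(b_try) <= f_old) {
        b <- b_try
        break
      }
      step <- step / 2
    }
  }
  list(b1 = b, objective = trace, converged = converged)
}
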