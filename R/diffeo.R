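# Group-wise diffeomorphic registration by Gauss-Newton on initial
# velocities (geodesic shooting), with the zero-mean-momentum constraint
# keeping the template in the group's average shape.

#' Template update for diffeomorphic registration
#'
#' mu = sum_n lam_n |D phi_n| f_n(phi_n) / sum_n lam_n |D phi_n|.
#'
#' @param warped list of warped image vectors f_n(phi_n) on the template grid.
#' @param detJs list of Jacobian determinant vectors |D phi_n|.
#' @param lams noise precisions.
#' @param masks optional list of in-FOV masks.
#' @return list(mu, mask).
#' @export
update_template_diffeo <- function(warped, detJs, lams, masks = NULL) {
  num <- 0; den <- 0
  for (n in seq_along(warped)) {
    w <- lams[n] * detJs[[n]]
    if (!is.null(masks)) w <- w * masks[[n]]
    num <- num + w * warped[[n]]
    den <- den + w
  }
  mask <- den > 0
  list(mu = ifelse(mask, num / pmax(den, .Machine$double.xmin), NA_real_),
       mask = mask)
}

#' Template gradients driving the registration
#'
#' g = sum_n lam_n |D phi_n| grad(f_n o phi_n) / sum_n lam_n |D phi_n|,
#' where grad(f_n o phi_n) = (D phi_n)^T (grad f_n)(phi_n) (pulled-back scan
#' gradients).  Deliberately not the spatial gradient of mu: the extra
#' Jacobian-gradient terms of that expression are harmful to the
#' registration.
#'
#' @param grads_pulled list of M x d pulled-back gradient matrices.
#' @param detJs,lams,masks as in [update_template_diffeo()].
#' @return M x d gradient field.
#' @export
template_gradients <- function(grads_pulled, detJs, lams, masks = NULL) {
  num <- 0; den <- 0
  for (n in seq_along(grads_pulled)) {
    w <- lams[n] * detJs[[n]]
    if (!is.null(masks)) w <- w * masks[[n]]
    num <- num + w * grads_pulled[[n]]
    den <- den + w
  }
  num / pmax(den, .Machine$double.xmin)
}

pull_through <- function(srep, def, X = NULL) {
  # warp an image through a deformation and pull back its gradient
  d <- length(def$dims)
  ev <- spline_eval(srep, def$phi, gradient = TRUE)
  gp <- matrix(0, nrow(def$phi), d)
  for (j in seq_len(d)) {
    for (k in seq_len(d)) gp[, j] <- gp[, j] + def$J[, k, j] * ev$grad[, k]
  }
  list(values = ev$values, grad_pulled = gp, mask = ev$mask)
}

#' First variation and Gauss-Newton weights for one velocity field
#'
#' Gradient field `a * g + L^t L v` with `a = lam |D phi| (f o phi - mu)` and
#' rank-one voxel Hessian weights `w = lam |D phi|`.
#'
#' @param a residual factor vector.
#' @param g M x d gradient field (shared, group-blended).
#' @param v current velocity (M x d).
#' @param sym operator symbol for this scan.
#' @param w weight vector.
#' @return list(grad_field, w).
#' @export
velocity_derivatives <- function(a, g, v, sym, w) {
  list(grad_field = a * g + apply_LdagL(v, sym), w = w)
}

#' Gauss-Newton solve for a velocity update
#'
#' Solves `(w g g^T + L^t L) delta = -grad` by PCG, preconditioned by the
#' spectral inverse of `L^t L + alpha I` with `alpha` the mean data-term
#' loading.
#'
#' @param grad_field M x d gradient field.
#' @param w voxel weights.
#' @param g M x d gradient field in the rank-one data term.
#' @param sym operator symbol.
#' @param tol relative residual tolerance.
#' @param rho Marquardt damping (0 for the plain Gauss-Newton system; larger
#'   values inflate the regularizer so the step shrinks toward a smoothed
#'   gradient direction).
#' @return M x d update delta.
#' @export
velocity_gn_step <- function(grad_field, w, g, sym, tol = 1e-6, rho = 0) {
  dims <- attr(sym, "dims")
  d <- attr(sym, "d")
  M <- prod(dims)
  alpha <- mean(w * rowSums(g * g)) / d
  # Marquardt damping inflates the regularizer: as rho grows the update
  # degrades gracefully into a short Green's-function-smoothed gradient step
  # (a tiny isotropic ridge keeps the DC mode solvable)
  opscale <- 1 + rho
  damp <- rho * max(alpha, 1e-12) * 1e-3
  ridge <- max(alpha, 1e-12) + damp
  Kp <- make_greens(sym, ridge = ridge / opscale)
  applyA <- function(x) {
    xm <- matrix(x, M, d)
    as.numeric(w * rowSums(g * xm) * g +
                 opscale * apply_LdagL(xm, sym) + damp * xm)
  }
  pre <- function(r) {
    as.numeric(apply_greens(matrix(r, M, d), Kp)) / opscale
  }
  sol <- pcg(applyA, -as.numeric(grad_field), pre, tol = tol,
             maxit = if (tol <= 1e-8) 2000L else 150L)
  if (!sol$converged && sol$relres > 1e-3) {
    warning("velocity Gauss-Newton solve did not reach tolerance (relres = ",
            format(sol$relres), ")")
  }
  matrix(sol$x, M, d)
}

# Levenberg-Marquardt-safeguarded velocity update: the Gauss-Newton system is
# re-solved with increasing damping until the proposed update decreases the
# scan objective (rank-one Hessians underestimate curvature badly on
# large-residual piecewise-constant images, where a plain full step
# overshoots).  Zero gradient still maps to a zero step for any damping.
lm_velocity_update <- function(grad_field, w, g, sym, rho, objective_of,
                               f_old, K = NULL, max_tries = 3L,
                               rho_cap = 1e4) {
  no_dc <- function(delta) {
    # velocities carry no DC component (global translations are the rigid
    # part's job); constraining the step keeps the later momentum
    # mean-correction from discarding accepted progress
    delta - matrix(colMeans(delta), nrow(delta), ncol(delta), byrow = TRUE)
  }
  for (tr in seq_len(max_tries)) {
    delta <- no_dc(velocity_gn_step(grad_field, w, g, sym, tol = 3e-5,
                                    rho = rho))
    f_new <- objective_of(delta)
    if (is.finite(f_new) && f_new <= f_old) {
      return(list(delta = delta, rho = max(rho / 10, 0), accepted = TRUE,
                  f_new = f_new))
    }
    rho <- if (rho <= 0) 1 else min(rho * 10, rho_cap)
  }
  # fall back to a line search along the kernel-smoothed gradient; the
  # Green's function filters the high-frequency components where the
  # discrete gradient is least reliable
  if (is.null(K)) K <- make_greens(sym)
  dir0 <- no_dc(-apply_greens(grad_field, K))
  # normalize to a bounded trial displacement so the line search starts at a
  # sensible scale regardless of how ill-conditioned the kernel is
  mx <- max(sqrt(rowSums(dir0 * dir0)))
  if (mx > 2) dir0 <- dir0 * (2 / mx)
  eta <- 1
  for (h in 1:14) {
    delta <- eta * dir0
    f_new <- objective_of(delta)
    if (is.finite(f_new) && f_new < f_old) {
      return(list(delta = delta, rho = max(rho / 10, 1), accepted = TRUE,
                  f_new = f_new))
    }
    eta <- eta / 2
  }
  list(delta = NULL, rho = 1, accepted = FALSE, f_new = f_old)
}

#' Zero-mean-momentum correction of a group of velocities
#'
#' ubar = mean_n L^t L v_n; v_n <- v_n - K_n ubar, then the DC component of
#' each velocity is projected out (the operator is blind to it and global
#' translations belong to the rigid part).  The mean momentum of the outputs
#' is the zero field to machine precision.
#'
#' @param vs list of M x d velocities.
#' @param syms list of per-scan operator symbols.
#' @param Ks list of per-scan Green's functions.
#' @return corrected list of velocities.
#' @export
zero_mean_momentum <- function(vs, syms, Ks) {
  N <- length(vs)
  ubar <- 0
  for (n in seq_len(N)) ubar <- ubar + apply_LdagL(vs[[n]], syms[[n]])
  ubar <- ubar / N
  out <- vector("list", N)
  for (n in seq_len(N)) {
    v <- vs[[n]] - apply_greens(ubar, Ks[[n]])
    v <- v - matrix(colMeans(v), nrow(v), ncol(v), byrow = TRUE)
    out[[n]] <- v
  }
  out
}

# The field-of-view mask is frozen during a scan's update (fixed_mask):
# otherwise boundary voxels enter and leave the data sum discontinuously
# under infinitesimal trial steps and the safeguard sees spurious jumps.
diffeo_objective_scan <- function(srep, v, lam, mu, mask_mu, reg, dims,
                                  sym, K, T_units = 1, fixed_mask = NULL) {
  sh <- geodesic_shoot_full(v, reg, dims, T_units, sym = sym, K = K)
  ev <- spline_eval(srep, sh$fwd$phi)
  m <- if (is.null(fixed_mask)) ev$mask & mask_mu else fixed_mask
  mu0 <- ifelse(is.na(mu), 0, mu)
  0.5 * lam * sum((sh$fwd$detJ * (ev$values - mu0)^2)[m]) +
    0.5 * sum(v * apply_LdagL(v, sym))
}

#' Group-wise diffeomorphic registration
#'
#' Per outer iteration: shoot all deformations, update the template and its
#' gradients, Gauss-Newton each initial velocity with step halving, then
#' mean-correct the momenta.  Runs coarse-to-fine over a multi-resolution
#' pyramid.  Scans are assumed rigidly pre-aligned on the template grid.
#'
#' @param images list of N >= 2 arrays on a common grid.
#' @param lams noise precisions.
#' @param reg a [vel_reg()] (common to all scans).
#' @param dims grid dimensions.
#' @param levels multi-resolution levels (1 = single scale).
#' @param max_iter outer iterations per level.
#' @param tol relative objective-change tolerance.
#' @param verbose print objective values.
#' @return list(velocities, template = list(mu, mask, g), objective,
#'   deformations, converged).
#' @export
groupwise_diffeo <- function(images, lams, reg, dims = dim(images[[1]]),
                             levels = 1L, max_iter = 20L, tol = 1e-6,
                             verbose = FALSE) {
  N <- length(images)
  stopifnot(N >= 2L)
  vs <- rep(list(matrix(0, prod(dims), length(dims))), N)
  res <- NULL
  for (lev in levels:1) {
    imgs <- lapply(images, function(f) smooth_level(array(f, dims), lev))
    res <- groupwise_diffeo_level(imgs, lams, reg, dims, vs, max_iter, tol,
                                  verbose)
    vs <- res$velocities
  }
  res
}

# Coarse-to-fine by image smoothing on a fixed grid: every stage shares one
# operator metric, so velocities carry over between stages without the
# metric-mismatch a resampling pyramid introduces.  Stage `lev` smooths with
# an effective kernel comparable to a 2^(lev-1)-fold downsampled grid.
smooth_level <- function(A, lev) {
  if (lev <= 1L) return(A)
  for (i in seq_len(2L * 4L^(lev - 2L))) A <- smooth_121(A)
  A
}

groupwise_diffeo_level <- function(images, lams, reg, dims, vs,
                                   max_iter, tol, verbose = FALSE) {
  N <- length(images)
  d <- length(dims)
  M <- prod(dims)
  sym <- vel_operator_symbol(reg, dims)
  K <- make_greens(sym)
  sreps <- lapply(images, function(f) spline_rep(array(f, dims), 3L, "reflect"))
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  shots <- vector("list", N)
  rhos <- rep(0, N)
  deltas <- rep(list(matrix(0, M, d)), N)
  for (it in seq_len(max_iter + 1L)) {
    for (n in seq_len(N)) {
      sv <- shoot_with_rescue(vs[[n]], reg, dims, sym = sym, K = K)
      vs[[n]] <- sv$v
      shots[[n]] <- sv$shot
    }
    pulls <- lapply(seq_len(N), function(n)
      pull_through(sreps[[n]], shots[[n]]$fwd))
    detJs <- lapply(shots, function(s) s$fwd$detJ)
    # the images live on the template grid itself: the whole grid is the
    # common field of view (reflected sampling extends the boundary), and a
    # stable integration domain keeps the objective consistent across
    # iterations
    masks <- rep(list(rep(TRUE, M)), N)
    tpl <- update_template_diffeo(lapply(pulls, `[[`, "values"), detJs,
                                  lams, masks)
    g <- template_gradients(lapply(pulls, `[[`, "grad_pulled"), detJs,
                            lams, masks)
    obj <- 0; dat <- 0; pen <- 0; nmask <- 0
    for (n in seq_len(N)) {
      m <- masks[[n]] & tpl$mask
      dat <- dat +
        0.5 * lams[n] * sum((detJs[[n]] * (pulls[[n]]$values - tpl$mu)^2)[m])
      pen <- pen + 0.5 * sum(vs[[n]] * apply_LdagL(vs[[n]], sym))
      nmask <- nmask + sum(m)
    }
    obj <- dat + pen
    trace <- c(trace, obj)
    if (verbose) message(sprintf(
      "diffeo iter %d: objective %.8g (data %.6g pen %.6g inFOV %d)",
      it - 1L, obj, dat, pen, nmask))
    if (it > max_iter ||
        (is.finite(prev) && abs(prev - obj) <= tol * abs(prev))) {
      converged <- it <= max_iter
      break
    }
    prev <- obj
    for (n in seq_len(N)) {
      m <- masks[[n]] & tpl$mask
      ed <- exact_data_gradient(pulls[[n]]$values, pulls[[n]]$grad_pulled,
                                detJs[[n]], tpl$mu, m, lams[n], dims)
      w <- lams[n] * detJs[[n]]
      w[!m] <- 0
      der <- list(grad_field = ed$G + apply_LdagL(vs[[n]], sym))
      f_old <- diffeo_objective_scan(sreps[[n]], vs[[n]], lams[n], tpl$mu,
                                     tpl$mask, reg, dims, sym, K,
                                     fixed_mask = m)
      upd <- lm_velocity_update(
        der$grad_field, w, ed$g_eff, sym, rhos[n],
        function(delta) tryCatch(
          diffeo_objective_scan(sreps[[n]], vs[[n]] + delta, lams[n],
                                tpl$mu, tpl$mask, reg, dims, sym, K,
                                fixed_mask = m),
          error = function(e) Inf),  # folding (detJ <= 0) rejects the step
        f_old, K = K)
      rhos[n] <- upd$rho
      deltas[[n]] <- if (upd$accepted) upd$delta else matrix(0, M, d)
    }
    # Global safeguard around the whole round: the momentum mean-correction
    # re-symmetrizes the group and can undo unevenly-sized per-scan steps,
    # so all steps are scaled together until the corrected state does not
    # increase the total objective (at scale 0 the correction is a no-op
    # because the constraint already held at the iteration start).
    tot0 <- 0
    for (n in seq_len(N)) {
      tot0 <- tot0 + diffeo_objective_scan(sreps[[n]], vs[[n]], lams[n],
                                           tpl$mu, tpl$mask, reg, dims,
                                           sym, K, fixed_mask = rep(TRUE, M))
    }
    tfac <- 1
    for (h in 1:8) {
      vs_try <- lapply(seq_len(N), function(n) vs[[n]] + tfac * deltas[[n]])
      vs_try <- zero_mean_momentum(vs_try, rep(list(sym), N),
                                   rep(list(K), N))
      tot1 <- tryCatch({
        s <- 0
        for (n in seq_len(N)) {
          s <- s + diffeo_objective_scan(sreps[[n]], vs_try[[n]], lams[n],
                                         tpl$mu, tpl$mask, reg, dims,
                                         sym, K,
                                         fixed_mask = rep(TRUE, M))
        }
        s
      }, error = function(e) Inf)
      if (is.finite(tot1) && tot1 <= tot0) {
        vs <- vs_try
        break
      }
      tfac <- tfac / 2
    }
  }
  list(velocities = vs, template = list(mu = tpl$mu, mask = tpl$mask, g = g),
       objective = trace, deformations = shots, converged = converged)
}

# A velocity that folds the grid (possible after the unsafeguarded momentum
# mean-correction or after prolongation to a finer level) is shortened until
# it shoots cleanly.
shoot_with_rescue <- function(v, reg, dims, T_units = 1, steps = NULL,
                              sym = NULL, K = NULL) {
  for (try in 0:10) {
    shot <- tryCatch(
      geodesic_shoot_full(v, reg, dims, T_units, steps, sym = sym, K = K),
      error = function(e) NULL)
    if (!is.null(shot)) {
      if (try > 0) {
        warning("velocity rescaled by 2^-", try,
                " to keep the deformation diffeomorphic")
      }
      return(list(v = v, shot = shot))
    }
    v <- v / 2
  }
  stop("could not obtain a diffeomorphic deformation even after rescaling")
}

# Exact discrete gradient of the warped-image data term under composition of
# the deformation with a small displacement.  The Jacobian-variation term is
# handled by discrete integration by parts (central_gradient is the exact
# negative adjoint of the central-difference divergence under wrap), which in
# the continuum turns the warped-scan gradient into the template-gradient
# form; g_eff is the corresponding direction used in the rank-one Hessian.
exact_data_gradient <- function(warped, grad_pulled, detJ, mu, mask, lam,
                                dims) {
  r <- warped - ifelse(is.na(mu), 0, mu)
  r[!mask] <- 0
  G <- lam * detJ * r * grad_pulled +
    0.5 * lam * (r^2 * central_gradient(detJ, dims) -
                   central_gradient(r^2 * detJ, dims))
  g_eff <- grad_pulled - central_gradient(r, dims)
  list(G = G, g_eff = g_eff, r = r)
}
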