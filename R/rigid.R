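# Group-wise rigid-body registration of all scans to the evolving mean.
#
# Each scan is matched to the template through the voxel-to-voxel affine
# xi_q = I M_n^-1 R_q M_mu, with R_q = se_exp(q) acting in world space.  The
# zero-mean constraint sum_n q_n = 0 (enforced by subtracting the mean after
# each round of Gauss-Newton updates) keeps the template in the group's
# average position.

#' Voxel-to-voxel map of a rigidly transformed scan
#'
#' @param q rigid parameters (length 6 in 3D, 3 in 2D).
#' @param M_n scan voxel-to-world affine.
#' @param M_mu template voxel-to-world affine.
#' @return (d+1) x (d+1) affine mapping template voxel coordinates to scan
#'   voxel coordinates, with the constant Jacobian determinant of its linear
#'   block as attribute `"detJ"`.
#' @export
rigid_map <- function(q, M_n, M_mu) {
  d <- nrow(M_mu) - 1L
  Xi <- solve(M_n) %*% se_exp(q) %*% M_mu
  attr(Xi, "detJ") <- det(Xi[1:d, 1:d, drop = FALSE])
  Xi
}

# warp all template voxels into scan n and sample intensities (+ gradients)
rigid_pull <- function(srep, Xi, X, gradient = FALSE) {
  d <- ncol(X)
  P <- affine_points(Xi, X)
  ev <- spline_eval(srep, P, gradient = gradient)
  out <- list(values = ev$values, mask = ev$mask,
              detJ = abs(attr(Xi, "detJ")))
  if (gradient) {
    # pull back: (D xi)^T grad f evaluated at xi(x)
    out$grad <- ev$grad %*% Xi[1:d, 1:d, drop = FALSE]
  }
  out
}

#' Template update for rigid registration
#'
#' Precision- and Jacobian-weighted mean of the resampled scans:
#' mu(x) = sum_n w_n f_n(xi_n x) / sum_n w_n, w_n = lam_n |D xi_n| inside the
#' common field of view, 0 outside.  Voxels with zero total weight are masked.
#'
#' @param scans list of [scan_image()].
#' @param rigids list of q vectors.
#' @param space a [template_space()].
#' @param degree interpolation degree for the scans.
#' @return list with `mu` (vector over template voxels), `mask`, and the
#'   per-scan pulls used.
#' @export
update_template_rigid <- function(scans, rigids, space, degree = 3L) {
  X <- grid_coords(space$dims)
  M <- nrow(X)
  num <- numeric(M); den <- numeric(M)
  pulls <- vector("list", length(scans))
  for (n in seq_along(scans)) {
    s <- scans[[n]]
    Xi <- rigid_map(rigids[[n]], s$M, space$M_mu)
    srep <- spline_rep(s$f, degree, "reflect")
    p <- rigid_pull(srep, Xi, X)
    w <- s$lam * p$detJ * p$mask
    num <- num + w * p$values
    den <- den + w
    pulls[[n]] <- p
  }
  mask <- den > 0
  mu <- ifelse(mask, num / pmax(den, .Machine$double.xmin), NA_real_)
  list(mu = mu, mask = mask, pulls = pulls)
}

# matching-term value for one scan, template frozen
rigid_objective_scan <- function(srep, Xi, X, lam, mu, mask_mu) {
  p <- rigid_pull(srep, Xi, X)
  m <- p$mask & mask_mu
  0.5 * lam * p$detJ * sum((p$values[m] - mu[m])^2)
}

#' Gauss-Newton derivatives of the rigid objective for one scan
#'
#' Gradient and positive semi-definite Hessian approximation of the matching
#' term with the template frozen.  The image gradient is sampled in the scan
#' and pulled back through the transpose of the affine Jacobian, so the
#' gradient is the exact derivative of the discrete objective (the template
#' gradient form coincides with it at the fixed point).
#'
#' @param scan a [scan_image()].
#' @param q current rigid parameters.
#' @param space template space.
#' @param mu template intensities (vector over template voxels).
#' @param mask_mu template validity mask.
#' @param srep optional precomputed spline representation of the scan.
#' @param g_override optional shared gradient field (M x d) to use instead of
#'   the per-scan pulled-back gradient (the combined model supplies the
#'   group-blended gradients here).
#' @param a_override,w_override optional residual / weight fields from the
#'   combined model.
#' @param points optional evaluation points for the generator fields h_i
#'   (the combined model evaluates them at the diffeomorphically deformed
#'   positions).
#' @return list(grad, hess) of dimensions nq and nq x nq.
#' @export
rigid_derivatives <- function(scan, q, space, mu, mask_mu = NULL,
                              srep = NULL, g_override = NULL,
                              a_override = NULL, w_override = NULL,
                              points = NULL) {
  d <- length(space$dims)
  nq <- if (d == 2L) 3L else 6L
  X <- grid_coords(space$dims)
  if (is.null(srep)) srep <- spline_rep(scan$f, 3L, "reflect")
  if (is.null(mask_mu)) mask_mu <- !is.na(mu)
  Xi <- rigid_map(q, scan$M, space$M_mu)
  p <- rigid_pull(srep, Xi, X, gradient = is.null(g_override))
  m <- p$mask & mask_mu
  if (!any(m)) {
    warning("empty overlap between scan and template")
    return(list(grad = numeric(nq), hess = matrix(0, nq, nq)))
  }
  g <- if (is.null(g_override)) p$grad else g_override
  a <- if (is.null(a_override)) {
    scan$lam * p$detJ * (p$values - mu)
  } else a_override
  w <- if (is.null(w_override)) rep(scan$lam * p$detJ, nrow(X)) else w_override
  a[!m] <- 0
  wm <- w; wm[!m] <- 0
  R <- se_exp(q)
  dR <- se_exp_derivatives(q)
  pre <- solve(space$M_mu) %*% solve(R)
  if (is.null(points)) points <- X
  gh <- matrix(0, nrow(X), nq)
  for (i in seq_len(nq)) {
    Hi <- pre %*% dR[[i]] %*% space$M_mu
    hi <- affine_points(Hi, points)
    gh[, i] <- rowSums(g * hi)
  }
  grad <- as.numeric(t(gh) %*% a)
  hess <- t(gh) %*% (wm * gh)
  list(grad = grad, hess = hess)
}

#' Group-wise rigid-body registration
#'
#' Alternates template re-estimation with per-scan Gauss-Newton updates of
#' the rigid parameters, applying a step-halving safeguard on the per-scan
#' objective, then subtracts the mean of the q_n so that `sum(q_n) = 0` and
#' the template stays in the average position.
#'
#' @param scans list of at least two [scan_image()].
#' @param space template space (computed from the headers if missing).
#' @param max_iter outer iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param max_halvings step halvings before an update is abandoned.
#' @param verbose print per-iteration objective values.
#' @return list with `rigids` (list of q), `template` (mu, mask),
#'   `objective` trace, and `converged`.
#' @export
groupwise_rigid <- function(scans, space = NULL, max_iter = 50L, tol = 1e-6,
                            max_halvings = 8L, verbose = FALSE) {
  stopifnot(length(scans) >= 2L)
  if (is.null(space)) space <- compute_template_space(scans)
  d <- length(space$dims)
  nq <- if (d == 2L) 3L else 6L
  N <- length(scans)
  X <- grid_coords(space$dims)
  sreps <- lapply(scans, function(s) spline_rep(s$f, 3L, "reflect"))
  rigids <- rep(list(numeric(nq)), N)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    tpl <- update_template_rigid(scans, rigids, space)
    obj <- 0
    for (n in seq_len(N)) {
      Xi <- rigid_map(rigids[[n]], scans[[n]]$M, space$M_mu)
      obj <- obj + rigid_objective_scan(sreps[[n]], Xi, X, scans[[n]]$lam,
                                        tpl$mu, tpl$mask)
    }
    trace <- c(trace, obj)
    if (verbose) message(sprintf("rigid iter %d: objective %.8g", it, obj))
    if (is.finite(prev) && abs(prev - obj) <= tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- obj
    for (n in seq_len(N)) {
      der <- rigid_derivatives(scans[[n]], rigids[[n]], space, tpl$mu,
                               tpl$mask, srep = sreps[[n]])
      H <- der$hess + diag(1e-8 * max(diag(der$hess), 1e-12), nq)
      delta <- solve(H, der$grad)
      f_old <- rigid_objective_scan(
        rigid_map(rigids[[n]], scans[[n]]$M, space$M_mu) , X = X,
        srep = sreps[[n]], lam = scans[[n]]$lam, mu = tpl$mu,
        mask_mu = tpl$mask)
      step <- 1
      accepted <- FALSE
      for (h in 0:max_halvings) {
        q_try <- rigids[[n]] - step * delta
        f_new <- rigid_objective_scan(
          rigid_map(q_try, scans[[n]]$M, space$M_mu), X = X,
          srep = sreps[[n]], lam = scans[[n]]$lam, mu = tpl$mu,
          mask_mu = tpl$mask)
        if (f_new <= f_old) {
          rigids[[n]] <- q_try
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted && verbose) {
        message(sprintf("rigid iter %d scan %d: step rejected", it, n))
      }
    }
    qbar <- Reduce(`+`, rigids) / N
    rigids <- lapply(rigids, function(q) q - qbar)
  }
  tpl <- update_template_rigid(scans, rigids, space)
  list(rigids = rigids, template = list(mu = tpl$mu, mask = tpl$mask),
       space = space, objective = trace, converged = converged)
}
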