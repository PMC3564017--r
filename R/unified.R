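# The combined generative model: each scan is a rigidly moved, diffeomorphically
# deformed version of the template, scaled by the exponential of a smooth
# inhomogeneity field, with known additive Gaussian noise.  All parameter
# groups are updated in an interleaved fashion against the single evolving
# template, per outer iteration: shoot, (mu, g), rigid + mean-correct,
# mu, bias (pushed forward to the scan grids, not mean-corrected),
# (mu, g), velocities + momentum mean-correct.

#' Acquisition-timing weights
#'
#' The template time is the median acquisition time; each scan's deformation
#' penalty becomes an energy per unit time, i.e. the operator is scaled by
#' 1 / |t_n| (clamped at `eps`).  Scans at the reference time are pinned:
#' their velocities stay zero.
#'
#' @param times numeric acquisition times in years (`NULL` or all-`NA` for
#'   pure group-wise mode with unit scales).
#' @param n number of scans (used when `times` is NULL).
#' @param eps clamp on |t_n| in years (one day).
#' @return list(t, scale, steps, pinned, reference).
#' @export
timing_weights <- function(times, n = length(times), eps = 1 / 365) {
  if (is.null(times) || all(is.na(times))) {
    return(list(t = rep(0, n), scale = rep(1, n),
                steps = rep(shoot_steps(1), n),
                pinned = rep(FALSE, n), reference = NA_real_))
  }
  stopifnot(!anyNA(times))
  ref <- stats::median(times)
  t_n <- times - ref
  if (all(t_n == 0)) {
    warning("all acquisition times are equal; using unit operator scales")
    return(list(t = t_n, scale = rep(1, n),
                steps = rep(shoot_steps(1), n),
                pinned = rep(FALSE, n), reference = ref))
  }
  at <- pmax(abs(t_n), eps)
  list(t = t_n, scale = 1 / at,
       steps = vapply(at, shoot_steps, integer(1)),
       pinned = abs(t_n) < eps, reference = ref)
}

#' Configuration for the combined longitudinal model
#'
#' @param vel_omega weights (stretch/shear, divergence, bending) of the
#'   velocity operator.
#' @param vel_abs absolute-displacement weight (0: translations belong to the
#'   rigid part).
#' @param bias_omega0 bending-energy weight of the log-inhomogeneity fields.
#' @param levels multi-resolution levels.
#' @param max_iter outer iterations per level.
#' @param tol relative objective-change tolerance.
#' @param bias_mean_correct subtract the voxel-wise mean log-field each outer
#'   iteration (off by default in the combined model).
#' @param max_halvings step halvings before an update is rejected.
#' @param verbose print objective components per iteration.
#' @export
longit_config <- function(vel_omega = c(0.001, 0.001, 2.0), vel_abs = 0,
                          bias_omega0 = 1e4, levels = 2L, max_iter = 10L,
                          tol = 1e-6, bias_mean_correct = FALSE,
                          max_halvings = 8L, verbose = FALSE) {
  list(vel_omega = vel_omega, vel_abs = vel_abs, bias_omega0 = bias_omega0,
       levels = as.integer(levels), max_iter = as.integer(max_iter),
       tol = tol, bias_mean_correct = bias_mean_correct,
       max_halvings = as.integer(max_halvings), verbose = verbose)
}

# ---- state assembly ---------------------------------------------------------

#' Interpolable representation of a log-inhomogeneity field
#'
#' Values are carried by linear interpolation (the voxel-wise
#' parameterization of the field); spatial gradients come from a separately
#' interpolated centered-difference field, which keeps the analytic
#' derivatives consistent with symmetric variations of the kinked linear
#' interpolant.
#'
#' @param b vector over the scan grid.
#' @param dims scan grid dimensions.
#' @export
bias_field_rep <- function(b, dims) {
  vrep <- spline_rep(array(b, dims), 1L, "reflect")
  d <- length(dims)
  g <- matrix(0, prod(dims), d)
  B <- array(as.numeric(b), dims)
  for (k in seq_len(d)) {
    gk <- (shift_axis(B, k, 1L) - shift_axis(B, k, -1L)) / 2
    # mirror symmetry: zero normal derivative at the edges (Neumann)
    idx <- rep(list(quote(expr = )), d)
    for (edge in c(1L, dims[k])) {
      idx_e <- idx; idx_e[[k]] <- edge
      gk <- do.call(`[<-`, c(list(gk), idx_e, list(0)))
    }
    g[, k] <- as.numeric(gk)
  }
  grep <- spline_rep(array(g, c(dims, d)), 1L, "reflect", channels = 1L)
  structure(list(value = vrep, grad = grep), class = "bias_field_rep")
}

# All per-scan template-space fields needed by every update: warp coordinates
# through phi then xi, sampled intensities and log-fields with pulled-back
# gradients, combined-model weights w_n and residual factors a_n.
unified_scan_fields <- function(scan, q, b_srep, shot, space, X,
                                f_srep, need_bias_grad = TRUE) {
  d <- length(space$dims)
  Xi <- rigid_map(q, scan$M, space$M_mu)
  C <- affine_points(Xi, shot$fwd$phi)
  ev <- spline_eval(f_srep, C, gradient = TRUE)
  evb <- spline_eval(b_srep$value, C)
  # pull back gradients through D(xi o phi) = Dxi Dphi
  A <- Xi[1:d, 1:d, drop = FALSE]
  gf <- ev$grad %*% A
  gb <- if (need_bias_grad) {
    matrix(spline_eval(b_srep$grad, C)$values, nrow(C), d) %*% A
  } else NULL
  J <- shot$fwd$J
  pull <- function(gr) {
    out <- matrix(0, nrow(X), d)
    for (j in seq_len(d)) {
      for (k in seq_len(d)) out[, j] <- out[, j] + J[, k, j] * gr[, k]
    }
    out
  }
  detphi <- abs(attr(Xi, "detJ")) * shot$fwd$detJ
  list(Xi = Xi, coords = C, fp = ev$values, bp = evb$values,
       grad_fp = pull(gf), grad_bp = if (need_bias_grad) pull(gb) else NULL,
       grad_fp_xi = gf, grad_bp_xi = gb,
       mask = ev$mask & evb$mask, detphi = detphi)
}

#' Template update of the combined model
#'
#' mu = sum_n w_n e^{-b'_n} f'_n / sum_n w_n with
#' w_n = lam_n |D phi_n| e^{2 b'_n} inside the common field of view.
#'
#' @param fields list of per-scan field lists (internal layout).
#' @param lams noise precisions.
#' @return list(mu, mask, w = per-scan weight vectors).
#' @export
combined_template <- function(fields, lams) {
  num <- 0; den <- 0
  ws <- vector("list", length(fields))
  for (n in seq_along(fields)) {
    fl <- fields[[n]]
    w <- lams[n] * fl$detphi * exp(2 * fl$bp)
    w[!fl$mask] <- 0
    ws[[n]] <- w
    num <- num + w * exp(-fl$bp) * fl$fp
    den <- den + w
  }
  mask <- den > 0
  list(mu = ifelse(mask, num / pmax(den, .Machine$double.xmin), NA_real_),
       mask = mask, w = ws)
}

#' Registration gradients of the combined model
#'
#' The group-blended gradient field driving both the rigid and the
#' diffeomorphic updates:
#' g = [sum w e^{-b'} (grad f' + f' grad b')] / sum w
#'     - 2 mu [sum w grad b'] / sum w.
#' With all fields zero it reduces to the Jacobian-weighted blend of
#' pulled-back image gradients.
#'
#' @param fields per-scan field lists.
#' @param tpl output of [combined_template()].
#' @return M x d gradient field.
#' @export
combined_gradients <- function(fields, tpl) {
  d <- ncol(fields[[1]]$grad_fp)
  num <- 0; den <- 0; sgb <- 0
  for (n in seq_along(fields)) {
    fl <- fields[[n]]
    w <- tpl$w[[n]]
    emb <- exp(-fl$bp)
    num <- num + w * emb * (fl$grad_fp + fl$fp * fl$grad_bp)
    sgb <- sgb + w * fl$grad_bp
    den <- den + w
  }
  den <- pmax(den, .Machine$double.xmin)
  mu0 <- ifelse(tpl$mask, tpl$mu, 0)
  g <- num / den - 2 * mu0 * sgb / den
  g[!tpl$mask, ] <- 0
  g
}

# Exact frozen-template data gradient for one scan:
# g_n = e^{-b'} grad f' - mu grad b' (reduces to the pulled-back image
# gradient when the log-field is zero).  The group-blended field of
# combined_gradients() coincides with it at the fixed point but is not a
# descent direction for the per-scan safeguarded objective.
per_scan_gradient <- function(fl, tpl) {
  mu0 <- ifelse(tpl$mask, tpl$mu, 0)
  exp(-fl$bp) * fl$grad_fp - mu0 * fl$grad_bp
}

residual_factor <- function(fl, w, mu, mask) {
  a <- w * (exp(-fl$bp) * fl$fp - ifelse(mask, mu, 0))
  a[!mask | !fl$mask] <- 0
  a
}

scan_data_term <- function(fl, lam, mu, mask, fixed_mask = NULL) {
  m <- if (is.null(fixed_mask)) fl$mask & mask else fixed_mask
  mu0 <- ifelse(is.na(mu), 0, mu)
  0.5 * lam * sum((fl$detphi * (fl$fp - mu0 * exp(fl$bp))^2)[m])
}

#' Combined objective of the unified model
#'
#' Data term plus half the velocity and bias penalty quadratic forms, summed
#' over scans.
#'
#' @param fields per-scan field lists.
#' @param tpl template list.
#' @param lams precisions.
#' @param vs velocities; `syms` their operator symbols.
#' @param biases log-fields on the scan grids; `bias_regs` their regularizers;
#'   `scan_dims` their grid dimensions.
#' @return list(total, data, vel_penalty, bias_penalty).
#' @export
combined_objective <- function(fields, tpl, lams, vs, syms, biases,
                               bias_regs, scan_dims) {
  dat <- 0; vp <- 0; bp <- 0
  for (n in seq_along(fields)) {
    dat <- dat + scan_data_term(fields[[n]], lams[n], tpl$mu, tpl$mask)
    vp <- vp + 0.5 * sum(vs[[n]] * apply_LdagL(vs[[n]], syms[[n]]))
    bp <- bp + bias_penalty(biases[[n]], bias_regs[[n]], scan_dims[[n]])
  }
  list(total = dat + vp + bp, data = dat, vel_penalty = vp,
       bias_penalty = bp)
}

#' Bias derivatives pushed forward to a scan grid
#'
#' The data-term derivatives are computed in template space and pushed
#' through the inverse deformation:
#' grad(y) = -|D phi^-1(y)| (a_n mu)(phi^-1(y)) + L_b^t L_b b_n,
#' hess(y) = |D phi^-1(y)| (w_n mu^2)(phi^-1(y)).
#'
#' @param an,wn residual factor and weight fields on the template grid.
#' @param mu template intensities.
#' @param shot geodesic-shooting result for the scan (with inverse).
#' @param Xi voxel-to-voxel affine of the scan.
#' @param space template space.
#' @param scan_dims scan grid dimensions.
#' @param b current log-field (vector on scan grid).
#' @param reg_b a [bias_reg()].
#' @return list(grad, hess_diag) on the scan grid.
#' @export
push_bias_derivatives <- function(an, wn, mu, shot, Xi, space, scan_dims,
                                  b, reg_b) {
  d <- length(space$dims)
  mu0 <- ifelse(is.na(mu), 0, mu)
  Y <- grid_coords(scan_dims)
  Z <- affine_points(solve(Xi), Y)        # scan voxel -> template voxel
  # inverse deformation and its determinant sampled at Z
  psi_disp <- shot$inv$phi - grid_coords(space$dims)
  ev_disp <- sample_field_wrap(psi_disp, space$dims, Z)
  inv_at <- Z + ev_disp
  det_at <- sample_field_wrap(matrix(shot$inv$detJ, ncol = 1),
                              space$dims, Z)[, 1]
  det_inv_xi <- abs(1 / attr(Xi, "detJ"))
  inside <- rep(TRUE, nrow(Y))
  for (k in seq_len(d)) {
    inside <- inside & Z[, k] >= 0 & Z[, k] <= space$dims[k] - 1
  }
  samp <- function(field) {
    S <- spline_rep(array(field, space$dims), 1L, "reflect")
    out <- spline_eval(S, inv_at)$values
    out[!inside] <- 0
    out
  }
  grad <- -det_inv_xi * det_at * samp(an * mu0) +
    apply_bias_op(b, reg_b, scan_dims)
  hess <- det_inv_xi * det_at * samp(wn * mu0^2)
  hess <- pmax(hess, 0)
  list(grad = grad, hess_diag = hess)
}

# ---- the full fit -----------------------------------------------------------

#' Fit the combined longitudinal model
#'
#' Group-wise rigid + inhomogeneity + diffeomorphic registration of N scans
#' of one subject to an evolving average template (interleaved Gauss-Newton
#' with zero-mean constraints), coarse-to-fine over a multi-resolution
#' pyramid.
#'
#' @param scans list of N >= 2 [scan_image()] (set `lam` per scan, or pass
#'   `lams`).
#' @param times acquisition times in years (`NULL`: pure group-wise mode;
#'   defaults to the scans' `t` fields when all are set).
#' @param config a [longit_config()].
#' @param lams optional noise precisions; `"auto"` estimates them from the
#'   scans' intensity histograms via the Rician mixture.
#' @param space optional [template_space()] (computed from headers otherwise).
#' @return object of class `longit_fit`.
#' @export
fit_longitudinal <- function(scans, times = NULL, config = longit_config(),
                             lams = NULL, space = NULL) {
  N <- length(scans)
  stopifnot(N >= 2L)
  d <- length(scans[[1]]$dims)
  if (is.null(lams)) {
    lams <- vapply(scans, `[[`, numeric(1), "lam")
  } else if (identical(lams, "auto")) {
    lams <- vapply(scans, function(s)
      1 / estimate_noise_variance(s$f)$variance, numeric(1))
  }
  if (is.null(times)) {
    tv <- vapply(scans, `[[`, numeric(1), "t")
    if (!anyNA(tv)) times <- tv
  }
  timing <- timing_weights(times, n = N)
  if (is.null(space)) space <- compute_template_space(scans)
  levels <- config$levels
  # coarse-to-fine by smoothing the scans on their native grids: all stages
  # share one template grid and one operator metric, so parameters carry
  # over between stages unchanged
  rigids <- rep(list(numeric(if (d == 2L) 3L else 6L)), N)
  biases <- lapply(scans, function(s) numeric(prod(s$dims)))
  vs <- rep(list(matrix(0, prod(space$dims), d)), N)
  trace <- list()
  res <- NULL
  for (l in levels:1) {
    sl <- lapply(scans, function(s)
      scan_image(smooth_level(s$f, l), s$M, s$lam, s$t))
    res <- fit_longitudinal_level(sl, space, rigids, biases, vs, lams,
                                  timing, config)
    rigids <- res$rigids
    biases <- res$biases
    vs <- res$velocities
    trace[[length(trace) + 1L]] <- res$objective
  }
  structure(list(
    rigids = rigids, biases = biases, velocities = vs,
    template = res$template, space = space, lams = lams, timing = timing,
    objective = trace, config = config, constraints = res$constraints,
    deformations = res$shots, converged = res$converged, scans = scans),
    class = "longit_fit")
}

#' @export
print.longit_fit <- function(x, ...) {
  obj <- x$objective[[length(x$objective)]]
  cat("<longit_fit> ", length(x$scans), " scans | template ",
      paste(x$space$dims, collapse = " x "),
      " | final objective ", format(obj[length(obj)], digits = 8), "\n",
      sep = "")
  cat("  max |sum q|: ", format(x$constraints$sum_q, digits = 3),
      " | mean momentum rel norm: ",
      format(x$constraints$mean_momentum_rel, digits = 3), "\n", sep = "")
  invisible(x)
}

fit_longitudinal_level <- function(scans, space, rigids, biases, vs, lams,
                                   timing, config) {
  N <- length(scans)
  d <- length(space$dims)
  M <- prod(space$dims)
  X <- grid_coords(space$dims)
  vox_mu <- voxel_sizes(space$M_mu)
  syms <- vector("list", N); Ks <- vector("list", N)
  for (n in seq_len(N)) {
    r <- vel_reg(config$vel_omega[1], config$vel_omega[2],
                 config$vel_omega[3], omega0 = config$vel_abs,
                 vox = vox_mu, scale = timing$scale[n])
    syms[[n]] <- vel_operator_symbol(r, space$dims)
    Ks[[n]] <- make_greens(syms[[n]])
    attr(syms[[n]], "reg") <- r
  }
  bias_regs <- lapply(scans, function(s)
    bias_reg(config$bias_omega0, vox = voxel_sizes(s$M)))
  scan_dims <- lapply(scans, `[[`, "dims")
  f_sreps <- lapply(scans, function(s) spline_rep(s$f, 3L, "reflect"))
  shots <- vector("list", N)
  fields <- vector("list", N)
  b_sreps <- lapply(seq_len(N), function(n)
    bias_field_rep(biases[[n]], scan_dims[[n]]))
  reshoot <- function(n, v) {
    geodesic_shoot_full(v, attr(syms[[n]], "reg"), space$dims,
                        steps = timing$steps[n], sym = syms[[n]],
                        K = Ks[[n]])
  }
  refresh <- function(n) {
    fields[[n]] <<- unified_scan_fields(scans[[n]], rigids[[n]],
                                        b_sreps[[n]], shots[[n]], space, X,
                                        f_sreps[[n]])
  }
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  rhos <- rep(0, N)
  deltas <- rep(list(matrix(0, M, d)), N)
  constraints <- list(sum_q = NA_real_, mean_momentum_rel = NA_real_)
  for (it in seq_len(config$max_iter + 1L)) {
    for (n in seq_len(N)) {
      sv <- shoot_with_rescue(vs[[n]], attr(syms[[n]], "reg"), space$dims,
                              steps = timing$steps[n], sym = syms[[n]],
                              K = Ks[[n]])
      vs[[n]] <- sv$v
      shots[[n]] <- sv$shot
      refresh(n)
    }
    tpl <- combined_template(fields, lams)
    g <- combined_gradients(fields, tpl)
    obj <- combined_objective(fields, tpl, lams, vs, syms, biases,
                              bias_regs, scan_dims)
    trace <- c(trace, obj$total)
    if (config$verbose) {
      message(sprintf(
        "level %dx%s iter %d: total %.8g (data %.4g, vel %.4g, bias %.4g)",
        space$dims[1], paste(space$dims[-1], collapse = "x"), it - 1L,
        obj$total, obj$data, obj$vel_penalty, obj$bias_penalty))
    }
    if (it > config$max_iter ||
        (is.finite(prev) && abs(prev - obj$total) <= config$tol * abs(prev))) {
      converged <- it <= config$max_iter
      break
    }
    prev <- obj$total
    # ---- rigid updates -----------------------------------------------------
    for (n in seq_len(N)) {
      fl <- fields[[n]]
      mu0 <- ifelse(tpl$mask, tpl$mu, 0)
      r <- fl$fp - mu0 * exp(fl$bp)
      m <- fl$mask & tpl$mask
      r[!m] <- 0
      wt <- lams[n] * fl$detphi
      g_rig <- fl$grad_fp_xi - mu0 * exp(fl$bp) * fl$grad_bp_xi
      der <- rigid_derivatives(scans[[n]], rigids[[n]], space, tpl$mu,
                               tpl$mask, srep = f_sreps[[n]],
                               g_override = g_rig, a_override = wt * r,
                               w_override = wt * m,
                               points = shots[[n]]$fwd$phi)
      nq <- length(rigids[[n]])
      H <- der$hess + diag(1e-8 * max(diag(der$hess), 1e-12), nq)
      delta <- solve(H, der$grad)
      f_old <- scan_data_term(fields[[n]], lams[n], tpl$mu, tpl$mask,
                              fixed_mask = m)
      step <- 1
      for (h in 0:config$max_halvings) {
        q_try <- rigids[[n]] - step * delta
        fl_try <- unified_scan_fields(scans[[n]], q_try, b_sreps[[n]],
                                      shots[[n]], space, X, f_sreps[[n]])
        if (scan_data_term(fl_try, lams[n], tpl$mu, tpl$mask,
                           fixed_mask = m) <= f_old) {
          rigids[[n]] <- q_try
          fields[[n]] <- fl_try
          break
        }
        step <- step / 2
      }
    }
    qbar <- Reduce(`+`, rigids) / N
    rigids <- lapply(rigids, function(q) q - qbar)
    for (n in seq_len(N)) refresh(n)
    tpl <- combined_template(fields, lams)
    # ---- bias updates (pushed to scan grids; not mean-corrected) ----------
    for (n in seq_len(N)) {
      w <- tpl$w[[n]]
      a <- residual_factor(fields[[n]], w, tpl$mu, tpl$mask)
      der <- push_bias_derivatives(a, w, tpl$mu, shots[[n]], fields[[n]]$Xi,
                                   space, scan_dims[[n]], biases[[n]],
                                   bias_regs[[n]])
      delta <- bias_gn_step(der$grad, der$hess_diag, bias_regs[[n]],
                            scan_dims[[n]])
      m0 <- fields[[n]]$mask & tpl$mask
      f_old <- scan_data_term(fields[[n]], lams[n], tpl$mu, tpl$mask,
                              fixed_mask = m0) +
        bias_penalty(biases[[n]], bias_regs[[n]], scan_dims[[n]])
      step <- 1
      for (h in 0:config$max_halvings) {
        b_try <- biases[[n]] + step * delta
        bs_try <- bias_field_rep(b_try, scan_dims[[n]])
        fl_try <- unified_scan_fields(scans[[n]], rigids[[n]], bs_try,
                                      shots[[n]], space, X, f_sreps[[n]])
        f_new <- scan_data_term(fl_try, lams[n], tpl$mu, tpl$mask,
                                fixed_mask = m0) +
          bias_penalty(b_try, bias_regs[[n]], scan_dims[[n]])
        if (f_new <= f_old) {
          biases[[n]] <- b_try
          b_sreps[[n]] <- bs_try
          fields[[n]] <- fl_try
          break
        }
        step <- step / 2
      }
    }
    if (config$bias_mean_correct) {
      # only meaningful when all scans share one grid
      if (length(unique(vapply(scan_dims, paste, "", collapse = "x"))) == 1L) {
        bbar <- Reduce(`+`, biases) / N
        biases <- lapply(biases, function(b) b - bbar)
        b_sreps <- lapply(seq_len(N), function(n)
          bias_field_rep(biases[[n]], scan_dims[[n]]))
        for (n in seq_len(N)) refresh(n)
      }
    }
    tpl <- combined_template(fields, lams)
    g <- combined_gradients(fields, tpl)
    # ---- velocity updates --------------------------------------------------
    for (n in seq_len(N)) {
      if (timing$pinned[n]) next
      fl <- fields[[n]]
      mu0 <- ifelse(tpl$mask, tpl$mu, 0)
      m <- fl$mask & tpl$mask
      g_pull <- fl$grad_fp - mu0 * exp(fl$bp) * fl$grad_bp
      ed <- exact_data_gradient(fl$fp, g_pull, fl$detphi,
                                mu0 * exp(fl$bp), m, lams[n], space$dims)
      w <- lams[n] * fl$detphi
      w[!m] <- 0
      der <- list(grad_field = ed$G + apply_LdagL(vs[[n]], syms[[n]]))
      gn <- ed$g_eff
      f_old <- scan_data_term(fields[[n]], lams[n], tpl$mu, tpl$mask,
                              fixed_mask = m) +
        0.5 * sum(vs[[n]] * apply_LdagL(vs[[n]], syms[[n]]))
      obj_of <- function(delta) {
        v_try <- vs[[n]] + delta
        ok <- tryCatch({
          shot_try <<- reshoot(n, v_try)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) return(Inf)
        fl_try <<- unified_scan_fields(scans[[n]], rigids[[n]],
                                       b_sreps[[n]], shot_try, space, X,
                                       f_sreps[[n]])
        scan_data_term(fl_try, lams[n], tpl$mu, tpl$mask, fixed_mask = m) +
          0.5 * sum(v_try * apply_LdagL(v_try, syms[[n]]))
      }
      shot_try <- NULL; fl_try <- NULL
      upd <- lm_velocity_update(der$grad_field, w, gn, syms[[n]],
                                rhos[n], obj_of, f_old, K = Ks[[n]])
      rhos[n] <- upd$rho
      deltas[[n]] <- if (upd$accepted) upd$delta else 0 * vs[[n]]
    }
    # Global safeguard around the whole velocity round including the
    # momentum mean-correction (see the diffeomorphic driver): all steps
    # are scaled together until the corrected group state does not increase
    # the combined objective.
    vmasks <- lapply(seq_len(N), function(n) fields[[n]]$mask & tpl$mask)
    tot_of <- function(vset) {
      s <- 0
      for (n in seq_len(N)) {
        sh <- tryCatch(reshoot(n, vset[[n]]), error = function(e) NULL)
        if (is.null(sh)) return(Inf)
        flx <- unified_scan_fields(scans[[n]], rigids[[n]], b_sreps[[n]],
                                   sh, space, X, f_sreps[[n]])
        s <- s + scan_data_term(flx, lams[n], tpl$mu, tpl$mask,
                                fixed_mask = vmasks[[n]]) +
          0.5 * sum(vset[[n]] * apply_LdagL(vset[[n]], syms[[n]]))
      }
      s
    }
    tot0 <- tot_of(vs)
    tfac <- 1
    for (h in 1:8) {
      vs_try <- lapply(seq_len(N), function(n) vs[[n]] + tfac * deltas[[n]])
      vs_try <- zero_mean_momentum(vs_try, syms, Ks)
      if (tot_of(vs_try) <= tot0) {
        vs <- vs_try
        break
      }
      tfac <- tfac / 2
    }
    # constraint audit
    um <- 0
    unorm <- 0
    for (n in seq_len(N)) {
      u <- apply_LdagL(vs[[n]], syms[[n]])
      um <- um + u / N
      unorm <- unorm + sqrt(sum(u * u)) / N
    }
    constraints$sum_q <- max(abs(Reduce(`+`, rigids)))
    constraints$mean_momentum_rel <-
      if (unorm > 0) sqrt(sum(um * um)) / unorm else 0
  }
  list(rigids = rigids, biases = biases, velocities = vs,
       template = list(mu = tpl$mu, mask = tpl$mask, g = g),
       objective = trace, constraints = constraints, converged = converged,
       shots = shots)
}

#' Rigid-only group alignment and averaging
#'
#' Group-wise rigid-body alignment with the non-linear and inhomogeneity
#' components disabled, returning the average-position template mean; used
#' for building per-time-point averages of repeated scans.
#'
#' @param scans list of [scan_image()].
#' @param ... passed to [groupwise_rigid()].
#' @return list(mu, mask, space, rigids).
#' @export
midpoint_average <- function(scans, ...) {
  fit <- groupwise_rigid(scans, ...)
  list(mu = fit$template$mu, mask = fit$template$mask, space = fit$space,
       rigids = fit$rigids)
}
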