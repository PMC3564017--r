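make_identity_setup <- function(dims, fs, lams, bs = NULL, vs = NULL,
                                reg = vel_reg(0.01, 0.01, 1)) {
  # all scans on the template grid with identity headers
  N <- length(fs)
  M <- prod(dims)
  space <- template_space(dims, diag(3))
  X <- grid_coords(dims)
  sym <- vel_operator_symbol(reg, dims)
  K <- make_greens(sym)
  if (is.null(bs)) bs <- rep(list(numeric(M)), N)
  if (is.null(vs)) vs <- rep(list(matrix(0, M, 2)), N)
  fields <- vector("list", N)
  shots <- vector("list", N)
  for (n in seq_len(N)) {
    shots[[n]] <- geodesic_shoot_full(vs[[n]], reg, dims, sym = sym, K = K)
    fields[[n]] <- longreg:::unified_scan_fields(
      scan_image(fs[[n]], diag(3), lams[n]), numeric(3),
      bias_field_rep(bs[[n]], dims), shots[[n]], space,
      X, spline_rep(array(fs[[n]], dims), 3L, "reflect"))
  }
  list(space = space, fields = fields, shots = shots, sym = sym, K = K,
       X = X, bs = bs, vs = vs)
}

test_that("the combined template and objective reduce to the components", {
  set.seed(91)
  dims <- c(16L, 14L)
  M <- prod(dims)
  fs <- list(texture_image(dims, seed = 91), texture_image(dims, seed = 92))
  lams <- c(2, 3)
  st <- make_identity_setup(dims, fs, lams)
  tpl <- combined_template(st$fields, lams)
  # with zero fields and identity warps: precision-weighted mean
  expect_equal(tpl$mu, (2 * as.numeric(fs[[1]]) + 3 * as.numeric(fs[[2]])) / 5,
               tolerance = 1e-9)
  reg_b <- bias_reg(10)
  obj <- combined_objective(st$fields, tpl, lams, st$vs,
                            rep(list(st$sym), 2), st$bs,
                            rep(list(reg_b), 2), rep(list(dims), 2))
  expect_equal(obj$vel_penalty, 0)
  expect_equal(obj$bias_penalty, 0)
  ref <- 0.5 * 2 * sum((as.numeric(fs[[1]]) - tpl$mu)^2) +
    0.5 * 3 * sum((as.numeric(fs[[2]]) - tpl$mu)^2)
  expect_equal(obj$data, ref, tolerance = 1e-9)
  # identical images: everything vanishes
  st0 <- make_identity_setup(dims, list(fs[[1]], fs[[1]]), c(1, 1))
  tpl0 <- combined_template(st0$fields, c(1, 1))
  obj0 <- combined_objective(st0$fields, tpl0, c(1, 1), st0$vs,
                             rep(list(st0$sym), 2), st0$bs,
                             rep(list(reg_b), 2), rep(list(dims), 2))
  expect_lt(obj0$total, 1e-16 * sum(fs[[1]]^2))
  # N = 1: mu = f' e^{-b'}
  b1 <- 0.1 * smooth_scalar(dims, seed = 93)
  st1 <- make_identity_setup(dims, fs[1], 2, bs = list(b1))
  tpl1 <- combined_template(st1$fields, 2)
  expect_equal(tpl1$mu, as.numeric(fs[[1]]) * exp(-b1), tolerance = 1e-9)
})

test_that("combined gradients reduce to the blend form and match a variational FD", {
  set.seed(94)
  dims <- c(16L, 16L)
  M <- prod(dims)
  fs <- list(texture_image(dims, seed = 94), texture_image(dims, seed = 95))
  lams <- c(2, 3)
  # with all log-fields zero the combined form reduces to the plain blend
  st <- make_identity_setup(dims, fs, lams)
  tpl <- combined_template(st$fields, lams)
  g0 <- combined_gradients(st$fields, tpl)
  gref <- template_gradients(lapply(st$fields, `[[`, "grad_fp"),
                             lapply(st$fields, function(f) f$detphi), lams)
  expect_equal(g0, gref, tolerance = 1e-10)
  # constant images: no gradient anywhere
  stc <- make_identity_setup(dims, list(array(1, dims), array(1, dims)),
                             lams)
  gc <- combined_gradients(stc$fields, combined_template(stc$fields, lams))
  expect_lt(max(abs(gc)), 1e-10)
  # with non-zero log-fields, check against the finite difference of the
  # data term through the template's dependence on shifted arguments
  bs <- list(0.2 * smooth_scalar(dims, seed = 96),
             -0.15 * smooth_scalar(dims, seed = 97))
  stb <- make_identity_setup(dims, fs, lams, bs = bs)
  tplb <- combined_template(stb$fields, lams)
  g <- combined_gradients(stb$fields, tplb)
  h <- smooth_velocity(dims, amplitude = 1, seed = 98)
  X <- grid_coords(dims)
  sreps_f <- lapply(fs, spline_rep, degree = 3L, boundary = "reflect")
  sreps_b <- lapply(bs, function(b) spline_rep(array(b, dims), 1L, "reflect"))
  mu_tau <- function(tau) {
    num <- 0; den <- 0
    for (l in 1:2) {
      fv <- spline_eval(sreps_f[[l]], X - tau * h)$values
      bv <- spline_eval(sreps_b[[l]], X - tau * h)$values
      w <- lams[l] * exp(2 * bv)
      num <- num + w * exp(-bv) * fv
      den <- den + w
    }
    num / den
  }
  # per scan (over the whole group the common shift largely cancels)
  data_tau_1 <- function(tau) {
    mu <- mu_tau(tau)
    0.5 * lams[1] * sum((as.numeric(fs[[1]]) - mu * exp(bs[[1]]))^2)
  }
  eps <- 1e-5
  fd <- (data_tau_1(eps) - data_tau_1(-eps)) / (2 * eps)
  a1 <- longreg:::residual_factor(stb$fields[[1]], tplb$w[[1]], tplb$mu,
                                  tplb$mask)
  pred <- sum(a1 * rowSums(g * h))
  expect_lt(abs(fd - pred) / abs(fd), 1e-3)
})

test_that("pushed bias derivatives reduce to the aligned forms and conserve mass", {
  set.seed(99)
  dims <- c(20L, 18L)
  M <- prod(dims)
  space <- template_space(dims, diag(3))
  f <- abs(texture_image(dims, seed = 99)) + 0.5
  b <- 0.1 * smooth_scalar(dims, seed = 100)
  mu <- abs(as.numeric(texture_image(dims, seed = 101))) + 0.5
  reg <- vel_reg(0.01, 0.01, 1)
  reg_b <- bias_reg(10)
  sym <- vel_operator_symbol(reg, dims); K <- make_greens(sym)
  X <- grid_coords(dims)
  scan <- scan_image(f, diag(3), 100)
  mk_fields <- function(shot) {
    longreg:::unified_scan_fields(scan, numeric(3),
                                  bias_field_rep(b, dims),
                                  shot, space, X,
                                  spline_rep(f, 3L, "reflect"))
  }
  # identity deformation: exact reduction to the aligned derivatives
  shot0 <- geodesic_shoot_full(matrix(0, M, 2), reg, dims, sym = sym, K = K)
  fl <- mk_fields(shot0)
  w <- 100 * fl$detphi * exp(2 * fl$bp)
  a <- w * (exp(-fl$bp) * fl$fp - mu)
  pd <- push_bias_derivatives(a, w, mu, shot0, fl$Xi, space, dims, b, reg_b)
  dd <- bias_derivatives(f, mu, b, 100, reg_b, dims)
  expect_equal(pd$grad, dd$grad, tolerance = 1e-10)
  expect_equal(pd$hess_diag, dd$hess_diag, tolerance = 1e-10)
  # a genuine deformation: pushing conserves the integral to ~1%
  v <- smooth_velocity(dims, amplitude = 1, seed = 102)
  shot <- geodesic_shoot_full(v, reg, dims, sym = sym, K = K)
  flv <- mk_fields(shot)
  wv <- 100 * flv$detphi * exp(2 * flv$bp)
  av <- wv * (exp(-flv$bp) * flv$fp - mu)
  # window the field away from the grid edge so no mass crosses the
  # boundary, where the wrap/reflect conventions meet
  X <- grid_coords(dims)
  wnd <- rep(1, M)
  for (k in 1:2) {
    dd <- pmin(X[, k], dims[k] - 1 - X[, k])
    wnd <- wnd * pmin(dd / 4, 1)
  }
  av <- av * wnd
  pdv <- push_bias_derivatives(av, wv, mu, shot, flv$Xi, space, dims, b,
                               reg_b)
  pushed <- -(pdv$grad - apply_bias_op(b, reg_b, dims))
  expect_lt(abs(sum(pushed) - sum(av * mu)) / abs(sum(av * mu)), 0.01)
  # zero residual: only the regularizer gradient
  pd0 <- push_bias_derivatives(numeric(M), wv, mu, shot, flv$Xi, space,
                               dims, b, reg_b)
  expect_equal(pd0$grad, apply_bias_op(b, reg_b, dims))
})

test_that("timing weights follow the median rule with clamping", {
  tw <- timing_weights(c(0, 1))
  expect_equal(tw$t, c(-0.5, 0.5))
  expect_equal(tw$scale, c(2, 2))
  tw5 <- timing_weights(c(0, 1, 2, 3, 4))
  expect_equal(tw5$reference, 2)
  expect_equal(tw5$scale[c(1, 2, 4, 5)], c(0.5, 1, 1, 0.5))
  expect_true(tw5$pinned[3])
  expect_lte(tw5$scale[3], 365)
  expect_warning(tw0 <- timing_weights(c(2, 2, 2)), "equal")
  expect_equal(tw0$scale, rep(1, 3))
  twn <- timing_weights(NULL, n = 4)
  expect_equal(twn$scale, rep(1, 4))
  expect_false(any(twn$pinned))
})

test_that("the combined fit leaves identical scans untouched and absorbs header shifts", {
  set.seed(103)
  dims <- c(24L, 24L)
  base <- texture_image(dims, seed = 103)
  s <- scan_image(base, diag(3), lam = 400)
  cfg <- longit_config(levels = 1L, max_iter = 3L, bias_omega0 = 1e3)
  fit0 <- suppressWarnings(fit_longitudinal(list(s, s), config = cfg))
  expect_equal(max(abs(unlist(fit0$rigids))), 0)
  expect_equal(max(abs(unlist(fit0$biases))), 0)
  expect_equal(max(abs(unlist(fit0$velocities))), 0)
  # a pure header translation is absorbed by the rigid component
  M1 <- diag(3); M1[1, 3] <- 1.2
  M2 <- diag(3); M2[1, 3] <- -1.2
  s1 <- scan_image(base, M1, lam = 400)
  s2 <- scan_image(base, M2, lam = 400)
  fit <- suppressWarnings(fit_longitudinal(
    list(s1, s2), config = longit_config(levels = 2L, max_iter = 8L,
                                         bias_omega0 = 1e3)))
  expect_lt(abs(fit$rigids[[1]][1] - 1.2), 0.1)
  expect_equal(Reduce(`+`, fit$rigids), numeric(3))
  expect_lt(fit$constraints$mean_momentum_rel, 1e-10)
})
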