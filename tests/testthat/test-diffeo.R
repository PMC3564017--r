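test_that("diffeomorphic template update has the stated closed forms", {
  n <- 40L
  # identity warps: precision-weighted mean
  tpl <- update_template_diffeo(list(rep(1, n), rep(3, n)),
                                list(rep(1, n), rep(1, n)), c(1, 3))
  expect_equal(unique(tpl$mu), 2.5)
  # single image through its warp
  w <- runif(n)
  tpl1 <- update_template_diffeo(list(w), list(runif(n, 0.5, 2)), 5)
  expect_equal(tpl1$mu, w)
  # constant images: weighted constant independent of the deformations
  tplc <- update_template_diffeo(list(rep(2, n), rep(2, n)),
                                 list(runif(n, 0.5, 2), runif(n, 0.5, 2)),
                                 c(1, 2))
  expect_equal(unique(round(tplc$mu, 12)), 2)
})

test_that("registration gradients are not the spatial gradient of the template", {
  set.seed(81)
  dims <- c(24L, 20L)
  M <- prod(dims)
  reg <- vel_reg(0.01, 0.01, 1)
  sym <- vel_operator_symbol(reg, dims)
  K <- make_greens(sym)
  f1 <- texture_image(dims, seed = 81)
  f2 <- texture_image(dims, seed = 82)
  v <- smooth_velocity(dims, amplitude = 1, seed = 83)
  sh1 <- geodesic_shoot_full(v, reg, dims, sym = sym, K = K)
  sh2 <- geodesic_shoot_full(-v, reg, dims, sym = sym, K = K)
  p1 <- longreg:::pull_through(spline_rep(f1, 3L, "reflect"), sh1$fwd)
  p2 <- longreg:::pull_through(spline_rep(f2, 3L, "reflect"), sh2$fwd)
  detJs <- list(sh1$fwd$detJ, sh2$fwd$detJ)
  g <- template_gradients(list(p1$grad_pulled, p2$grad_pulled), detJs,
                          c(1, 1))
  tpl <- update_template_diffeo(list(p1$values, p2$values), detJs, c(1, 1))
  gmu <- central_gradient(tpl$mu, dims)
  # with unequal detJ the blend differs measurably from grad(mu), which
  # carries extra Jacobian-gradient terms
  rel <- sqrt(sum((g - gmu)^2) / sum(g^2))
  expect_gt(rel, 0.01)
  # but they stay strongly aligned (same field up to the extra terms)
  expect_gt(cor(as.numeric(g), as.numeric(gmu)), 0.9)
})

test_that("velocity gradient matches the variational finite difference", {
  # at identity warps the blended-gradient form is the exact derivative of
  # the data term under a common shift of the template-blend arguments
  set.seed(84)
  dims <- c(16L, 16L)
  M <- prod(dims)
  lams <- c(2, 3)
  fs <- list(texture_image(dims, seed = 84), texture_image(dims, seed = 85))
  sreps <- lapply(fs, spline_rep, degree = 3L, boundary = "reflect")
  detJs <- list(rep(1, M), rep(1, M))
  pulls <- lapply(sreps, function(s) spline_eval(s, grid_coords(dims),
                                                 gradient = TRUE))
  g <- template_gradients(lapply(pulls, `[[`, "grad"), detJs, lams)
  mu <- update_template_diffeo(lapply(pulls, `[[`, "values"), detJs, lams)$mu
  X <- grid_coords(dims)
  h <- smooth_velocity(dims, amplitude = 1, seed = 86)
  # per scan: over the whole group the common template shift cancels exactly
  data_term_1 <- function(tau) {
    shifted <- lapply(sreps, function(s) spline_eval(s, X - tau * h)$values)
    mu_t <- (lams[1] * shifted[[1]] + lams[2] * shifted[[2]]) / sum(lams)
    0.5 * lams[1] * sum((pulls[[1]]$values - mu_t)^2)
  }
  eps <- 1e-5
  fd <- (data_term_1(eps) - data_term_1(-eps)) / (2 * eps)
  a1 <- lams[1] * (pulls[[1]]$values - mu)
  pred <- sum(a1 * rowSums(g * h))
  expect_lt(abs(fd - pred) / abs(fd), 1e-3)
})

test_that("identical images stay at zero velocity and order swap is exact", {
  set.seed(87)
  dims <- c(24L, 24L)
  f <- texture_image(dims, seed = 87)
  reg <- vel_reg(0.01, 0.01, 1)
  fit0 <- suppressWarnings(groupwise_diffeo(list(f, f), c(100, 100), reg,
                                            dims, max_iter = 3L))
  expect_equal(max(abs(unlist(fit0$velocities))), 0)
  wp <- make_warped_pair(texture_image(dims, seed = 88), amplitude = 1,
                         reg = reg, scale = 6, seed = 88)
  fit <- suppressWarnings(groupwise_diffeo(list(wp$f1, wp$f2), c(1e4, 1e4),
                                           reg, dims, max_iter = 6L))
  fit_sw <- suppressWarnings(groupwise_diffeo(list(wp$f2, wp$f1),
                                              c(1e4, 1e4), reg, dims,
                                              max_iter = 6L))
  expect_equal(fit_sw$velocities[[1]], fit$velocities[[2]])
  expect_equal(fit_sw$velocities[[2]], fit$velocities[[1]])
  # pairwise antisymmetry from the momentum mean-correction
  expect_lt(max(abs(fit$velocities[[1]] + fit$velocities[[2]])),
            1e-10 * max(abs(fit$velocities[[1]])))
  # all Jacobians positive
  for (s in fit$deformations) expect_true(all(s$fwd$detJ > 0))
})
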