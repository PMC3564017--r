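test_that("bias template update has the stated closed forms", {
  n <- 50L
  # all fields zero: precision-weighted mean
  mu <- update_template_bias(list(rep(1, n), rep(3, n)),
                             list(numeric(n), numeric(n)), c(1, 3))
  expect_equal(unique(mu), (1 + 9) / 4)
  # single image: mu = f e^{-b}
  b <- seq(-0.2, 0.2, length.out = n)
  f <- runif(n, 0.5, 1.5)
  expect_equal(update_template_bias(list(f), list(b), 2), f * exp(-b),
               tolerance = 1e-12)
  # constant pair (c, c e^{2 beta}) with opposite fields b1 = -beta,
  # b2 = +beta (the generative assignment: f_n = mu e^{b_n}): mu = c e^{beta}
  beta <- 0.4
  mu2 <- update_template_bias(list(rep(2, n), rep(2 * exp(2 * beta), n)),
                              list(rep(-beta, n), rep(beta, n)), c(3, 3))
  expect_equal(unique(round(mu2, 12)), round(2 * exp(beta), 12))
})

test_that("bias derivatives are the exact voxel-wise gradient", {
  set.seed(71)
  dims <- c(16L, 14L)
  n <- prod(dims)
  reg <- bias_reg(omega0 = 10)
  f <- abs(texture_image(dims, seed = 71)) + 0.5
  mu <- abs(as.numeric(texture_image(dims, seed = 72))) + 0.5
  b <- 0.1 * smooth_scalar(dims, seed = 73)
  der <- bias_derivatives(f, mu, b, 2.5, reg, dims)
  idx <- sample(n, 8)
  fd <- sapply(idx, function(j) {
    e <- numeric(n); e[j] <- 1e-6
    (longreg:::bias_objective_scan(f, mu, b + e, 2.5, reg, dims) -
       longreg:::bias_objective_scan(f, mu, b - e, 2.5, reg, dims)) / 2e-6
  })
  expect_lt(max(abs(fd - der$grad[idx]) / pmax(abs(fd), 1e-10)), 1e-4)
  # zero residual: only the regularizer gradient remains
  der0 <- bias_derivatives(mu * exp(b), mu, b, 2.5, reg, dims)
  expect_equal(der0$grad, apply_bias_op(b, reg, dims), tolerance = 1e-10)
  # data Hessian strictly positive wherever mu is
  expect_true(all(der$hess_diag > 0))
})

test_that("group-wise bias estimation recovers a smooth relative field", {
  set.seed(74)
  dims <- c(32L, 32L)
  base <- abs(texture_image(dims, scale = 5, seed = 74)) + 0.5
  s <- 0.15 * smooth_scalar(dims, scale = 8, seed = 75)
  f1 <- as.numeric(base) * exp(-s)
  f2 <- as.numeric(base) * exp(+s)
  reg <- bias_reg(omega0 = 100)
  fit <- groupwise_bias(list(f1, f2), c(400, 400), reg, dims, max_iter = 60L)
  expect_gt(cor(fit$biases[[2]], s), 0.95)
  # geometric-mean-one constraint: fields sum to zero voxel-wise
  expect_lt(max(abs(fit$biases[[1]] + fit$biases[[2]])), 1e-12)
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
  # identical inputs give vanishing fields
  fit0 <- groupwise_bias(list(f1, f1), c(400, 400), reg, dims, max_iter = 20L)
  expect_lt(max(abs(fit0$biases[[1]])), 1e-6)
  # permutation invariance
  fit_sw <- groupwise_bias(list(f2, f1), c(400, 400), reg, dims,
                           max_iter = 60L)
  expect_equal(fit_sw$biases[[1]], fit$biases[[2]], tolerance = 1e-10)
})

test_that("the pairwise ratio-field solution equals the two-image group fit", {
  set.seed(76)
  dims <- c(24L, 24L)
  base <- abs(texture_image(dims, scale = 5, seed = 76)) + 0.5
  s <- 0.12 * smooth_scalar(dims, scale = 7, seed = 77)
  f1 <- as.numeric(base) * exp(-s)
  f2 <- as.numeric(base) * exp(+s)
  reg <- bias_reg(omega0 = 50)
  gb <- groupwise_bias(list(f1, f2), c(300, 300), reg, dims,
                       max_iter = 80L, tol = 1e-12)
  pw <- pairwise_ratio_field(f1, f2, 300, 300, reg, dims, max_iter = 80L)
  expect_lt(max(abs(pw$b1 - gb$biases[[1]])), 1e-6)
  # swapping the images flips the sign exactly
  pw_sw <- pairwise_ratio_field(f2, f1, 300, 300, reg, dims, max_iter = 80L)
  expect_equal(pw_sw$b1, -pw$b1)
  expect_equal(pairwise_ratio_field(f1, f1, 300, 300, reg, dims)$b1,
               numeric(prod(dims)))
})
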