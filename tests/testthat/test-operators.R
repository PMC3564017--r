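test_that("the operator symbol matches real-space finite-difference energy", {
  set.seed(41)
  dims <- c(16L, 12L)
  M <- prod(dims)
  reg <- vel_reg(0.7, 0.4, 1.3, omega0 = 0.05, scale = 1.7)
  sym <- vel_operator_symbol(reg, dims)
  v <- matrix(rnorm(M * 2), M, 2)
  u <- apply_LdagL(v, sym)
  fd <- function(A, k) longreg:::shift_axis_wrap(A, k, 1L) - A
  Dv <- array(0, c(dims, 2, 2))
  for (j in 1:2) for (l in 1:2) Dv[, , j, l] <- fd(array(v[, j], dims), l)
  lap <- function(A) {
    o <- array(0, dim(A))
    for (k in 1:2) {
      o <- o + longreg:::shift_axis_wrap(A, k, 1L) +
        longreg:::shift_axis_wrap(A, k, -1L) - 2 * A
    }
    o
  }
  E <- 0
  for (j in 1:2) for (l in 1:2) E <- E + sum((Dv[, , j, l] + Dv[, , l, j])^2)
  E <- reg$omega[1] / 4 * E +
    reg$omega[2] * sum((Dv[, , 1, 1] + Dv[, , 2, 2])^2) +
    reg$omega[3] * (sum(lap(array(v[, 1], dims))^2) +
                      sum(lap(array(v[, 2], dims))^2)) +
    reg$omega0 * sum(v^2)
  E <- E * reg$scale
  expect_equal(sum(v * u), E, tolerance = 1e-10)
  expect_gte(sum(v * u), 0)
})

test_that("the Green's function inverts the operator off its null space", {
  set.seed(42)
  # a 2D size with as many voxels as a 64^3 volume
  dims <- c(512L, 512L)
  M <- prod(dims)
  reg <- vel_reg(0.01, 0.01, 1)
  sym <- vel_operator_symbol(reg, dims)
  K <- make_greens(sym)
  v <- matrix(rnorm(M * 2), M, 2)
  v <- v - matrix(colMeans(v), M, 2, byrow = TRUE)
  rt <- apply_greens(apply_LdagL(v, sym), K)
  expect_lt(sqrt(sum((rt - v)^2) / sum(v^2)), 1e-6)
  # constant fields are projected out (zero DC)
  cst <- matrix(5, M, 2)
  expect_lt(max(abs(apply_greens(apply_LdagL(cst, sym), K))), 1e-8)
  # real, even kernel: symbol symmetric under frequency negation
  k11 <- array(K[[1]][[1]], dims)
  neg <- k11[c(1, dims[1]:2), c(1, dims[2]:2)]
  expect_lt(max(Mod(k11 - Conj(neg))) / max(Mod(k11)), 1e-10)
})

test_that("invalid regularization without bending or displacement penalty errors", {
  expect_error(vel_reg(0.05, 0, 0), "bending")
})

test_that("bias operator matches an explicit dense Neumann stencil", {
  dims <- c(7L, 6L)
  n <- prod(dims)
  reg <- bias_reg(omega0 = 3.5)
  Dense <- dense_operator(function(x) apply_bias_op(x, reg, dims), n)
  expect_lt(max(abs(Dense - t(Dense))), 1e-12)
  # independently built Neumann Laplacian, squared
  L <- matrix(0, n, n)
  idx <- function(i, j) i + (j - 1L) * dims[1]
  for (j in 1:dims[2]) for (i in 1:dims[1]) {
    r <- idx(i, j)
    nb <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    for (p in nb) {
      pi <- min(max(p[1], 1L), dims[1])
      pj <- min(max(p[2], 1L), dims[2])
      L[r, idx(pi, pj)] <- L[r, idx(pi, pj)] + 1
      L[r, r] <- L[r, r] - 1
    }
  }
  expect_lt(max(abs(Dense - reg$omega0 * (L %*% L))), 1e-10)
  set.seed(43)
  b <- rnorm(n)
  expect_equal(bias_penalty(b, reg, dims),
               0.5 * sum(b * (Dense %*% b)), tolerance = 1e-12)
  expect_equal(bias_penalty(numeric(n), reg, dims), 0)
  expect_equal(bias_penalty(rep(3, n), reg, dims), 0)
})

test_that("PCG with the circulant preconditioner matches dense solves", {
  set.seed(44)
  dims <- c(8L, 7L)
  n <- prod(dims)
  reg <- bias_reg(omega0 = 2)
  c0 <- runif(n, 0.5, 2)
  Dense <- dense_operator(function(x) c0 * x + apply_bias_op(x, reg, dims), n)
  rhs <- rnorm(n)
  sol <- bias_gn_step(-rhs, c0, reg, dims, tol = 1e-12)
  expect_lt(max(abs(sol - solve(Dense, rhs))), 1e-8)
  expect_equal(bias_gn_step(numeric(n), c0, reg, dims), numeric(n))
})

test_that("velocity Gauss-Newton solves match dense solves on small grids", {
  set.seed(45)
  dims <- c(8L, 8L)
  M <- prod(dims)
  reg <- vel_reg(0.1, 0.1, 0.5)
  sym <- vel_operator_symbol(reg, dims)
  g <- matrix(rnorm(M * 2), M, 2)
  w <- runif(M, 0.5, 2)
  applyA <- function(x) {
    xm <- matrix(x, M, 2)
    as.numeric(w * rowSums(g * xm) * g + apply_LdagL(xm, sym))
  }
  Dense <- dense_operator(applyA, 2L * M)
  grad <- matrix(rnorm(M * 2), M, 2)
  delta <- velocity_gn_step(grad, w, g, sym, tol = 1e-12)
  ref <- solve(Dense, -as.numeric(grad))
  expect_lt(max(abs(as.numeric(delta) - ref)), 1e-6)
  expect_equal(velocity_gn_step(matrix(0, M, 2), w, g, sym),
               matrix(0, M, 2))
})

test_that("momentum mean-correction zeroes the group mean momentum", {
  set.seed(46)
  dims <- c(12L, 10L)
  M <- prod(dims)
  reg <- vel_reg(0.01, 0.01, 1)
  sym <- vel_operator_symbol(reg, dims)
  K <- make_greens(sym)
  vs <- lapply(1:3, function(i) matrix(rnorm(M * 2), M, 2))
  out <- zero_mean_momentum(vs, rep(list(sym), 3), rep(list(K), 3))
  um <- Reduce(`+`, lapply(out, apply_LdagL, sym = sym)) / 3
  scale <- mean(sapply(out, function(v) sqrt(sum(apply_LdagL(v, sym)^2))))
  expect_lt(sqrt(sum(um^2)), 1e-10 * scale)
  # antisymmetric pair is unchanged
  v <- vs[[1]] - matrix(colMeans(vs[[1]]), M, 2, byrow = TRUE)
  pair <- zero_mean_momentum(list(v, -v), rep(list(sym), 2), rep(list(K), 2))
  expect_equal(pair[[1]], v, tolerance = 1e-10)
  # identical velocities lose everything but (at most) their mean
  same <- zero_mean_momentum(list(vs[[2]], vs[[2]]),
                             rep(list(sym), 2), rep(list(K), 2))
  expect_lt(max(abs(same[[1]])), 1e-8)
})
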