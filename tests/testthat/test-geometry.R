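test_that("se_exp reproduces the truncated power series and group structure", {
  expect_equal(se_exp(rep(0, 6)), diag(4))
  # pure translation: nilpotent generator, series terminates at first order
  Tr <- se_exp(c(1.7, 0, 0, 0, 0, 0))
  expect_equal(Tr, diag(4) + 1.7 * se_generators(6L)[[1]])
  # pure rotation vs 30-term series
  q <- c(0, 0, 0, 0.4, 0, 0)
  Q <- longreg:::se_generator_sum(q)
  S <- diag(4); P <- diag(4)
  for (k in 1:30) {
    P <- P %*% Q / k
    S <- S + P
  }
  expect_lt(max(abs(se_exp(q) - S)), 1e-12)
  # rigid-body structure and inverses, both dimensionalities
  for (qq in list(c(0.3, -0.2, 0.1, 0.2, -0.15, 0.35), c(0.5, -0.3, 0.4))) {
    R <- se_exp(qq)
    d <- nrow(R) - 1L
    expect_lt(max(abs(t(R[1:d, 1:d]) %*% R[1:d, 1:d] - diag(d))), 1e-12)
    expect_equal(det(R[1:d, 1:d]), 1, tolerance = 1e-12)
    expect_lt(max(abs(R %*% se_exp(-qq) - diag(d + 1))), 1e-12)
  }
  expect_error(se_exp(c(1, 2)), "length")
})

test_that("se_exp derivatives match finite differences and generators", {
  at0 <- se_exp_derivatives(rep(0, 6))
  G <- se_generators(6L)
  for (i in 1:6) expect_equal(at0[[i]], G[[i]], tolerance = 1e-12)
  set.seed(21)
  q <- rnorm(6, 0, 0.3)
  D <- se_exp_derivatives(q)
  for (i in 1:6) {
    e <- numeric(6); e[i] <- 1e-5
    fd <- (se_exp(q + e) - se_exp(q - e)) / 2e-5
    expect_lt(max(abs(fd - D[[i]])) / max(abs(D[[i]])), 1e-6)
  }
  # translation derivatives at a pure rotation are constant in translations
  qr <- c(0, 0, 0, 0.3, -0.2, 0.1)
  Dr <- se_exp_derivatives(qr)
  for (i in 1:3) {
    e <- numeric(6); e[i] <- 1e-5
    fd <- (se_exp(qr + e) - se_exp(qr - e)) / 2e-5
    expect_lt(max(abs(fd - Dr[[i]])), 1e-7)
  }
})

test_that("exponential barycenter solves the log-sum condition", {
  mk <- function(q) se_exp(q)
  M <- mk(c(1, -2, 0.5, 0.1, 0.2, -0.1))
  expect_equal(exponential_barycenter(list(M, M, M)), M, tolerance = 1e-12)
  # two opposite translations / rotations -> identity
  B <- exponential_barycenter(list(mk(c(2, 0, 0, 0, 0, 0)),
                                   mk(c(-2, 0, 0, 0, 0, 0))))
  expect_lt(max(abs(B - diag(4))), 1e-10)
  B2 <- exponential_barycenter(list(mk(c(0, 0, 0, 0.4, 0, 0)),
                                    mk(c(0, 0, 0, -0.4, 0, 0))))
  # verified through the log-sum condition
  S <- mat_log(solve(B2) %*% mk(c(0, 0, 0, 0.4, 0, 0))) +
    mat_log(solve(B2) %*% mk(c(0, 0, 0, -0.4, 0, 0)))
  expect_lt(norm(S, "F"), 1e-10)
  # left-equivariance under a fixed transform
  set.seed(22)
  Ms <- lapply(1:3, function(i) mk(rnorm(6, 0, 0.2)))
  G <- mk(c(1, 2, -1, 0.3, 0.1, -0.2))
  expect_lt(max(abs(exponential_barycenter(lapply(Ms, function(M) G %*% M)) -
                      G %*% exponential_barycenter(Ms))), 1e-9)
})

test_that("closest nine-parameter projection matches a generic optimizer", {
  tr <- c(1, -2, 3); rot <- c(0.2, -0.1, 0.3); ls <- log(c(1.1, 0.9, 1.3))
  Tgt <- longreg:::trs_matrix(tr, rot, ls)
  expect_lt(max(abs(closest_nine_param(Tgt) - Tgt)), 1e-10)
  Sh <- Tgt
  Sh[1, 2] <- Sh[1, 2] + 0.03   # small shear
  C9 <- closest_nine_param(Sh)
  obj <- function(p) sum((longreg:::trs_matrix(p[1:3], p[4:6], p[7:9]) - Sh)^2)
  o <- optim(c(tr, rot, ls), obj, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 5000))
  ref <- longreg:::trs_matrix(o$par[1:3], o$par[4:6], o$par[7:9])
  expect_lt(max(abs(C9 - ref)), 1e-6)
  neg <- -diag(4); neg[4, 4] <- 1
  expect_error(closest_nine_param(neg), "determinant")
})

test_that("template space covers all corners and is permutation invariant", {
  set.seed(23)
  mk_scan <- function(seed) {
    set.seed(seed)
    f <- array(runif(16 * 14 * 12), c(16L, 14L, 12L))
    M <- se_exp(rnorm(6, 0, 0.05)) %*% diag(c(1, 1.2, 0.9, 1))
    scan_image(f, M)
  }
  scans <- lapply(24:26, mk_scan)
  sp <- compute_template_space(scans)
  Minv <- solve(sp$M_mu)
  for (s in scans) {
    pv <- longreg:::affine_points(
      Minv, longreg:::affine_points(s$M, longreg:::corner_coords(s$dims)))
    expect_true(all(pv >= 0 - 1e-9))
    expect_true(all(sweep(pv, 2, sp$dims - 1) <= 1e-9))
  }
  sp2 <- compute_template_space(rev(scans))
  expect_equal(sp2$dims, sp$dims)
  expect_equal(sp2$M_mu, sp$M_mu, tolerance = 1e-9)
  # single image: the nine-parameter projection of its own header
  sp1 <- compute_template_space(scans[1])
  expect_true(all(sp1$dims >= scans[[1]]$dims))
})
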