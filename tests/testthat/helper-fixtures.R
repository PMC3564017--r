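# Shared fixture builders.  Everything is generated in code under fixed
# seeds; images are small so the default test run stays fast.

# smooth textured image with gradients everywhere (velocities are only
# observable where the image has contrast)
texture_image <- function(dims, contrast = 0.25, scale = 3, seed = 1) {
  set.seed(seed)
  array(0.5 + contrast * smooth_random_field(dims, scale)[, 1], dims)
}

smooth_scalar <- function(dims, scale = 6, seed = 1) {
  set.seed(seed)
  smooth_random_field(dims, scale)[, 1]
}

# band-limited velocity with a given maximum magnitude
smooth_velocity <- function(dims, amplitude = 1, scale = 6, seed = 1) {
  set.seed(seed)
  v <- smooth_random_field(dims, scale, length(dims))
  v * (amplitude / max(sqrt(rowSums(v * v))))
}

# dense matrix of a linear operator on fields, built column by column
dense_operator <- function(apply_fn, n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n)
    e[i] <- 1
    A[, i] <- apply_fn(e)
  }
  A
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), .Machine$double.xmin), tol)
}
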