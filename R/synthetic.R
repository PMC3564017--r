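# Synthetic fixtures with known ground truth.
#
# Everything here is deterministic under a fixed seed, and the warped-pair
# generator uses the package's own geodesic shooting, so that recovery tests
# close the loop exactly (the fixtures state the model's own truth; they are
# not a registration benchmark).

sigmoid_edge <- function(dist, width = 1) 1 / (1 + exp(dist / (width / 4)))

#' Smooth zero-mean Gaussian random field
#'
#' White noise filtered with a Gaussian spectral kernel of the stated
#' correlation length, rescaled to unit standard deviation.
#'
#' @param dims grid dimensions.
#' @param scale correlation length in voxels.
#' @param ncomp number of components (1 for scalar fields).
#' @return `prod(dims)` x ncomp matrix.
#' @export
smooth_random_field <- function(dims, scale = 8, ncomp = 1L) {
  d <- length(dims)
  filt <- array(1, dims)
  for (k in seq_len(d)) {
    m <- 0:(dims[k] - 1)
    ang <- 2 * pi * pmin(m, dims[k] - m) / dims[k]
    filt_k <- exp(-0.5 * (ang * scale)^2)
    perm <- c(k, seq_len(d)[-k])
    fp <- aperm(filt, perm) * filt_k
    filt <- aperm(fp, order(perm))
  }
  out <- matrix(0, prod(dims), ncomp)
  for (c in seq_len(ncomp)) {
    A <- array(stats::rnorm(prod(dims)), dims)
    B <- Re(fft(fft(A) * filt, inverse = TRUE)) / prod(dims)
    B <- B - mean(B)
    out[, c] <- as.numeric(B) / stats::sd(B)
  }
  out
}

ellipse_dist <- function(X, center, a, b) {
  r <- sqrt(((X[, 1] - center[1]) / a)^2 + ((X[, 2] - center[2]) / b)^2)
  (r - 1) * min(a, b)
}

#' Simulated circle/ellipse image pair
#'
#' Two 2D images with intensities in [0, 1] and anti-aliased edges: one with
#' circular blobs, one with ellipses of exactly matched areas at the same
#' locations, emulating the classic simulated pair used for regularization
#' studies.  The construction is scale-invariant in `dims`.
#'
#' @param dims image dimensions (default 256 x 128).
#' @return list(A, B): two arrays of dimension `dims`.
#' @export
make_figure3_pair <- function(dims = c(256L, 128L)) {
  stopifnot(length(dims) == 2L)
  W <- dims[1]; H <- dims[2]
  X <- grid_coords(dims)
  k <- 1.6   # ellipse aspect; areas match the circles exactly (pi a b)
  shapes <- list(
    list(center = c(0.34 * W, 0.50 * H), r = 0.32 * H),
    list(center = c(0.75 * W, 0.50 * H), r = 0.16 * H)
  )
  A <- numeric(prod(dims)); B <- numeric(prod(dims))
  for (s in shapes) {
    A <- pmax(A, sigmoid_edge(ellipse_dist(X, s$center, s$r, s$r)))
    B <- pmax(B, sigmoid_edge(ellipse_dist(X, s$center, s$r * k, s$r / k)))
  }
  list(A = array(A, dims), B = array(B, dims))
}

#' Bias-corrupted image pair with known log-field
#'
#' f1 = base exp(-s) + noise, f2 = base exp(+s) + noise, with `s` a smooth
#' random field of the stated amplitude (standard deviation) and correlation
#' length.
#'
#' @param base base image (array).
#' @param sigma_noise additive Gaussian noise standard deviation.
#' @param bias_amp standard deviation of the log-field.
#' @param bias_scale correlation length of the log-field in voxels.
#' @param seed RNG seed (fixtures are bit-reproducible under a fixed seed).
#' @return list(f1, f2, true_b) with `true_b = s` as a vector.
#' @export
make_biased_pair <- function(base, sigma_noise = 0.01, bias_amp = 0.15,
                             bias_scale = 10, seed = 1L) {
  dims <- dim(base)
  withr_seed(seed)
  s <- bias_amp * smooth_random_field(dims, bias_scale)[, 1]
  n1 <- stats::rnorm(prod(dims), 0, sigma_noise)
  n2 <- stats::rnorm(prod(dims), 0, sigma_noise)
  list(f1 = array(as.numeric(base) * exp(-s) + n1, dims),
       f2 = array(as.numeric(base) * exp(+s) + n2, dims),
       true_b = s)
}

withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Warped image pair with known initial velocities
#'
#' The two images are generated from a common midpoint image by shooting
#' +v0/2 and -v0/2 with the package's own integrator, so the symmetric
#' model's ground-truth velocities are exactly +/- v0/2.  If the requested
#' amplitude folds the grid, it is reduced and generation retried.
#'
#' @param base midpoint image.
#' @param amplitude maximum initial-velocity magnitude in voxels.
#' @param reg a [vel_reg()] used both to shape the random field and to shoot.
#' @param scale correlation length of the random velocity (voxels).
#' @param sigma_noise additive noise standard deviation.
#' @param seed RNG seed.
#' @return list(f1, f2, true_v1, true_v2, v0).
#' @export
make_warped_pair <- function(base, amplitude = 2, reg = vel_reg(),
                             scale = 6, sigma_noise = 0, seed = 1L) {
  dims <- dim(base)
  d <- length(dims)
  withr_seed(seed)
  v0 <- amplitude_scaled_field(dims, d, scale, amplitude)
  brep <- spline_rep(base, 3L, "reflect")
  for (try in 1:8) {
    ok <- tryCatch({
      i1 <- shoot_inverse(v0 / 2, reg, dims)
      i2 <- shoot_inverse(-v0 / 2, reg, dims)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    v0 <- v0 * 0.8
  }
  if (!ok) stop("could not generate a diffeomorphic pair at any amplitude")
  f1 <- spline_eval(brep, i1$phi)$values
  f2 <- spline_eval(brep, i2$phi)$values
  if (sigma_noise > 0) {
    f1 <- f1 + stats::rnorm(length(f1), 0, sigma_noise)
    f2 <- f2 + stats::rnorm(length(f2), 0, sigma_noise)
  }
  list(f1 = array(f1, dims), f2 = array(f2, dims),
       true_v1 = v0 / 2, true_v2 = -v0 / 2, v0 = v0)
}

amplitude_scaled_field <- function(dims, d, scale, amplitude) {
  v <- smooth_random_field(dims, scale, d)
  v * (amplitude / max(sqrt(rowSums(v * v))))
}
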