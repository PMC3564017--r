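# B-spline interpolation on regular 2D/3D grids.
#
# Voxel coordinates are 0-based throughout.  Two boundary semantics are
# supported: "reflect" (whole-sample mirror, period 2n-2), used for image
# intensities, and "wrap" (circulant), used for everything living on the
# template grid during geodesic shooting.

#' Grid of 0-based voxel coordinates
#'
#' @param dims integer vector of grid dimensions (length 2 or 3).
#' @return `prod(dims)` x `length(dims)` matrix of coordinates in column-major
#'   order (first axis fastest), matching R array storage.
#' @export
grid_coords <- function(dims) {
  d <- length(dims)
  M <- prod(dims)
  out <- matrix(0, M, d)
  rep_each <- 1L
  for (k in seq_len(d)) {
    out[, k] <- rep(rep(0:(dims[k] - 1L), each = rep_each),
                    length.out = M)
    rep_each <- rep_each * dims[k]
  }
  out
}

fold_index <- function(i, n, boundary) {
  if (n == 1L) return(rep(0L, length(i)))
  if (boundary == "wrap") {
    i %% n
  } else {
    p <- i %% (2L * n - 2L)
    ifelse(p >= n, 2L * n - 2L - p, p)
  }
}

# Cubic B-spline prefilter via FFT.  For "reflect" the array is mirror-extended
# (period 2n-2 per axis) so that the circulant solve is exact for the mirrored
# signal; the extension is then cropped.
bspline_prefilter <- function(A, boundary) {
  dims <- dim(A)
  d <- length(dims)
  if (boundary == "reflect") {
    idx <- lapply(dims, function(n) if (n > 1) c(1:n, (n - 1):2) else 1L)
    A <- do.call(`[`, c(list(A), idx, list(drop = FALSE)))
  }
  de <- dim(A)
  tot <- array(1, de)
  for (k in seq_len(d)) {
    n <- de[k]
    th <- 2 * pi * (0:(n - 1)) / n
    bk <- (4 + 2 * cos(th)) / 6
    # broadcast multiply along axis k
    perm <- c(k, seq_len(d)[-k])
    tp <- aperm(tot, perm)
    tp <- tp * bk
    tot <- aperm(tp, order(perm))
  }
  C <- Re(fft(fft(A) / tot, inverse = TRUE)) / prod(de)
  if (boundary == "reflect") {
    idx <- lapply(dims, seq_len)
    C <- do.call(`[`, c(list(C), idx, list(drop = FALSE)))
  }
  C
}

#' Spline representation of a gridded image or field
#'
#' Precomputes interpolation coefficients so that repeated evaluation is cheap.
#' Degrees 1 (linear) and 3 (cubic B-spline, with exact prefilter) are
#' supported; multi-channel arrays put channels in the last dimension.
#'
#' @param A numeric array; spatial dimensions first.
#' @param degree 1 or 3.
#' @param boundary "reflect" or "wrap".
#' @param channels number of trailing channel dimensions collapsed into one
#'   (0 for scalar images).
#' @return object of class `spline_rep`.
#' @export
spline_rep <- function(A, degree = 3L, boundary = "reflect", channels = 0L) {
  stopifnot(degree %in% c(1L, 3L), boundary %in% c("reflect", "wrap"))
  da <- dim(A)
  if (is.null(da)) da <- length(A)
  if (channels > 0L) {
    dims <- da[seq_len(length(da) - channels)]
    nc <- prod(da[(length(da) - channels + 1L):length(da)])
  } else {
    dims <- da
    nc <- 1L
  }
  M <- prod(dims)
  Cm <- matrix(as.numeric(A), M, nc)
  if (degree == 3L) {
    for (c in seq_len(nc)) {
      Cm[, c] <- as.numeric(bspline_prefilter(array(Cm[, c], dims), boundary))
    }
  }
  structure(list(C = Cm, dims = as.integer(dims), nc = nc,
                 degree = as.integer(degree), boundary = boundary),
            class = "spline_rep")
}

cubic_w <- function(t) {
  # weights for offsets -1,0,1,2 given fractional part t in [0,1)
  u <- 1 - t
  list(u * u * u / 6,
       (3 * t^3 - 6 * t^2 + 4) / 6,
       (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
       t^3 / 6)
}

cubic_dw <- function(t) {
  u <- 1 - t
  list(-u * u / 2,
       (3 * t^2 - 4 * t) / 2,
       (-3 * t^2 + 2 * t + 1) / 2,
       t^2 / 2)
}

#' Evaluate a spline representation at arbitrary voxel coordinates
#'
#' @param S a [spline_rep()].
#' @param P M x d matrix of 0-based voxel coordinates.
#' @param gradient if `TRUE`, also return per-axis spatial derivatives.
#' @return list with `values` (M x nc matrix, or vector when nc = 1), `mask`
#'   (logical M, inside the source field of view), and optionally `grad`
#'   (M x d x nc array, dropped to M x d when nc = 1).
#' @export
spline_eval <- function(S, P, gradient = FALSE) {
  dims <- S$dims
  d <- length(dims)
  stopifnot(ncol(P) == d)
  M <- nrow(P)
  nc <- S$nc
  if (S$degree == 3L) {
    offs <- -1:2
    i0 <- floor(P)
    Wk <- vector("list", d); dWk <- vector("list", d)
    for (k in seq_len(d)) {
      t <- P[, k] - i0[, k]
      Wk[[k]] <- cubic_w(t)
      if (gradient) dWk[[k]] <- cubic_dw(t)
    }
  } else {
    offs <- 0:1
    i0 <- floor(P)
    Wk <- vector("list", d); dWk <- vector("list", d)
    for (k in seq_len(d)) {
      t <- P[, k] - i0[, k]
      Wk[[k]] <- list(1 - t, t)
      if (gradient) dWk[[k]] <- list(rep(-1, M), rep(1, M))
    }
  }
  no <- length(offs)
  # fold all needed indices once per axis/offset
  idx <- vector("list", d)
  for (k in seq_len(d)) {
    idx[[k]] <- lapply(seq_len(no), function(o)
      fold_index(as.integer(i0[, k]) + offs[o], dims[k], S$boundary))
  }
  strides <- cumprod(c(1L, dims[-d]))
  vals <- matrix(0, M, nc)
  grad <- if (gradient) array(0, c(M, d, nc)) else NULL
  combo <- as.matrix(do.call(expand.grid, rep(list(seq_len(no)), d)))
  for (r in seq_len(nrow(combo))) {
    lin <- rep(1, M)
    for (k in seq_len(d)) lin <- lin + idx[[k]][[combo[r, k]]] * strides[k]
    w <- Wk[[1]][[combo[r, 1]]]
    if (d > 1) for (k in 2:d) w <- w * Wk[[k]][[combo[r, k]]]
    g <- S$C[lin, , drop = FALSE]
    vals <- vals + w * g
    if (gradient) {
      for (a in seq_len(d)) {
        wa <- dWk[[a]][[combo[r, a]]]
        for (k in seq_len(d)) if (k != a) wa <- wa * Wk[[k]][[combo[r, k]]]
        grad[, a, ] <- grad[, a, ] + wa * g
      }
    }
  }
  mask <- rep(TRUE, M)
  for (k in seq_len(d)) {
    mask <- mask & P[, k] >= 0 & P[, k] <= dims[k] - 1L
  }
  out <- list(values = if (nc == 1L) drop(vals) else vals, mask = mask)
  if (gradient) {
    out$grad <- if (nc == 1L) array(grad, c(M, d)) else grad
  }
  out
}

#' Resample a gridded image at mapped voxel coordinates
#'
#' Convenience wrapper: builds the spline representation and evaluates it.
#' Points outside the source field of view are flagged in the mask; values
#' there come from the boundary extension and should be down-weighted to zero
#' by callers.
#'
#' @param A numeric array.
#' @param P M x d matrix of 0-based coordinates in `A`'s voxel space.
#' @param degree interpolation degree (1 or 3).
#' @param boundary boundary handling.
#' @param gradient also return spatial derivatives.
#' @export
resample <- function(A, P, degree = 3L, boundary = "reflect",
                     gradient = FALSE) {
  spline_eval(spline_rep(A, degree, boundary), P, gradient = gradient)
}
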