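# Dense matrix exponential / logarithm and small batched Hermitian solves.
# Scaling-and-squaring is used in both directions; accuracy near machine
# precision is needed because the exponential-barycenter fixed point is
# iterated to 1e-10 in the Frobenius norm.

#' Matrix exponential by scaling and squaring
#'
#' Power-series evaluation after scaling the argument so that its Frobenius
#' norm is below 1/2, followed by repeated squaring.
#'
#' @param A square numeric matrix.
#' @return Matrix exponential of `A`.
#' @export
mat_exp <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  nrm <- norm(A, "F")
  if (nrm == 0) return(diag(n))
  j <- max(0L, ceiling(log2(nrm)) + 1L)
  As <- A / 2^j
  E <- diag(n) + As
  term <- As
  for (k in 2:30) {
    term <- term %*% As / k
    E <- E + term
    if (norm(term, "F") < 1e-17 * norm(E, "F")) break
  }
  for (i in seq_len(j)) E <- E %*% E
  E
}

# Denman-Beavers iteration for the principal matrix square root.
mat_sqrt <- function(A, maxit = 50L) {
  Y <- A
  Z <- diag(nrow(A))
  for (i in seq_len(maxit)) {
    Y1 <- 0.5 * (Y + solve(Z))
    Z1 <- 0.5 * (Z + solve(Y))
    d <- norm(Y1 - Y, "F")
    Y <- Y1; Z <- Z1
    if (d < 1e-14 * max(1, norm(Y, "F"))) break
  }
  Y
}

#' Principal matrix logarithm by inverse scaling and squaring
#'
#' Repeated principal square roots bring the argument close to the identity,
#' where a truncated Mercator series applies; the result is scaled back up.
#' Intended for voxel-to-world affines and rigid-body transforms, i.e.
#' matrices with no eigenvalues on the closed negative real axis.
#'
#' @param A square numeric matrix (invertible, principal log assumed to exist).
#' @return Matrix `X` with `mat_exp(X)` equal to `A`.
#' @export
mat_log <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  if (abs(det(A)) < .Machine$double.eps) {
    stop("matrix logarithm of a singular matrix")
  }
  k <- 0L
  B <- A
  while (norm(B - diag(n), "F") > 0.25 && k < 60L) {
    B <- mat_sqrt(B)
    k <- k + 1L
  }
  if (norm(B - diag(n), "F") > 0.25) {
    stop("matrix logarithm did not converge (matrix too far from identity)")
  }
  X <- B - diag(n)
  S <- X
  P <- X
  for (m in 2:40) {
    P <- P %*% X
    S <- S + ((-1)^(m + 1) / m) * P
    if (norm(P, "F") / m < 1e-17 * max(1, norm(S, "F"))) break
  }
  S * 2^k
}

# ---- batched small Hermitian matrix fields -----------------------------------
# A matrix field is a d x d list-of-lists, each element a complex vector of
# length M (one value per spatial frequency).  Used for the momentum operator
# symbol and its Green's function.

mat_field_apply <- function(A, vm) {
  d <- length(A)
  out <- vector("list", d)
  for (j in seq_len(d)) {
    acc <- A[[j]][[1]] * vm[[1]]
    if (d > 1) for (l in 2:d) acc <- acc + A[[j]][[l]] * vm[[l]]
    out[[j]] <- acc
  }
  out
}

mat_field_inv <- function(A) {
  d <- length(A)
  if (d == 1) {
    return(list(list(1 / A[[1]][[1]])))
  }
  if (d == 2) {
    a <- A[[1]][[1]]; b <- A[[1]][[2]]
    c <- A[[2]][[1]]; e <- A[[2]][[2]]
    det <- a * e - b * c
    return(list(
      list(e / det, -b / det),
      list(-c / det, a / det)
    ))
  }
  if (d == 3) {
    a11 <- A[[1]][[1]]; a12 <- A[[1]][[2]]; a13 <- A[[1]][[3]]
    a21 <- A[[2]][[1]]; a22 <- A[[2]][[2]]; a23 <- A[[2]][[3]]
    a31 <- A[[3]][[1]]; a32 <- A[[3]][[2]]; a33 <- A[[3]][[3]]
    c11 <- a22 * a33 - a23 * a32
    c12 <- a13 * a32 - a12 * a33
    c13 <- a12 * a23 - a13 * a22
    c21 <- a23 * a31 - a21 * a33
    c22 <- a11 * a33 - a13 * a31
    c23 <- a13 * a21 - a11 * a23
    c31 <- a21 * a32 - a22 * a31
    c32 <- a12 * a31 - a11 * a32
    c33 <- a11 * a22 - a12 * a21
    det <- a11 * c11 + a21 * c12 + a31 * c13
    return(list(
      list(c11 / det, c12 / det, c13 / det),
      list(c21 / det, c22 / det, c23 / det),
      list(c31 / det, c32 / det, c33 / det)
    ))
  }
  stop("unsupported dimension")
}
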