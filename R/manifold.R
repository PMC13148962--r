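#' Differential geometry on the cone of symmetric positive-definite matrices
#'
#' Gene coexpression matrices are symmetric positive (semi-)definite (SPD/PSD)
#' and live on a curved Riemannian manifold, not in Euclidean space. These
#' primitives -- matrix logarithm/exponential, the log-Euclidean distance, the
#' affine-invariant geodesic distance, and condition-volume normalization --
#' are the geometric core on which local coexpression comparison is built.
#'
#' @name manifold
NULL

.sym_tol <- 1e-8

# Symmetric eigendecomposition with a deterministic sign convention: each
# eigenvector's first component of magnitude > tol is made positive.
# Eigenvalues come back nonincreasing (LAPACK dsyevr convention).
sym_eigen <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  Q <- e$vectors
  for (j in seq_len(ncol(Q))) {
    nz <- which(abs(Q[, j]) > 1e-12)
    if (length(nz) && Q[nz[1], j] < 0) Q[, j] <- -Q[, j]
  }
  list(values = e$values, vectors = Q)
}

check_symmetric <- function(A, name = "A") {
  A <- as_dense_matrix(A)
  if (nrow(A) != ncol(A)) {
    abort(sprintf("`%s` must be square, got %d x %d.", name, nrow(A), ncol(A)),
          class = "sceodesic_validation_error")
  }
  asym <- max(abs(A - t(A)))
  scale <- max(abs(A), 1)
  if (asym > .sym_tol * scale) {
    abort(sprintf("`%s` is not symmetric: max |A - t(A)| = %.3g.", name, asym),
          class = "sceodesic_validation_error")
  }
  (A + t(A)) / 2
}

#' Matrix logarithm of a symmetric positive-definite matrix
#'
#' The matrix log shares the eigenvectors of its argument; its eigenvalues are
#' the (scalar) logs of the original eigenvalues. This is the map from the SPD
#' manifold to its tangent space at the identity, where Euclidean arithmetic
#' on coexpression becomes meaningful.
#'
#' @param A A symmetric positive-definite matrix.
#' @return A symmetric matrix `Q diag(log lambda) Q'`.
#' @export
#' @examples
#' matrix_log(diag(c(exp(1), exp(2))))
matrix_log <- function(A) {
  A <- check_symmetric(A)
  e <- sym_eigen(A)
  smax <- max(e$values)
  tol <- 1e-12 * max(smax, 1)
  if (min(e$values) <= tol) {
    abort(sprintf(
      "Matrix is singular or indefinite: smallest eigenvalue %.3g (tolerance %.3g).",
      min(e$values), tol),
      class = "sceodesic_singularity_error")
  }
  L <- e$vectors %*% (log(e$values) * t(e$vectors))
  (L + t(L)) / 2
}

#' Matrix exponential of a symmetric matrix
#'
#' Inverse of [matrix_log()] on the SPD cone.
#'
#' @param A A symmetric matrix.
#' @return The symmetric positive-definite matrix `Q diag(exp lambda) Q'`.
#' @export
matrix_exp <- function(A) {
  A <- check_symmetric(A)
  e <- sym_eigen(A)
  E <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (E + t(E)) / 2
}

#' Log-Euclidean distance between SPD matrices
#'
#' The Frobenius norm of the difference of matrix logarithms,
#' `||log(A) - log(B)||_F`. It is a true metric on the SPD cone and a lower
#' bound of the affine-invariant geodesic distance, computable with a single
#' eigendecomposition per matrix.
#'
#' @param A,B Symmetric positive-definite matrices of equal dimension.
#' @return A nonnegative scalar.
#' @export
log_euclidean_distance <- function(A, B) {
  A <- as_dense_matrix(A); B <- as_dense_matrix(B)
  if (!all(dim(A) == dim(B))) {
    abort(sprintf("Dimension mismatch: %d x %d vs %d x %d.",
                  nrow(A), ncol(A), nrow(B), ncol(B)),
          class = "sceodesic_validation_error")
  }
  norm(matrix_log(A) - matrix_log(B), type = "F")
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' The canonical Riemannian geodesic distance
#' `||log(A^{-1/2} B A^{-1/2})||_F`. It is invariant under congruence
#' `(A, B) -> (M A M', M B M')` for any invertible `M` and upper-bounds the
#' log-Euclidean distance; used here as the reference metric when auditing the
#' log-Euclidean approximation.
#'
#' @inheritParams log_euclidean_distance
#' @return A nonnegative scalar.
#' @export
affine_invariant_distance <- function(A, B) {
  A <- check_symmetric(A, "A"); B <- check_symmetric(B, "B")
  if (!all(dim(A) == dim(B))) {
    abort("Dimension mismatch between A and B.", class = "sceodesic_validation_error")
  }
  ea <- sym_eigen(A)
  smax <- max(ea$values)
  if (min(ea$values) <= 1e-12 * max(smax, 1)) {
    abort("A is singular: cannot form A^{-1/2}.", class = "sceodesic_singularity_error")
  }
  Ainvhalf <- ea$vectors %*% ((1 / sqrt(ea$values)) * t(ea$vectors))
  W <- Ainvhalf %*% B %*% Ainvhalf
  norm(matrix_log((W + t(W)) / 2), type = "F")
}

#' Condition-volume normalization of a covariance matrix
#'
#' Regularizes a (possibly singular) sample covariance matrix into the
#' well-conditioned positive-definite matrix nearest to it in Frobenius norm:
#' eigenvalues are floored at `sigma_max / M` (Tanaka-Nakata nearest matrix
#' with condition number at most `M`), then every eigenvalue is divided by the
#' floored minimum so the spectrum lies in `[1, M]`. The rescaling makes the
#' smallest log-eigenvalues exactly zero (sparsifying the tangent-space image)
#' and bounds the determinant -- the "volume" of overall covariance -- by
#' `M^h`, making magnitudes comparable across cell cohorts.
#'
#' @param S A symmetric positive semi-definite matrix (sample covariance).
#'   Small negative eigenvalues from numerical error are clamped to zero.
#' @param M Target condition number, `> 1`. Default 50.
#' @param rescale If `TRUE` (default) divide the spectrum by its floored
#'   minimum so eigenvalues lie in `[1, M]`; if `FALSE` return the floored
#'   matrix unscaled (the Frobenius-nearest condition-constrained matrix).
#' @return A list of class `spd_matrix` with elements `values` (the matrix),
#'   `eigenvalues` (nonincreasing), `eigenvectors`, `scale` (the divisor
#'   `sigma_tilde_min` applied when rescaling), and `M`.
#' @export
#' @examples
#' condition_volume_normalize(diag(c(100, 1)), M = 50)$eigenvalues
condition_volume_normalize <- function(S, M = 50, rescale = TRUE) {
  assert_scalar_number(M, "M")
  if (M <= 1) {
    abort("Target condition number `M` must be > 1.", class = "sceodesic_config_error")
  }
  S <- check_symmetric(S, "S")
  e <- sym_eigen(S)
  vals <- pmax(e$values, 0)
  smax <- max(vals)
  if (smax <= 0) {
    abort("Cannot normalize the zero matrix: sigma_max = 0 gives no scale.",
          class = "sceodesic_singularity_error")
  }
  floored <- pmax(vals, smax / M)
  scale <- if (rescale) min(floored) else 1
  newvals <- floored / scale
  V <- e$vectors %*% (newvals * t(e$vectors))
  structure(
    list(values = (V + t(V)) / 2,
         eigenvalues = newvals,
         eigenvectors = e$vectors,
         scale = scale,
         M = M),
    class = "spd_matrix"
  )
}

#' @export
print.spd_matrix <- function(x, ...) {
  h <- length(x$eigenvalues)
  cat(sprintf("<spd_matrix> %d x %d, eigenvalues in [%.4g, %.4g], cond %.4g (M = %g)\n",
              h, h, min(x$eigenvalues), max(x$eigenvalues),
              max(x$eigenvalues) / min(x$eigenvalues), x$M))
  invisible(x)
}
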