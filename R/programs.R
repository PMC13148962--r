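#' Study-wide gene programs by population value decomposition
#'
#' Each cohort's normalized covariance has an eigenbasis of local gene
#' programs. Population value decomposition (PVD) treats the pooled local
#' eigenvectors themselves as observations in gene space and extracts, by
#' (sparse) principal component analysis of that pool, a single study-wide
#' dictionary of programs that best reconstructs the local bases.
#'
#' @name programs
NULL

#' Collect retained local eigenvectors from cohort covariances
#'
#' Per cohort, keeps eigenvectors of the normalized covariance in
#' nonincreasing eigenvalue order up to the smallest count whose cumulative
#' eigenvalue share reaches `v_pvd` (default 0.9, i.e. 90% of cohort
#' variability), limiting noisy trailing features. Each retained vector's
#' largest-magnitude component is made positive.
#'
#' @param covs A [cohort_covariances()] result.
#' @param v_pvd Fraction of per-cohort variance to retain, in (0, 1].
#' @return A list of class `local_programs`: per cohort a list with
#'   `cohort_index`, `vectors` (genes x m_k), `retained_variance`.
#' @export
collect_local_programs <- function(covs, v_pvd = 0.9) {
  stopifnot(inherits(covs, "cohort_covariances"))
  assert_scalar_number(v_pvd, "v_pvd", lower = 1e-12, upper = 1)
  out <- lapply(seq_along(covs$covariances), function(k) {
    st <- covs$covariances[[k]]$sigma_tilde
    vals <- st$eigenvalues
    share <- cumsum(vals) / sum(vals)
    m <- which(share >= v_pvd - 1e-12)[1]
    V <- st$eigenvectors[, seq_len(m), drop = FALSE]
    for (j in seq_len(ncol(V))) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    list(cohort_index = k, vectors = V,
         retained_variance = share[m])
  })
  structure(out, class = "local_programs")
}

# Pool local eigenbases into one genes x (sum m_k) matrix.
pool_matrix <- function(local) {
  do.call(cbind, lapply(local, `[[`, "vectors"))
}

# Sparse rank-k second-moment PCA of the pooled eigenvectors, in the
# elastic-net thresholding limit of Zou-style alternating SPCA:
#   B-step: b_j = soft(C a_j, lambda * max|C a_j|), C = pool %*% t(pool)
#   A-step: A = UV' from the SVD of C B  (Procrustes)
# `lambda` is a relative threshold in [0, 1).
sparse_pca_pool <- function(P, k, lambda, max_iter = 1000L, tol = 1e-7) {
  C <- P %*% t(P)
  sv <- svd(C, nu = k, nv = 0)
  A <- sv$u[, seq_len(k), drop = FALSE]
  B <- A
  soft <- function(w, t) sign(w) * pmax(abs(w) - t, 0)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    W <- C %*% A
    B_new <- W
    for (j in seq_len(k)) {
      B_new[, j] <- soft(W[, j], lambda * max(abs(W[, j])))
    }
    s2 <- svd(C %*% B_new)
    A_new <- s2$u %*% t(s2$v)
    resid <- max(norm(B_new - B, "F") / max(1, norm(B, "F")),
                 norm(A_new - A, "F"))
    A <- A_new; B <- B_new
    if (resid < tol) break
  }
  if (resid >= tol && max_iter > 1L) {
    abort(sprintf(
      "Sparse PCA did not converge after %d iterations (last relative change %.3g).",
      max_iter, resid),
      class = "sceodesic_convergence_error")
  }
  B
}

#' Fit the study-wide program dictionary (PVD)
#'
#' Performs (sparse) PCA on the pooled retained cohort eigenvectors, treating
#' each eigenvector as an observation in gene space. With `lambda = 0` this is
#' exact (uncentered, second-moment) PCA of the pool -- pooled eigenvectors
#' have no natural origin, so no centering is applied. With `lambda > 0` each
#' component is estimated by alternating soft-thresholding (an elastic-net
#' limit of sparse PCA), `lambda` acting as a relative threshold in `[0, 1)`.
#' Columns are unit-normalized, ordered by explained pool variance, and
#' sign-fixed (largest-magnitude component positive). If the pool has rank
#' below `h`, trailing programs are zero-padded with a warning.
#'
#' @param local A [collect_local_programs()] result (or a plain genes x pool
#'   matrix of unit-norm columns).
#' @param h Number of programs (defaults to the gene dimension).
#' @param lambda Sparsity penalty in `[0, 1)`; 0 gives dense PCA.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @return A list of class `program_dictionary`: `programs` (genes x h matrix
#'   `U_hat`), `sparsity_lambda`, `support` (list of nonzero index sets),
#'   `explained` (pool variance share per program), `seed`.
#' @export
pvd_fit <- function(local, h = NULL, lambda = 0, seed = 1L) {
  P <- if (inherits(local, "local_programs")) pool_matrix(local) else
    as_dense_matrix(local)
  g <- nrow(P)
  if (is.null(h)) h <- g
  assert_scalar_number(h, "h", lower = 1, upper = g)
  assert_scalar_number(lambda, "lambda", lower = 0, upper = 1 - 1e-9)
  if (ncol(P) < h) {
    abort(sprintf(
      "Pooled eigenvectors (%d) fewer than requested programs (%d); lower h or set v_pvd = 1.",
      ncol(P), h),
      class = "sceodesic_validation_error")
  }
  rank_tol <- 1e-10
  if (lambda == 0) {
    sv <- svd(P, nu = h, nv = 0)
    U <- sv$u[, seq_len(h), drop = FALSE]
    d <- sv$d[seq_len(h)]
    # within groups of (numerically) tied singular values the PCA basis is
    # arbitrary; break ties toward the pooled eigenvectors themselves so a
    # single-cohort pool reproduces the cohort's own eigenbasis exactly
    grp <- cumsum(c(TRUE, diff(d) < -1e-8 * max(sv$d)))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < 2) next
      Ug <- U[, idx, drop = FALSE]
      coords <- t(Ug) %*% P
      B <- matrix(0, length(idx), length(idx))
      for (t in seq_along(idx)) {
        nrm <- colSums(coords^2)
        j <- which.max(nrm)
        if (nrm[j] < rank_tol) break
        b <- coords[, j] / sqrt(nrm[j])
        B[, t] <- b
        coords <- coords - b %*% (t(b) %*% coords)
      }
      if (all(colSums(B^2) > 0.5)) U[, idx] <- Ug %*% B
    }
    keep <- d > rank_tol * max(sv$d)
  } else {
    U <- sparse_pca_pool(P, h, lambda)
    keep <- colSums(abs(U)) > 0
  }
  if (!all(keep)) {
    warn(sprintf(
      "Pool supports only %d of %d programs; trailing programs zero-padded.",
      sum(keep), h))
    U[, !keep] <- 0
  }
  nrm <- sqrt(colSums(U^2))
  U[, nrm > 0] <- sweep(U[, nrm > 0, drop = FALSE], 2, nrm[nrm > 0], "/")
  # order by explained pool variance, then fix signs
  expl <- rowSums((t(U) %*% P)^2)
  ord <- order(-expl)
  U <- U[, ord, drop = FALSE]
  expl <- expl[ord]
  for (j in seq_len(ncol(U))) {
    if (any(U[, j] != 0)) {
      i <- which.max(abs(U[, j]))
      if (U[i, j] < 0) U[, j] <- -U[, j]
    }
  }
  rownames(U) <- rownames(P)
  colnames(U) <- paste0("program_", seq_len(h))
  structure(
    list(programs = U,
         sparsity_lambda = lambda,
         support = apply(U, 2, function(v) which(abs(v) > 1e-12),
                         simplify = FALSE),
         explained = expl / sum(colSums(P^2)),
         seed = as.integer(seed)),
    class = "program_dictionary"
  )
}

#' @export
print.program_dictionary <- function(x, ...) {
  supp <- lengths(x$support)
  cat(sprintf("<program_dictionary> %d programs over %d genes, lambda = %g, support sizes %d-%d\n",
              ncol(x$programs), nrow(x$programs), x$sparsity_lambda,
              min(supp), max(supp)))
  invisible(x)
}

#' @rdname pvd_fit
#' @param x A `program_dictionary`.
#' @param ... Unused.
#' @method tidy program_dictionary
#' @export
tidy.program_dictionary <- function(x, ...) {
  U <- x$programs
  tibble::tibble(
    program = rep(colnames(U), each = nrow(U)),
    gene = rep(rownames(U) %||% as.character(seq_len(nrow(U))), ncol(U)),
    weight = as.vector(U)
  ) |> dplyr::filter(abs(.data$weight) > 1e-12)
}
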