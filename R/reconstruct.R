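#' Log-Euclidean reconstruction of cohort coexpression
#'
#' Given the study-wide program dictionary `U_hat`, each cohort's normalized
#' covariance is re-expressed as program loadings by minimizing the
#' log-Euclidean objective `|| log(Sigma_tilde) - log(U_hat S U_hat') ||_F`
#' over diagonal `S`. Because `log(U_hat S U_hat') = U_hat log(S) U_hat'`, the
#' problem is solved on the tangent space in closed form:
#' `loading_j = [U_hat' log(Sigma_tilde) U_hat]_jj`.
#'
#' @name reconstruct
NULL

#' Closed-form program loadings for one cohort covariance
#'
#' @param cov A single cohort entry from [cohort_covariances()] (a list with
#'   `sigma_tilde` and `log_sigma`), or an `spd_matrix`, or a plain normalized
#'   SPD matrix.
#' @param dict A [pvd_fit()] dictionary (or a plain genes x h matrix with
#'   unit-norm columns).
#' @return A list with `loadings` (length h, the diagonal of
#'   `U_hat' log(Sigma_tilde) U_hat`) and `residual`
#'   (`|| log(Sigma_tilde) - U_hat diag(loadings) U_hat' ||_F`). When `U_hat`
#'   is orthogonal and equals the cohort's own eigenbasis, the loadings are
#'   the log-eigenvalues and the residual is 0; for sparse, non-orthogonal
#'   `U_hat` the same closed form is applied and the residual reports the
#'   reconstruction quality.
#' @export
reconstruct_loadings <- function(cov, dict) {
  L <- if (is.list(cov) && !is.null(cov$log_sigma)) {
    cov$log_sigma
  } else if (inherits(cov, "spd_matrix")) {
    cov$eigenvectors %*% (log(cov$eigenvalues) * t(cov$eigenvectors))
  } else {
    matrix_log(as_dense_matrix(cov))
  }
  U <- if (inherits(dict, "program_dictionary")) dict$programs else
    as_dense_matrix(dict)
  if (nrow(U) != nrow(L)) {
    abort(sprintf("Dictionary has %d genes but covariance has %d.",
                  nrow(U), nrow(L)),
          class = "sceodesic_validation_error")
  }
  M <- t(U) %*% L %*% U
  s <- diag(M)
  R <- L - U %*% (s * t(U))
  list(loadings = as.numeric(s), residual = norm(R, type = "F"))
}

#' Broadcast cohort loadings to a cell-by-program matrix
#'
#' Every cell receives the loading vector of its cohort; row order follows the
#' input cell order. Optionally concatenates an external per-cell embedding
#' (e.g. PCA or NMF scores) column-wise, combining global and local features.
#'
#' @param loadings An `n_cohorts x h` matrix of per-cohort loadings.
#' @param model A [build_cohorts()] result (or an integer assignment vector).
#' @param extra Optional `N x p` matrix of per-cell features to append.
#' @return An `N x h` (or `N x (h + p)`) matrix.
#' @export
assemble_cell_matrix <- function(loadings, model, extra = NULL) {
  loadings <- as_dense_matrix(loadings)
  assignment <- if (inherits(model, "cohort_model")) model$assignment else
    as.integer(model)
  if (any(assignment < 1L) || any(assignment > nrow(loadings))) {
    abort(sprintf(
      "Assignment indices must lie in [1, %d] (the number of loading rows).",
      nrow(loadings)),
      class = "sceodesic_validation_error")
  }
  out <- loadings[assignment, , drop = FALSE]
  rownames(out) <- names(assignment)
  if (!is.null(extra)) {
    extra <- as_dense_matrix(extra)
    if (nrow(extra) != length(assignment)) {
      abort("`extra` must have one row per cell.",
            class = "sceodesic_validation_error")
    }
    out <- cbind(out, extra)
  }
  out
}
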