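#' Fit cell-state-specific gene programs
#'
#' Runs the full pipeline on a cell-by-gene count matrix: median-library
#' log-normalization, highly-variable-gene selection, cohort construction,
#' per-cohort condition-volume-normalized covariance estimation, population
#' value decomposition of the pooled cohort eigenbases into a study-wide
#' program dictionary, and closed-form log-Euclidean reconstruction of each
#' cohort's covariance as program loadings broadcast to every cell.
#'
#' @param X Cell-by-gene count matrix (dense or `Matrix` sparse), ideally with
#'   cell/gene dimnames.
#' @param h Number of highly variable genes / programs (default 300, capped at
#'   the gene count). Guidance: around 300 genes keeps per-cohort covariance
#'   estimation tractable.
#' @param n_cohorts Number of cohorts (default `max(2, N / h)` so a typical
#'   cohort is just large enough to avoid a singular covariance; 1 is allowed).
#' @param method Cohorting method: `"gmm"` (default), `"kmeans"`, or
#'   `"provided"` (with `labels`).
#' @param labels Cohort labels when `method = "provided"`.
#' @param M Target condition number for covariance normalization (default 50).
#' @param lambda Sparse-PCA penalty in `[0, 1)` (default 0, dense programs).
#' @param v_pvd Per-cohort variance fraction retained in the PVD pool
#'   (default 0.9).
#' @param gamma GMM diagonal ridge (default 0.01).
#' @param seed Integer seed fanned out to all random substeps.
#' @param normalized Set `TRUE` if `X` is already log-normalized expression.
#' @return An object of class `sceodesic_fit` with components `programs`
#'   (a `program_dictionary`), `cohort_loadings` (n x h matrix), `cell_matrix`
#'   (N x h, the "X_sceodesic" embedding), `residuals` (length n),
#'   `cohorts` (`cohort_model`), `covariances` (`cohort_covariances`),
#'   `hvg` (`hvg_selection` or NULL), and `config`.
#' @seealso [tidy.sceodesic_fit()], [glance.sceodesic_fit()],
#'   [autoplot.sceodesic_fit()]
#' @export
sceodesic <- function(X, h = 300, n_cohorts = NULL,
                      method = c("gmm", "kmeans", "provided"), labels = NULL,
                      M = 50, lambda = 0, v_pvd = 0.9, gamma = 0.01,
                      seed = 1L, normalized = FALSE) {
  method <- match.arg(method)
  X <- as_dense_matrix(X)
  N <- nrow(X)
  h <- min(h, ncol(X))
  if (is.null(n_cohorts)) n_cohorts <- max(2, round(N / h))
  Xnorm <- if (normalized) X else normalize_counts(X)
  hvg <- NULL
  if (h < ncol(Xnorm)) {
    hvg <- select_variable_genes(Xnorm, h = h, seed = seed)
    Xh <- Xnorm[, hvg$selected_indices, drop = FALSE]
  } else {
    Xh <- Xnorm
  }
  model <- build_cohorts(Xh, n = n_cohorts, method = method, labels = labels,
                         gamma = gamma, seed = seed)
  covs <- cohort_covariances(Xh, model, M = M)
  model <- covs$model
  local <- collect_local_programs(covs, v_pvd = v_pvd)
  dict <- pvd_fit(local, h = h, lambda = lambda,
                  seed = substream_seed(seed, "pvd"))
  rec <- lapply(covs$covariances, reconstruct_loadings, dict = dict)
  loadings <- do.call(rbind, lapply(rec, `[[`, "loadings"))
  residuals <- vapply(rec, `[[`, numeric(1), "residual")
  colnames(loadings) <- colnames(dict$programs)
  rownames(loadings) <- paste0("cohort_", seq_len(nrow(loadings)))
  cell_matrix <- assemble_cell_matrix(loadings, model)
  rownames(cell_matrix) <- rownames(Xh) %||% paste0("cell_", seq_len(N))
  structure(
    list(programs = dict,
         cohort_loadings = loadings,
         cell_matrix = cell_matrix,
         residuals = residuals,
         cohorts = model,
         covariances = covs,
         hvg = hvg,
         config = list(h = h, n_cohorts = model$n_cohorts, method = method,
                       M = M, lambda = lambda, v_pvd = v_pvd, gamma = gamma,
                       seed = seed)),
    class = "sceodesic_fit"
  )
}

#' @export
print.sceodesic_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sceodesic_fit> %d cells, %d genes/programs, %d cohorts (%s)\n",
    nrow(x$cell_matrix), cfg$h, cfg$n_cohorts, cfg$method))
  cat(sprintf("  M = %g, lambda = %g, v_pvd = %g; reconstruction residuals %.3g-%.3g\n",
              cfg$M, cfg$lambda, cfg$v_pvd, min(x$residuals), max(x$residuals)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-cohort program loadings of a fit
#'
#' One row per (cohort, program) with the loading and the cohort's
#' reconstruction residual.
#'
#' @param x A [sceodesic()] fit.
#' @param ... Unused.
#' @return A tibble with columns `cohort`, `program`, `loading`, `residual`,
#'   `n_cells`.
#' @method tidy sceodesic_fit
#' @export
tidy.sceodesic_fit <- function(x, ...) {
  L <- x$cohort_loadings
  tibble::tibble(
    cohort = rep(seq_len(nrow(L)), times = ncol(L)),
    program = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  ) |>
    dplyr::left_join(
      tibble::tibble(cohort = seq_len(nrow(L)),
                     residual = x$residuals,
                     n_cells = x$cohorts$sizes),
      by = "cohort") |>
    dplyr::arrange(.data$cohort)
}

#' One-row summary of a fit
#'
#' @inheritParams tidy.sceodesic_fit
#' @return A tibble with `n_cells`, `n_genes`, `n_cohorts`, `lambda`,
#'   `v_pvd`, `M`, `mean_residual`, `max_residual`, `mean_support`.
#' @method glance sceodesic_fit
#' @export
glance.sceodesic_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cell_matrix),
    n_genes = x$config$h,
    n_cohorts = x$config$n_cohorts,
    lambda = x$config$lambda,
    v_pvd = x$config$v_pvd,
    M = x$config$M,
    mean_residual = mean(x$residuals),
    max_residual = max(x$residuals),
    mean_support = mean(lengths(x$programs$support))
  )
}

#' Heatmap of per-cohort program expression
#'
#' @param object A [sceodesic()] fit.
#' @param top_programs Number of leading programs to show (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sceodesic_fit
#' @export
autoplot.sceodesic_fit <- function(object, top_programs = 25, ...) {
  L <- object$cohort_loadings
  keep <- head(seq_len(ncol(L)), top_programs)
  df <- tidy(object) |>
    dplyr::filter(.data$program %in% colnames(L)[keep])
  df$program <- factor(df$program, levels = colnames(L)[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$program, y = factor(.data$cohort),
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "gene program", y = "cell cohort",
                  fill = "log-scale\nloading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Scree-style plot of program support sizes and explained pool variance
#'
#' @param dict A [pvd_fit()] dictionary.
#' @return A ggplot object.
#' @export
plot_program_summary <- function(dict) {
  stopifnot(inherits(dict, "program_dictionary"))
  df <- tibble::tibble(
    program = seq_along(dict$support),
    support = lengths(dict$support),
    explained = dict$explained
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$program)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$support / max(.data$support) *
                                      max(.data$explained)),
                       color = "#B2182B") +
    ggplot2::labs(x = "program (by explained pool variance)",
                  y = "explained pool variance share") +
    ggplot2::theme_minimal()
}
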