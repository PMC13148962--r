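#' Evaluate a fit against external cell annotations
#'
#' Computes, from a fitted model and a per-cell label table: (i) cohort
#' purity and dominant labels, (ii) the 1-D discriminant AUROC of each cohort
#' distance metric for predicting shared labels between cohort pairs,
#' (iii) case-control scores per case label against a designated control
#' label, and (iv) per-program Spearman time correlations plus the Hedges' g
#' of the best time-correlated program between the earliest and latest time
#' point, when a time covariate is supplied. Labels are joined by cell id, so
#' row order in the label table is irrelevant.
#'
#' @param fit A [sceodesic()] fit.
#' @param cell_data A data frame with a `cell_id` column matching the fit's
#'   cells, a `label` column, and optionally a `time` column (ordinal).
#' @param Xnorm The normalized cell-by-gene matrix restricted to the fit's
#'   variable genes (rows matching the fit's cells). Required for the
#'   metric-based statistics.
#' @param control_label Label treated as the control condition for
#'   case-control scores (default: no case-control block).
#' @param purity Minimum dominant-label fraction for a cohort to enter the
#'   AUROC comparison (default 0.9).
#' @param metrics Cohort distance metrics to evaluate.
#' @param n_partitions Control halvings for the intra distance.
#' @param seed Integer seed.
#' @return A tibble in long form: columns `statistic`, `metric`, `group`,
#'   `program`, `value`, `detail`.
#' @export
evaluate_fit <- function(fit, cell_data, Xnorm, control_label = NULL,
                         purity = 0.9, metrics = c("mean", "cov", "logcov"),
                         n_partitions = 100, seed = 1L) {
  stopifnot(inherits(fit, "sceodesic_fit"))
  cell_data <- tibble::as_tibble(cell_data)
  if (!all(c("cell_id", "label") %in% names(cell_data))) {
    abort("`cell_data` needs columns `cell_id` and `label`.",
          class = "sceodesic_validation_error")
  }
  ids <- rownames(fit$cell_matrix)
  missing <- setdiff(ids, cell_data$cell_id)
  if (length(missing)) {
    abort(paste0("Labels missing for cell(s): ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5)),
          class = "sceodesic_validation_error")
  }
  cell_data <- cell_data[match(ids, cell_data$cell_id), ]
  Xnorm <- as_dense_matrix(Xnorm)
  if (nrow(Xnorm) != length(ids)) {
    abort("`Xnorm` must have one row per fitted cell.",
          class = "sceodesic_validation_error")
  }
  M <- fit$config$M
  out <- list()

  # cohort purity and dominant labels
  assignment <- fit$cohorts$assignment
  n <- fit$cohorts$n_cohorts
  dominant <- character(n); pur <- numeric(n)
  for (k in seq_len(n)) {
    tab <- sort(table(cell_data$label[assignment == k]), decreasing = TRUE)
    dominant[k] <- names(tab)[1]
    pur[k] <- tab[1] / sum(tab)
  }
  out$purity <- tibble::tibble(statistic = "cohort_purity", metric = NA_character_,
                               group = as.character(seq_len(n)),
                               program = NA_character_, value = pur,
                               detail = dominant)

  # pairwise-cohort AUROC per metric, restricted to pure cohorts
  keep <- which(pur >= purity)
  if (length(keep) >= 2 && length(unique(dominant[keep])) >= 2) {
    summaries <- lapply(keep, function(k) {
      summarize_cohort(Xnorm[assignment == k, , drop = FALSE], M = M,
                       label = dominant[k])
    })
    pairs <- utils::combn(length(keep), 2)
    same <- dominant[keep[pairs[1, ]]] == dominant[keep[pairs[2, ]]]
    if (any(same) && any(!same)) {
      for (m in metrics) {
        d <- vapply(seq_len(ncol(pairs)), function(i) {
          cohort_distance(summaries[[pairs[1, i]]], summaries[[pairs[2, i]]], m)
        }, numeric(1))
        out[[paste0("auroc_", m)]] <- tibble::tibble(
          statistic = "auroc", metric = m, group = NA_character_,
          program = NA_character_, value = discriminant_auroc(d, same),
          detail = sprintf("%d cohort pairs, purity >= %g", ncol(pairs), purity))
      }
    }
  }

  # case-control scores per case label against the control label
  if (!is.null(control_label)) {
    if (!control_label %in% cell_data$label) {
      abort(sprintf("Control label '%s' not present.", control_label),
            class = "sceodesic_validation_error")
    }
    control <- Xnorm[cell_data$label == control_label, , drop = FALSE]
    for (lab in setdiff(unique(cell_data$label), control_label)) {
      case <- Xnorm[cell_data$label == lab, , drop = FALSE]
      for (m in metrics) {
        sc <- case_control_score(case, control, metric = m,
                                 n_partitions = n_partitions, M = M,
                                 seed = seed)
        out[[paste0("cc_", lab, "_", m)]] <- tibble::tibble(
          statistic = "case_control_score", metric = m, group = lab,
          program = NA_character_, value = sc$score,
          detail = sprintf("inter %.4g / intra %.4g", sc$inter, sc$intra))
      }
    }
  }

  # time correlations and effect size of the best program
  if ("time" %in% names(cell_data)) {
    tc <- time_correlation(fit$cell_matrix, cell_data$time)
    out$time <- dplyr::mutate(tc$correlations,
                              statistic = "spearman_time", metric = NA_character_,
                              group = NA_character_, .before = 1) |>
      dplyr::rename(value = "rho") |>
      dplyr::mutate(detail = NA_character_)
    best <- tc$best_program
    tp <- cell_data$time
    first_cells <- fit$cell_matrix[tp == min(tp), best]
    last_cells <- fit$cell_matrix[tp == max(tp), best]
    if (length(first_cells) >= 2 && length(last_cells) >= 2 &&
        (var(first_cells) > 0 || var(last_cells) > 0)) {
      g <- hedges_g(first_cells, last_cells)
      out$effect <- tibble::tibble(
        statistic = "hedges_g", metric = NA_character_, group = NA_character_,
        program = colnames(fit$cell_matrix)[best], value = g$g,
        detail = sprintf("n1 %d, n2 %d, pooled sd %.4g", g$n1, g$n2, g$pooled_sd))
    }
  }
  dplyr::bind_rows(out)
}
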