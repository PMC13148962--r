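#' Evaluation statistics for cell-state separation
#'
#' Statistics used to benchmark coexpression metrics: first- and second-moment
#' distances between cohort summaries, the case-control score (inter-condition
#' distance over intra-control distance), a 1-D distance-threshold AUROC,
#' Spearman correlation of program expression with time, and Hedges' g.
#'
#' @name evaluate
NULL

#' Summarize a group of cells for metric comparison
#'
#' @param X Cell-by-gene matrix (normalized expression) for one group.
#' @param M Target condition number used to normalize the covariance.
#' @param label Optional group label.
#' @return A list of class `cohort_summary` with `mean_vector`, `covariance`
#'   (condition-volume normalized `spd_matrix`), `log_covariance`, `n_cells`,
#'   `label`.
#' @export
summarize_cohort <- function(X, M = 50, label = NULL) {
  X <- as_dense_matrix(X)
  if (nrow(X) < 2) {
    abort("Need at least 2 cells to summarize a cohort.",
          class = "sceodesic_validation_error")
  }
  st <- condition_volume_normalize(cov(X), M = M)
  lg <- st$eigenvectors %*% (log(st$eigenvalues) * t(st$eigenvectors))
  structure(
    list(mean_vector = colMeans(X), covariance = st,
         log_covariance = (lg + t(lg)) / 2,
         n_cells = nrow(X), label = label),
    class = "cohort_summary"
  )
}

#' Distance between two cohort summaries
#'
#' `metric = "mean"` is the Euclidean distance of mean expression vectors
#' (d_mu); `"cov"` the Frobenius distance of normalized covariance matrices
#' (d_Sigma); `"logcov"` the log-Euclidean distance (d_logSigma).
#'
#' @param a,b [summarize_cohort()] results.
#' @param metric One of `"mean"`, `"cov"`, `"logcov"`.
#' @return A nonnegative scalar.
#' @export
cohort_distance <- function(a, b, metric = c("mean", "cov", "logcov")) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "cohort_summary"), inherits(b, "cohort_summary"))
  if (length(a$mean_vector) != length(b$mean_vector)) {
    abort("Summaries have different gene dimensions.",
          class = "sceodesic_validation_error")
  }
  switch(metric,
    mean = sqrt(sum((a$mean_vector - b$mean_vector)^2)),
    cov = norm(a$covariance$values - b$covariance$values, type = "F"),
    logcov = norm(a$log_covariance - b$log_covariance, type = "F")
  )
}

#' Case-control score of a metric
#'
#' The ratio of the inter-condition distance (case summary vs. the full
#' control summary) to the intra-condition distance (the mean, over random
#' equal halvings of the control group, of the distance between the two
#' half-summaries). Larger scores mean the metric separates the conditions
#' better than its own sampling noise.
#'
#' @param case_cells,control_cells Cell-by-gene matrices (normalized
#'   expression) for the two conditions.
#' @param metric Passed to [cohort_distance()].
#' @param n_partitions Number of random halvings of the control group used to
#'   estimate the intra distance (1000 matches the original protocol; smaller
#'   values are adequate at desk scale).
#' @param M Condition number target for the covariance summaries.
#' @param seed Integer seed for the halvings.
#' @return A tibble with one row: `metric`, `inter`, `intra`, `score`,
#'   `intra_se` (partition standard error), `n_partitions`, `seed`.
#' @export
case_control_score <- function(case_cells, control_cells,
                               metric = c("mean", "cov", "logcov"),
                               n_partitions = 1000, M = 50, seed = 1L) {
  metric <- match.arg(metric)
  case_cells <- as_dense_matrix(case_cells)
  control_cells <- as_dense_matrix(control_cells)
  if (nrow(control_cells) < 4) {
    abort("Control group must have at least 4 cells to halve.",
          class = "sceodesic_validation_error")
  }
  assert_scalar_number(n_partitions, "n_partitions", lower = 1)
  # light-weight summary: only the pieces the chosen metric needs
  summarize_for <- function(X) {
    if (metric == "mean") return(list(mean = colMeans(X)))
    st <- condition_volume_normalize(cov(X), M = M)
    if (metric == "cov") return(list(cov = st$values))
    lg <- st$eigenvectors %*% (log(st$eigenvalues) * t(st$eigenvectors))
    list(logcov = (lg + t(lg)) / 2)
  }
  dist_for <- function(a, b) {
    if (metric == "mean") sqrt(sum((a$mean - b$mean)^2))
    else norm(a[[metric]] - b[[metric]], type = "F")
  }
  inter <- dist_for(summarize_for(case_cells), summarize_for(control_cells))
  n <- nrow(control_cells)
  half <- n %/% 2
  intra_draws <- with_seed(substream_seed(seed, "partitions"), {
    vapply(seq_len(n_partitions), function(i) {
      idx <- sample.int(n, half)
      dist_for(summarize_for(control_cells[idx, , drop = FALSE]),
               summarize_for(control_cells[-idx, , drop = FALSE]))
    }, numeric(1))
  })
  intra <- mean(intra_draws)
  if (intra <= 0) {
    abort("Degenerate control group: intra-condition distance is zero.",
          class = "sceodesic_validation_error")
  }
  tibble::tibble(
    metric = metric,
    inter = inter,
    intra = intra,
    score = inter / intra,
    intra_se = sd(intra_draws) / sqrt(n_partitions),
    n_partitions = as.integer(n_partitions),
    seed = as.integer(seed)
  )
}

#' AUROC of a 1-D distance-threshold discriminant
#'
#' Treats "the two cohorts share a label" as the positive class predicted by
#' small distance, and computes the area under the ROC curve by the
#' rank (Mann-Whitney) formulation; ties contribute half credit. The result
#' is invariant under any strictly monotone transform of the distances.
#'
#' @param distances Numeric vector of pairwise cohort distances.
#' @param same_label Logical vector: do the two cohorts in the pair share a
#'   label?
#' @return AUROC in `[0, 1]`.
#' @export
discriminant_auroc <- function(distances, same_label) {
  if (length(distances) != length(same_label)) {
    abort("`distances` and `same_label` must have equal length.",
          class = "sceodesic_validation_error")
  }
  same_label <- as.logical(same_label)
  n_pos <- sum(same_label)
  n_neg <- sum(!same_label)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Both classes (same-label and different-label pairs) must be present.",
          class = "sceodesic_validation_error")
  }
  # score = -distance predicts the positive class
  r <- rank(-distances, ties.method = "average")
  (sum(r[same_label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hedges' g standardized effect size
#'
#' `|mean1 - mean2| / s*` with pooled standard deviation
#' `s* = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` (sample variances
#' with denominator n-1). The absolute value is reported because program
#' expression is arbitrary up to sign.
#'
#' @param group1,group2 Numeric vectors of program expression (each length
#'   >= 2).
#' @return A tibble with `g`, `n1`, `n2`, `pooled_sd`.
#' @export
hedges_g <- function(group1, group2) {
  group1 <- as.numeric(group1); group2 <- as.numeric(group2)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) {
    abort("Both groups need at least 2 observations.",
          class = "sceodesic_validation_error")
  }
  s_star <- sqrt(((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) /
                   (n1 + n2 - 2))
  if (s_star <= 0) {
    abort("Pooled standard deviation is zero; effect size undefined.",
          class = "sceodesic_validation_error")
  }
  tibble::tibble(
    g = abs(mean(group1) - mean(group2)) / s_star,
    n1 = n1, n2 = n2, pooled_sd = s_star
  )
}

#' Spearman correlation of program expression with time
#'
#' Per-program Spearman rank correlation between an ordinal time covariate
#' and program expression, plus the program maximizing `|rho|`. Constant
#' program columns get `rho = 0` with a warning.
#'
#' @param program_expr `N x h` cell-by-program matrix (or data frame).
#' @param time_points Length-`N` ordinal/numeric time covariate.
#' @return A list with `correlations` (a tibble: `program`, `rho`) and
#'   `best_program` (index maximizing `|rho|`).
#' @export
time_correlation <- function(program_expr, time_points) {
  program_expr <- as_dense_matrix(program_expr)
  tp <- as.numeric(time_points)
  if (length(tp) != nrow(program_expr)) {
    abort("`time_points` must have one entry per cell.",
          class = "sceodesic_validation_error")
  }
  if (length(unique(tp)) < 2) {
    abort("Need at least 2 distinct time points.",
          class = "sceodesic_validation_error")
  }
  rho <- vapply(seq_len(ncol(program_expr)), function(j) {
    v <- program_expr[, j]
    if (var(v) == 0) {
      warn(sprintf("Program %d is constant; recording rho = 0.", j))
      return(0)
    }
    cor(tp, v, method = "spearman")
  }, numeric(1))
  nm <- colnames(program_expr) %||% paste0("program_", seq_along(rho))
  list(
    correlations = tibble::tibble(program = nm, rho = rho),
    best_program = which.max(abs(rho))
  )
}
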