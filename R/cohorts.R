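#' Cell cohort construction and per-cohort covariance estimation
#'
#' Cells with similar transcriptional profiles are grouped into cohorts (cell
#' states); each cohort contributes one locally estimated, condition-volume
#' normalized gene covariance matrix. Balanced cohorts matter: very small
#' cohorts force heavy regularization that distorts the covariance spectrum.
#'
#' @name cohorts
NULL

#' Median-library count normalization followed by log1p
#'
#' Scales every cell's counts to the median library size of the dataset, then
#' applies `log1p`. Cells with zero total counts are dropped with a warning.
#'
#' @param X Cell-by-gene count matrix (dense or sparse), optionally with
#'   dimnames giving cell and gene identifiers.
#' @return A dense numeric matrix of log-normalized expression, same dimnames,
#'   possibly fewer rows if all-zero cells were removed.
#' @export
normalize_counts <- function(X) {
  X <- as_dense_matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) {
    abort("Empty count matrix.", class = "sceodesic_validation_error")
  }
  if (min(X) < 0) {
    abort("Counts must be nonnegative.", class = "sceodesic_validation_error")
  }
  lib <- rowSums(X)
  if (any(lib == 0)) {
    warn(sprintf("Dropping %d cell(s) with zero total counts.", sum(lib == 0)))
    X <- X[lib > 0, , drop = FALSE]
    lib <- lib[lib > 0]
    if (nrow(X) == 0L) {
      abort("All cells had zero total counts.", class = "sceodesic_validation_error")
    }
  }
  med <- stats::median(lib)
  log1p(X * (med / lib))
}

#' Select highly variable genes by cross-cluster dispersion
#'
#' Cells are coarsely pre-clustered with k-means; per cluster and gene the
#' dispersion (variance / mean) is computed. Genes are ranked by the fraction
#' of clusters in which their dispersion exceeds that cluster's 75th
#' percentile dispersion -- "high dispersion across a large proportion of
#' clusters" -- with ties broken by mean dispersion, and the top `h` are kept.
#'
#' @param Xnorm Normalized cell-by-gene matrix (see [normalize_counts()]).
#' @param h Number of variable genes to keep.
#' @param k_pre Number of coarse pre-clusters (default `max(10, nrow/1000)`,
#'   capped by the number of cells).
#' @param seed Integer seed for the k-means initialization.
#' @return A list of class `hvg_selection`: `selected_indices` (length `h`),
#'   `h`, `ranking` (a tibble with per-gene score and mean dispersion), and
#'   `per_cluster_dispersion` (genes x clusters matrix).
#' @export
select_variable_genes <- function(Xnorm, h, k_pre = NULL, seed = 1L) {
  Xnorm <- as_dense_matrix(Xnorm)
  G <- ncol(Xnorm); N <- nrow(Xnorm)
  assert_scalar_number(h, "h", lower = 1, upper = G)
  if (is.null(k_pre)) k_pre <- max(10, round(N / 1000))
  k_pre <- max(1L, min(as.integer(k_pre), N))
  cl <- if (k_pre == 1L) rep(1L, N) else {
    with_seed(substream_seed(seed, "hvg_kmeans"),
              kmeans(Xnorm, centers = k_pre, nstart = 5, iter.max = 50)$cluster)
  }
  k_eff <- length(unique(cl))
  disp <- matrix(0, nrow = G, ncol = k_eff)
  for (j in seq_len(k_eff)) {
    sub <- Xnorm[cl == sort(unique(cl))[j], , drop = FALSE]
    mu <- colMeans(sub)
    v <- apply(sub, 2, var)
    d <- ifelse(mu > 0, v / mu, 0)
    disp[, j] <- ifelse(is.finite(d), d, 0)
  }
  # fraction of clusters where the gene clears that cluster's 75th percentile
  thresh <- apply(disp, 2, quantile, probs = 0.75, names = FALSE)
  above <- sweep(disp, 2, thresh, ">")
  score <- rowMeans(above)
  mean_disp <- rowMeans(disp)
  nonzero_var <- apply(Xnorm, 2, var) > 0
  if (sum(nonzero_var) < h) {
    abort(sprintf(
      "Requested h = %d variable genes but only %d genes have nonzero variance (deficit %d).",
      h, sum(nonzero_var), h - sum(nonzero_var)),
      class = "sceodesic_validation_error")
  }
  ord <- order(-score, -mean_disp, seq_len(G))
  ord <- ord[nonzero_var[ord]]
  sel <- sort(ord[seq_len(h)])
  gene_ids <- colnames(Xnorm) %||% as.character(seq_len(G))
  structure(
    list(selected_indices = sel,
         h = as.integer(h),
         ranking = tibble::tibble(gene = gene_ids, index = seq_len(G),
                                  score = score, mean_dispersion = mean_disp,
                                  selected = seq_len(G) %in% sel),
         per_cluster_dispersion = disp),
    class = "hvg_selection"
  )
}

# Diagonal-covariance Gaussian mixture fitted by EM, kmeans-initialized, with
# ridge `gamma` added to every component variance (keeps components proper when
# a cluster collapses onto sparse expression). Returns hard argmax labels plus
# the responsibility matrix.
fit_diagonal_gmm <- function(X, n, gamma = 0.01, seed = 1L, max_iter = 100L,
                             tol = 1e-6) {
  N <- nrow(X); P <- ncol(X)
  km <- with_seed(substream_seed(seed, "gmm_init"),
                  kmeans(X, centers = n, nstart = 3, iter.max = 50))
  z <- km$cluster
  pi_k <- tabulate(z, n) / N
  mu <- km$centers
  sig2 <- matrix(0, n, P)
  for (k in seq_len(n)) {
    sub <- X[z == k, , drop = FALSE]
    sig2[k, ] <- (if (nrow(sub) > 1) apply(sub, 2, var) else rep(0, P)) + gamma
  }
  loglik_old <- -Inf
  R <- NULL
  for (it in seq_len(max_iter)) {
    logp <- matrix(0, N, n)
    for (k in seq_len(n)) {
      logp[, k] <- log(pmax(pi_k[k], 1e-300)) -
        0.5 * sum(log(2 * pi * sig2[k, ])) -
        0.5 * colSums((t(X) - mu[k, ])^2 / sig2[k, ])
    }
    m <- apply(logp, 1, max)
    R <- exp(logp - m)
    rs <- rowSums(R)
    loglik <- sum(m + log(rs))
    R <- R / rs
    Nk <- colSums(R)
    pi_k <- Nk / N
    keep <- Nk > 1e-8
    for (k in which(keep)) {
      mu[k, ] <- colSums(R[, k] * X) / Nk[k]
      sig2[k, ] <- colSums(R[, k] * t(t(X) - mu[k, ])^2) / Nk[k] + gamma
    }
    if (abs(loglik - loglik_old) < tol * (1 + abs(loglik))) break
    loglik_old <- loglik
  }
  list(assignment = max.col(R, ties.method = "first"),
       responsibilities = R, means = mu, variances = sig2, weights = pi_k)
}

#' Partition cells into cohorts
#'
#' Groups cells into `n` cohorts by a diagonal-covariance Gaussian mixture
#' (default; hard labels by argmax responsibility), k-means, or user-supplied
#' labels. Empty cohorts are dropped (with a message) and indices compacted.
#'
#' @param Xnorm Normalized cell-by-gene matrix restricted to variable genes.
#' @param n Number of cohorts. The usual guidance is `n = N / h` so a typical
#'   cohort is just large enough to yield a non-singular covariance.
#' @param method One of `"gmm"`, `"kmeans"`, `"provided"`.
#' @param labels Required when `method = "provided"`: a vector of length
#'   `nrow(Xnorm)` of cohort labels (any type; factorized internally).
#' @param gamma Diagonal ridge added to GMM component variances (default 0.01).
#' @param seed Integer seed.
#' @return A list of class `cohort_model`: `assignment` (1-based integers),
#'   `n_cohorts`, `method`, `responsibilities` (GMM only), `sizes`, `seed`.
#' @export
build_cohorts <- function(Xnorm, n, method = c("gmm", "kmeans", "provided"),
                          labels = NULL, gamma = 0.01, seed = 1L) {
  method <- match.arg(method)
  Xnorm <- as_dense_matrix(Xnorm)
  N <- nrow(Xnorm)
  resp <- NULL
  if (method == "provided") {
    if (is.null(labels)) {
      abort("method = \"provided\" requires `labels`.",
            class = "sceodesic_validation_error")
    }
    if (length(labels) != N) {
      abort(sprintf("`labels` has length %d but there are %d cells.",
                    length(labels), N),
            class = "sceodesic_validation_error")
    }
    assignment <- as.integer(factor(labels))
  } else {
    assert_scalar_number(n, "n", lower = 1, upper = N)
    n <- as.integer(n)
    if (n == 1L) {
      assignment <- rep(1L, N)
    } else if (method == "kmeans") {
      assignment <- with_seed(substream_seed(seed, "cohort_kmeans"),
                              kmeans(Xnorm, centers = n, nstart = 3,
                                     iter.max = 50)$cluster)
    } else {
      fit <- fit_diagonal_gmm(Xnorm, n, gamma = gamma, seed = seed)
      assignment <- fit$assignment
      resp <- fit$responsibilities
    }
  }
  present <- sort(unique(assignment))
  if (length(present) < max(assignment)) {
    inform(sprintf("Dropping %d empty cohort(s); n reduced to %d.",
                   max(assignment) - length(present), length(present)))
  }
  assignment <- match(assignment, present)
  if (!is.null(resp)) resp <- resp[, present, drop = FALSE]
  sizes <- tabulate(assignment, length(present))
  h <- ncol(Xnorm)
  if (min(sizes) < h / 4) {
    warn(sprintf(
      "Smallest cohort has %d cells (< h/4 = %.0f); covariance estimates will be heavily regularized.",
      min(sizes), h / 4))
  }
  structure(
    list(assignment = assignment,
         n_cohorts = length(present),
         method = method,
         responsibilities = resp,
         sizes = sizes,
         seed = as.integer(seed)),
    class = "cohort_model"
  )
}

#' @export
print.cohort_model <- function(x, ...) {
  cat(sprintf("<cohort_model> %d cells in %d cohorts (%s); sizes %d-%d\n",
              length(x$assignment), x$n_cohorts, x$method,
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Per-cohort normalized covariance matrices
#'
#' For each cohort, computes the sample covariance (denominator `n - 1`) of
#' the normalized expression of its cells, condition-volume normalizes it, and
#' caches its matrix logarithm. Cohorts with fewer than 2 cells are merged
#' into the cohort with the nearest centroid first.
#'
#' @param Xnorm Normalized cell-by-gene matrix restricted to variable genes.
#' @param model A [build_cohorts()] result.
#' @param M Target condition number for normalization.
#' @return A list of class `cohort_covariances`: per cohort a list with
#'   `sigma` (raw sample covariance), `sigma_tilde` (`spd_matrix`),
#'   `log_sigma`, `n_cells`; plus the (possibly updated) `model`.
#' @export
cohort_covariances <- function(Xnorm, model, M = 50) {
  Xnorm <- as_dense_matrix(Xnorm)
  stopifnot(inherits(model, "cohort_model"))
  assignment <- model$assignment
  if (length(assignment) != nrow(Xnorm)) {
    abort("Cohort model and matrix disagree on the number of cells.",
          class = "sceodesic_validation_error")
  }
  sizes <- tabulate(assignment, model$n_cohorts)
  if (any(sizes < 2)) {
    centroids <- t(vapply(seq_len(model$n_cohorts), function(k) {
      colMeans(Xnorm[assignment == k, , drop = FALSE])
    }, numeric(ncol(Xnorm))))
    small <- which(sizes < 2)
    big <- which(sizes >= 2)
    if (length(big) == 0L) {
      abort("No cohort has >= 2 cells; cannot estimate covariance.",
            class = "sceodesic_validation_error")
    }
    for (k in small) {
      d2 <- rowSums((centroids[big, , drop = FALSE] -
                       matrix(centroids[k, ], length(big), ncol(Xnorm),
                              byrow = TRUE))^2)
      target <- big[which.min(d2)]
      assignment[assignment == k] <- target
    }
    inform(sprintf("Merged %d cohort(s) with < 2 cells into nearest-centroid cohorts.",
                   length(small)))
    present <- sort(unique(assignment))
    assignment <- match(assignment, present)
    model$assignment <- assignment
    model$n_cohorts <- length(present)
    model$sizes <- tabulate(assignment, length(present))
    if (!is.null(model$responsibilities)) {
      model$responsibilities <- model$responsibilities[, present, drop = FALSE]
    }
  }
  covs <- vector("list", model$n_cohorts)
  for (k in seq_len(model$n_cohorts)) {
    sub <- Xnorm[assignment == k, , drop = FALSE]
    sigma <- cov(sub)
    st <- tryCatch(
      condition_volume_normalize(sigma, M = M),
      error = function(e) {
        abort(sprintf("Cohort %d: %s", k, conditionMessage(e)),
              class = class(e)[1], parent = e)
      }
    )
    lg <- st$eigenvectors %*% (log(st$eigenvalues) * t(st$eigenvectors))
    covs[[k]] <- list(sigma = sigma, sigma_tilde = st,
                      log_sigma = (lg + t(lg)) / 2, n_cells = nrow(sub))
  }
  structure(list(covariances = covs, model = model, M = M),
            class = "cohort_covariances")
}

#' @export
print.cohort_covariances <- function(x, ...) {
  cat(sprintf("<cohort_covariances> %d cohorts, %d genes, M = %g\n",
              length(x$covariances),
              nrow(x$covariances[[1]]$sigma), x$M))
  invisible(x)
}
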