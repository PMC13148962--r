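test_that("count normalization scales to the median library and conserves it", {
  # single cell: median library is its own, scaling factor 1
  expect_equal(normalize_counts(matrix(c(2, 0), 1)), matrix(c(log(3), 0), 1))
  # equal library sizes: scaling factor 1 for every cell
  X <- rbind(c(3, 1), c(2, 2), c(0, 4))
  expect_equal(normalize_counts(X), log1p(X))
  # conservation: rows of expm1(output) all sum to the median library
  set.seed(1)
  Y <- matrix(rpois(200 * 30, lambda = 2), 200, 30)
  Y <- Y[rowSums(Y) > 0, ]
  out <- normalize_counts(Y)
  expect_equal(rowSums(expm1(out)), rep(median(rowSums(Y)), nrow(out)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("count normalization drops zero cells and validates input", {
  X <- rbind(c(1, 2), c(0, 0))
  expect_warning(out <- normalize_counts(X), "zero total counts")
  expect_equal(nrow(out), 1L)
  expect_error(normalize_counts(matrix(numeric(), 0, 0)),
               class = "sceodesic_validation_error")
  expect_error(normalize_counts(matrix(c(-1, 2), 1)),
               class = "sceodesic_validation_error")
})

test_that("variable-gene selection recovers planted high-dispersion genes", {
  set.seed(8)
  N <- 300; G <- 50
  X <- matrix(rpois(N * G, lambda = 5), N, G)
  planted <- 1:20
  # overdispersed counts for planted genes: Poisson-gamma mixture
  for (g in planted) X[, g] <- rpois(N, lambda = rgamma(N, shape = 0.3, scale = 20))
  X[, 50] <- 0  # silent gene: zero variance even after normalization
  Xn <- normalize_counts(X)
  sel <- select_variable_genes(Xn, h = 20, k_pre = 5, seed = 2)
  expect_length(sel$selected_indices, 20)
  expect_setequal(sel$selected_indices, planted)
  expect_false(50 %in% sel$selected_indices)
  # h equal to the count of informative genes: constant gene still excluded
  sel_all <- select_variable_genes(Xn, h = 49, k_pre = 5, seed = 2)
  expect_false(50 %in% sel_all$selected_indices)
  expect_error(select_variable_genes(Xn, h = 50, k_pre = 5, seed = 2),
               class = "sceodesic_validation_error")
})

test_that("cohort construction recovers well-separated blobs and partitions cells", {
  set.seed(4)
  n <- 150
  X <- rbind(matrix(rnorm(n * 5, 0), n, 5), matrix(rnorm(n * 5, 20), n, 5))
  truth <- rep(1:2, each = n)
  for (m in c("gmm", "kmeans")) {
    model <- build_cohorts(X, n = 2, method = m, seed = 3)
    expect_equal(mclust::adjustedRandIndex(model$assignment, truth), 1)
    expect_equal(sum(model$sizes), nrow(X))
    expect_length(model$assignment, nrow(X))
  }
  one <- build_cohorts(X, n = 1, method = "gmm", seed = 3)
  expect_equal(unique(one$assignment), 1L)
  prov <- build_cohorts(X, n = 2, method = "provided",
                        labels = rep(c("a", "b"), each = n))
  expect_equal(mclust::adjustedRandIndex(prov$assignment, truth), 1)
  expect_error(build_cohorts(X, n = 2, method = "provided"),
               class = "sceodesic_validation_error")
})

test_that("gmm responsibilities are row-stochastic and deterministic under a seed", {
  set.seed(10)
  X <- matrix(rnorm(400), 100, 4)
  m1 <- suppressWarnings(build_cohorts(X, n = 3, method = "gmm", seed = 7))
  m2 <- suppressWarnings(build_cohorts(X, n = 3, method = "gmm", seed = 7))
  expect_identical(m1$assignment, m2$assignment)
  expect_equal(rowSums(m1$responsibilities),
               rep(1, nrow(X)), tolerance = 1e-6)
})

test_that("small-cohort warning fires when a cohort is below h/4 cells", {
  set.seed(2)
  X <- rbind(matrix(rnorm(3 * 20), 3, 20), matrix(rnorm(100 * 20, 10), 100, 20))
  expect_warning(build_cohorts(X, n = 2, method = "kmeans", seed = 1),
                 "heavily regularized")
})

test_that("cohort covariances match a known diagonal MVN within 10%", {
  set.seed(6)
  vars <- c(16, 8, 4, 2, 1)
  X <- rmvn(5000, rep(0, 5), diag(vars))
  model <- build_cohorts(X, n = 1, method = "kmeans", seed = 1)
  covs <- cohort_covariances(X, model, M = 50)
  ev <- covs$covariances[[1]]$sigma_tilde$eigenvalues
  expect_equal(ev / min(ev), vars / min(vars), tolerance = 0.1)
  expect_lte(max(ev) / min(ev), 50)
})

test_that("degenerate cohorts error with the cohort named; singletons are merged", {
  X <- matrix(1, 10, 3)  # identical cells: zero covariance
  model <- build_cohorts(X + 0, n = 1, method = "provided", labels = rep(1, 10))
  err <- tryCatch(cohort_covariances(X, model), error = identity)
  expect_match(conditionMessage(err), "Cohort 1")
  # a singleton cohort is merged into the nearest-centroid cohort
  set.seed(3)
  Y <- matrix(rnorm(21 * 4), 21, 4)
  model <- build_cohorts(Y, n = 2, method = "provided",
                         labels = c(rep("a", 20), "b"))
  expect_message(covs <- cohort_covariances(Y, model), "Merged")
  expect_equal(length(covs$covariances), 1L)
  expect_equal(covs$model$n_cohorts, 1L)
})

test_that("cohorting pipeline is deterministic given one seed", {
  set.seed(12)
  X <- matrix(rpois(200 * 12, 4), 200, 12)
  run <- function() {
    Xn <- normalize_counts(X)
    model <- build_cohorts(Xn, n = 3, method = "gmm", seed = 5)
    cohort_covariances(Xn, model, M = 50)
  }
  a <- run(); b <- run()
  expect_identical(a$model$assignment, b$model$assignment)
  expect_identical(a$covariances[[1]]$sigma_tilde$values,
                   b$covariances[[1]]$sigma_tilde$values)
})
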