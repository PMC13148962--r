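test_that("cohort distances match closed forms by metric", {
  set.seed(60)
  mu <- rnorm(4)
  S <- random_spd(4)
  a <- make_summary(mu, S)
  for (m in c("mean", "cov", "logcov")) {
    expect_equal(cohort_distance(a, a, m), 0)
  }
  # identical covariances, shifted means: only d_mu responds
  b <- make_summary(mu + 1, S)
  expect_equal(cohort_distance(a, b, "mean"), 2)
  expect_equal(cohort_distance(a, b, "cov"), 0)
  expect_equal(cohort_distance(a, b, "logcov"), 0)
  # commuting (diagonal) case: d_logcov equals the Euclidean distance of
  # log-eigenvalue vectors of the normalized spectra
  d1 <- c(8, 4, 2, 1); d2 <- c(6, 3, 1.5, 1)
  x <- make_summary(rep(0, 4), diag(d1))
  y <- make_summary(rep(0, 4), diag(d2))
  expect_equal(cohort_distance(x, y, "logcov"),
               sqrt(sum((log(d1 / min(d1)) - log(d2 / min(d2)))^2)))
  expect_error(cohort_distance(a, make_summary(rnorm(3), random_spd(3)), "mean"),
               class = "sceodesic_validation_error")
})

test_that("case-control score finds no signal under the null and strong signal for coexpression", {
  set.seed(61)
  h <- 10
  null_case <- rmvn(800, rep(0, h), diag(h))
  null_ctrl <- rmvn(800, rep(0, h), diag(h))
  r <- case_control_score(null_case, null_ctrl, "mean", n_partitions = 50, seed = 2)
  # no separation: the score sits near 1 (inter between full groups vs intra
  # between halves), far from the >> 1 regime of real signal
  expect_lt(r$score, 1.5)
  expect_gt(r$score, 0.3)
  # block-correlated alternative: equal means, covariance I vs rho = 0.8 blocks
  S <- diag(h); S[1:5, 1:5] <- 0.8; diag(S) <- 1
  case <- rmvn(2000, rep(0, h), S)
  ctrl <- rmvn(2000, rep(0, h), diag(h))
  s_log <- case_control_score(case, ctrl, "logcov", n_partitions = 50, seed = 2)
  s_mu <- case_control_score(case, ctrl, "mean", n_partitions = 50, seed = 2)
  expect_gt(s_log$score, s_mu$score)
  expect_gt(s_log$score, 3)
})

test_that("intra estimate is Monte-Carlo stable in the partition count", {
  set.seed(62)
  ctrl <- rmvn(600, rep(0, 6), diag(6))
  case <- rmvn(600, rep(0.5, 6), diag(6))
  r1 <- case_control_score(case, ctrl, "mean", n_partitions = 100, seed = 9)
  r2 <- case_control_score(case, ctrl, "mean", n_partitions = 200, seed = 10)
  expect_lt(abs(r1$intra - r2$intra),
            2 * sqrt(r1$intra_se^2 + r2$intra_se^2) + 1e-12)
})

test_that("mean-metric score is invariant to global expression rescaling", {
  set.seed(63)
  case <- rmvn(300, rep(1, 5), diag(5))
  ctrl <- rmvn(300, rep(0, 5), diag(5))
  r1 <- case_control_score(case, ctrl, "mean", n_partitions = 50, seed = 4)
  r2 <- case_control_score(3 * case, 3 * ctrl, "mean", n_partitions = 50, seed = 4)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
})

test_that("case-control score validates inputs", {
  expect_error(case_control_score(matrix(1, 5, 2), matrix(1, 3, 2), "mean"),
               class = "sceodesic_validation_error")
  # degenerate control: identical cells, zero intra distance
  expect_error(case_control_score(matrix(rnorm(10), 5, 2),
                                  matrix(1, 8, 2), "mean", n_partitions = 5),
               class = "sceodesic_validation_error")
})

test_that("discriminant AUROC matches the O(n^2) concordance oracle", {
  # perfectly separated distances
  expect_equal(discriminant_auroc(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # 6-pair toy with a tie, against brute-force pair counting
  d <- c(1, 3, 2, 3, 5, 4)
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  brute <- 0
  for (i in which(lab)) for (j in which(!lab)) {
    brute <- brute + (d[i] < d[j]) + 0.5 * (d[i] == d[j])
  }
  brute <- brute / (sum(lab) * sum(!lab))
  expect_equal(discriminant_auroc(d, lab), brute)
  # label-independent distances: AUROC near chance
  set.seed(64)
  d <- runif(2000); lab <- runif(2000) > 0.5
  expect_equal(discriminant_auroc(d, lab), 0.5, tolerance = 0.05)
  # invariance under monotone transformation of distances
  expect_equal(discriminant_auroc(exp(d), lab), discriminant_auroc(d, lab))
  expect_error(discriminant_auroc(c(1, 2), c(TRUE, TRUE)),
               class = "sceodesic_validation_error")
})

test_that("Hedges' g matches the pooled-sd formula", {
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3))$g, 0)
  base <- as.numeric(scale(rnorm(10)))  # sample mean 0, sd 1 exactly
  expect_equal(hedges_g(base + 1, base)$g, 1)
  # seeded draws against an independent formula evaluation
  set.seed(65)
  x <- rnorm(17, 2, 1.3); y <- rnorm(23, 1.1, 0.7)
  s_star <- sqrt(((17 - 1) * var(x) + (23 - 1) * var(y)) / (17 + 23 - 2))
  expect_equal(hedges_g(x, y)$g, abs(mean(x) - mean(y)) / s_star)
  expect_equal(hedges_g(x, y)$pooled_sd, s_star)
  expect_error(hedges_g(c(1), c(1, 2)), class = "sceodesic_validation_error")
  expect_error(hedges_g(c(1, 1), c(1, 1)), class = "sceodesic_validation_error")
})

test_that("time correlation matches the rank formula and flags constants", {
  tp <- 1:5
  up <- matrix(tp, ncol = 1)
  expect_equal(time_correlation(up, tp)$correlations$rho, 1)
  expect_equal(time_correlation(-up, tp)$correlations$rho, -1)
  # 5-point toy: ranks (1..5) vs (2,1,4,3,5) -> rho = 1 - 6*4/120 = 0.8
  toy <- matrix(c(2, 1, 4, 3, 5), ncol = 1)
  expect_equal(time_correlation(toy, tp)$correlations$rho, 0.8)
  # best program by |rho|
  m <- cbind(c(2, 1, 4, 3, 5), -tp)
  res <- time_correlation(m, tp)
  expect_equal(res$best_program, 2L)
  expect_warning(res0 <- time_correlation(cbind(rep(1, 5)), tp), "constant")
  expect_equal(res0$correlations$rho, 0)
  expect_error(time_correlation(up, rep(1, 5)),
               class = "sceodesic_validation_error")
})
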