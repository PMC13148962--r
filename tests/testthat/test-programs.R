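test_that("local program collection honours the cumulative-variance rule", {
  covs <- as_cohort_covs(list(diag(c(9, 1))))
  # normalized eigenvalues (9, 1): one vector explains 9/10 >= 0.9
  one <- collect_local_programs(covs, v_pvd = 0.9)
  expect_equal(ncol(one[[1]]$vectors), 1L)
  all_vec <- collect_local_programs(covs, v_pvd = 1)
  expect_equal(ncol(all_vec[[1]]$vectors), 2L)
  # pooled columns are the sum of per-cohort retained counts
  set.seed(31)
  covs3 <- as_cohort_covs(replicate(3, random_spd(5, 0.5, 8), simplify = FALSE))
  loc <- collect_local_programs(covs3, v_pvd = 0.8)
  pool <- do.call(cbind, lapply(loc, `[[`, "vectors"))
  expect_equal(ncol(pool), sum(vapply(loc, function(l) ncol(l$vectors), 1L)))
  # unit-norm columns, sign convention: largest-magnitude entry positive
  expect_equal(colSums(pool^2), rep(1, ncol(pool)), ignore_attr = TRUE)
  for (j in seq_len(ncol(pool))) expect_gt(pool[which.max(abs(pool[, j])), j], 0)
})

test_that("dense PVD (lambda = 0) equals second-moment PCA of the pool", {
  set.seed(40)
  # crafted pool with well-separated singular values so PCA columns are
  # identifiable up to sign
  h <- 6
  Q <- random_orthonormal(h)
  O <- random_orthonormal(10)[, 1:h]
  P <- Q %*% (c(6, 4, 2.5, 1.6, 1, 0.6) * t(O))
  dict <- pvd_fit(P, h = h, lambda = 0)
  # independent oracle: eigenvectors of the pool's uncentered second moment
  oracle <- eigen(P %*% t(P), symmetric = TRUE)$vectors
  for (j in 1:h) {
    v <- dict$programs[, j]; w <- oracle[, j]
    expect_lt(min(sum((v - w)^2), sum((v + w)^2)), 1e-10)
  }
  # on generic cohort pools the spanned subspace agrees even when close
  # eigenvalues make individual columns non-identifiable
  covs <- as_cohort_covs(replicate(4, random_spd(6, 0.5, 6), simplify = FALSE))
  loc <- collect_local_programs(covs, v_pvd = 0.9)
  d2 <- pvd_fit(loc, h = 4, lambda = 0)
  Pl <- do.call(cbind, lapply(loc, `[[`, "vectors"))
  or2 <- eigen(Pl %*% t(Pl), symmetric = TRUE)$vectors[, 1:4]
  expect_equal(svd(t(d2$programs) %*% or2)$d, rep(1, 4), tolerance = 1e-8)
})

test_that("single cohort at full variance spans its own eigenbasis", {
  set.seed(41)
  S <- random_spd(5, 0.5, 5)
  covs <- as_cohort_covs(list(S))
  loc <- collect_local_programs(covs, v_pvd = 1)
  dict <- pvd_fit(loc, h = 5, lambda = 0)
  U1 <- covs$covariances[[1]]$sigma_tilde$eigenvectors
  # principal angles between span(U_hat) and span(U_1) are all ~0
  sv <- svd(t(dict$programs) %*% U1)$d
  expect_equal(sv, rep(1, 5), tolerance = 1e-8)
})

test_that("duplicated cohorts recover the shared leading eigenvector", {
  set.seed(42)
  Q <- random_orthonormal(6)
  S <- Q %*% (c(40, 3, 2.5, 2, 1.5, 1) * t(Q))
  covs <- as_cohort_covs(replicate(5, S, simplify = FALSE))
  loc <- collect_local_programs(covs, v_pvd = 0.7)  # dominant vector only
  expect_true(all(vapply(loc, function(l) ncol(l$vectors), 1L) == 1L))
  dict <- pvd_fit(loc, h = 1, lambda = 0)
  lead <- covs$covariances[[1]]$sigma_tilde$eigenvectors[, 1]
  expect_lt(min(sum((dict$programs[, 1] - lead)^2),
                sum((dict$programs[, 1] + lead)^2)), 1e-10)
})

test_that("program support is monotone nonincreasing in the sparsity penalty", {
  set.seed(43)
  covs <- as_cohort_covs(replicate(6, random_spd(8, 0.5, 8), simplify = FALSE))
  loc <- collect_local_programs(covs, v_pvd = 0.9)
  supports <- vapply(c(0, 0.1, 0.3, 0.5, 0.7), function(lam) {
    d <- pvd_fit(loc, h = 3, lambda = lam)
    sum(lengths(d$support))
  }, numeric(1))
  expect_true(all(diff(supports) <= 0))
})

test_that("planted coexpression blocks are recovered with high support overlap", {
  set.seed(44)
  h <- 25
  block1 <- 1:10; block2 <- 11:20
  make_block_cov <- function(idx, rho) {
    S <- diag(h)
    S[idx, idx] <- rho
    diag(S) <- 1
    S
  }
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  scores <- replicate(10, {
    mats <- lapply(1:6, function(i) {
      w1 <- runif(1, 0.5, 0.9); w2 <- runif(1, 0.5, 0.9)
      X <- rmvn(400, rep(0, h),
                make_block_cov(block1, w1) + make_block_cov(block2, w2) - diag(h))
      cov(X)
    })
    loc <- collect_local_programs(as_cohort_covs(mats), v_pvd = 0.5)
    dict <- pvd_fit(loc, h = 4, lambda = 0.35)
    c(max(vapply(dict$support, jacc, numeric(1), b = block1)),
      max(vapply(dict$support, jacc, numeric(1), b = block2)))
  })
  expect_gte(mean(scores[1, ]), 0.8)
  expect_gte(mean(scores[2, ]), 0.8)
})

test_that("pvd_fit validates pool size and pads rank-deficient pools", {
  set.seed(45)
  covs <- as_cohort_covs(list(diag(c(9, 1))))
  loc <- collect_local_programs(covs, v_pvd = 0.9)  # one pooled vector
  expect_error(pvd_fit(loc, h = 2, lambda = 0),
               class = "sceodesic_validation_error")
  # rank-1 pool of two identical columns requested at h = 2: zero padding
  P <- cbind(c(1, 0), c(1, 0))
  expect_warning(dict <- pvd_fit(P, h = 2, lambda = 0), "zero-padded")
  expect_equal(dict$programs[, 2], c(0, 0), ignore_attr = TRUE)
})
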