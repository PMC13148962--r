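# Shared fixture builders. All randomness is locally seeded.

# Random SPD matrix with log-uniform eigenvalues in [lo, hi].
random_spd <- function(h, lo = 0.1, hi = 10) {
  Q <- qr.Q(qr(matrix(rnorm(h * h), h)))
  lam <- exp(runif(h, log(lo), log(hi)))
  S <- Q %*% (lam * t(Q))
  (S + t(S)) / 2
}

# Random PSD matrix; with probability p_sing some eigenvalues are exactly 0.
random_psd <- function(h, p_sing = 0.3) {
  Q <- qr.Q(qr(matrix(rnorm(h * h), h)))
  lam <- exp(runif(h, log(0.01), log(10)))
  if (runif(1) < p_sing) lam[sample.int(h, 1)] <- 0
  S <- Q %*% (lam * t(Q))
  (S + t(S)) / 2
}

# Random orthonormal matrix.
random_orthonormal <- function(h) qr.Q(qr(matrix(rnorm(h * h), h)))

# Wrap a list of normalized covariance matrices as a cohort_covariances
# object (bypassing cells) for program-level tests.
as_cohort_covs <- function(mats, M = 50) {
  covs <- lapply(mats, function(S) {
    st <- condition_volume_normalize(S, M = M)
    lg <- st$eigenvectors %*% (log(st$eigenvalues) * t(st$eigenvectors))
    list(sigma = S, sigma_tilde = st, log_sigma = (lg + t(lg)) / 2,
         n_cells = NA_integer_)
  })
  structure(list(covariances = covs, model = NULL, M = M),
            class = "cohort_covariances")
}

# Build a cohort_summary directly from a mean vector and covariance matrix.
make_summary <- function(mu, S, M = 50) {
  st <- condition_volume_normalize(S, M = M)
  lg <- st$eigenvectors %*% (log(st$eigenvalues) * t(st$eigenvectors))
  structure(list(mean_vector = mu, covariance = st,
                 log_covariance = (lg + t(lg)) / 2,
                 n_cells = NA_integer_, label = NULL),
            class = "cohort_summary")
}

# Sample n cells from MVN(mu, S) (Cholesky).
rmvn <- function(n, mu, S) {
  h <- length(mu)
  Z <- matrix(rnorm(n * h), n, h)
  sweep(Z %*% chol(S), 2, mu, "+")
}
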