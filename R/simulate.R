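#' Synthetic scRNA-seq with known regulatory structure
#'
#' A compact gene-regulatory-network simulator in the chemical-Langevin
#' tradition: master regulator genes have basal production; downstream genes
#' respond to regulator levels through Hill functions; expression evolves by
#' Euler-Maruyama integration of
#' `dx = (production(x) - decay * x) dt + amp * sqrt(production + decay * x) dW`,
#' cells are sampled at steady state, and observed counts are Poisson draws of
#' the steady-state levels. [build_two_type_grn()] emulates the benchmark
#' design of two cell types with matched mean expression but distinct
#' gene-gene coexpression induced by differentially wired master regulators.
#'
#' @name simulate
NULL

#' Construct a gene regulatory network specification
#'
#' @param n_genes Number of genes.
#' @param basal Length-`n_genes` basal production rates.
#' @param edges Data frame with columns `regulator`, `target`, `strength`,
#'   `hill_k` (Hill coefficient >= 1), `half_sat` (half-saturation level).
#'   The regulator -> target graph must be acyclic.
#' @param decay Per-gene decay rates (scalar recycled).
#' @param noise_amplitude Per-gene Langevin noise scales (scalar recycled).
#' @return A list of class `grn_spec`.
#' @export
grn_spec <- function(n_genes, basal, edges = NULL, decay = 0.8,
                     noise_amplitude = 1) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  n_genes <- as.integer(n_genes)
  basal <- rep_len(as.numeric(basal), n_genes)
  decay <- rep_len(as.numeric(decay), n_genes)
  noise_amplitude <- rep_len(as.numeric(noise_amplitude), n_genes)
  if (any(basal < 0) || any(decay <= 0) || any(noise_amplitude < 0)) {
    abort("Basal rates must be >= 0, decay > 0, noise amplitudes >= 0.",
          class = "sceodesic_validation_error")
  }
  if (is.null(edges)) {
    edges <- tibble::tibble(regulator = integer(), target = integer(),
                            strength = numeric(), hill_k = numeric(),
                            half_sat = numeric())
  }
  edges <- tibble::as_tibble(edges)
  needed <- c("regulator", "target", "strength", "hill_k", "half_sat")
  if (!all(needed %in% names(edges))) {
    abort(paste0("`edges` needs columns: ", paste(needed, collapse = ", "), "."),
          class = "sceodesic_validation_error")
  }
  if (nrow(edges)) {
    if (any(edges$hill_k < 1)) {
      abort("Hill coefficients must be >= 1.", class = "sceodesic_validation_error")
    }
    if (any(edges$regulator < 1) || any(edges$regulator > n_genes) ||
        any(edges$target < 1) || any(edges$target > n_genes)) {
      abort("Edge endpoints out of gene range.",
            class = "sceodesic_validation_error")
    }
    # acyclicity by Kahn's algorithm on the regulator -> target graph
    indeg <- tabulate(edges$target, n_genes)
    queue <- which(indeg == 0)
    seen <- 0L
    indeg_work <- indeg
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      outs <- edges$target[edges$regulator == v]
      for (w in outs) {
        indeg_work[w] <- indeg_work[w] - 1L
        if (indeg_work[w] == 0L) queue <- c(queue, w)
      }
    }
    if (seen < n_genes) {
      abort("Regulator -> target graph has a cycle.",
            class = "sceodesic_validation_error")
    }
  }
  structure(list(n_genes = n_genes, basal = basal, edges = edges,
                 decay = decay, noise_amplitude = noise_amplitude),
            class = "grn_spec")
}

#' @export
print.grn_spec <- function(x, ...) {
  cat(sprintf("<grn_spec> %d genes, %d edges\n", x$n_genes, nrow(x$edges)))
  invisible(x)
}

# Expected value of the Hill response x^k / (x^k + H^k) under a Normal(m, s^2)
# regulator level truncated to x >= 0 (numerical quadrature). Used to match
# mean production between wired and unwired cell types.
expected_hill <- function(m, s, k, H) {
  if (s <= 0) return(m^k / (m^k + H^k))
  f <- function(x) (x^k / (x^k + H^k)) * stats::dnorm(x, m, s)
  num <- stats::integrate(f, lower = 0, upper = m + 10 * s,
                          rel.tol = 1e-8)$value
  den <- 1 - stats::pnorm(0, m, s)
  num / den
}

#' Build two cell-type GRNs with matched means and distinct coexpression
#'
#' Both specs share the gene set and total basal production; they differ only
#' in which target block each master regulator drives. The first `n_blocks`
#' genes are master regulators: slow, bursty genes whose stochastic
#' fluctuations are the source of extrinsic covariance. The next
#' `2 * n_blocks * block_size` genes are targets, organized as two disjoint
#' block sets: in cell type A, regulator `i` drives block `i` of the first
#' set through Hill activation; in cell type B, the same regulator drives
#' block `i` of the second set. Targets not driven in a given type receive a
#' constant compensating production equal to the expected Hill drive (under
#' the regulator's stationary law), so the expected steady-state mean of
#' every gene matches across types while the coexpression blocks are
#' entirely disjoint. Any remaining genes are unregulated high-expression
#' filler genes, identical in both types. With `strength = 0` no edges or
#' compensation are created and the two specs are identical.
#'
#' @param n_genes Total genes (default 100; must be `>= 2 * n_blocks + 2`).
#' @param n_blocks Coexpression blocks (equivalently master regulators) per
#'   cell type (default 4).
#' @param block_size Targets per block; default `NULL` fills the available
#'   genes, `(n_genes - n_blocks) %/% (2 * n_blocks)`.
#' @param hill_k Hill coefficient for all regulatory edges (1, 2, or 3 in the
#'   benchmark; any value `>= 1` accepted).
#' @param strength Hill drive strength `K` (production added at saturation);
#'   the default makes the shared regulator fluctuations dominate target
#'   noise, giving tight within-block coexpression.
#' @param mr_basal,mr_decay,mr_noise Master-regulator basal production, decay,
#'   and Langevin amplitude. The defaults (40, 0.2, 6) give regulators a high
#'   mean level (200) with slow, large relative fluctuations.
#' @param target_basal,target_decay,target_noise Same for target genes.
#' @param seed Unused (construction is deterministic); kept for interface
#'   symmetry.
#' @return A list with elements `type_a`, `type_b` (both `grn_spec`), and
#'   `blocks` (a tibble mapping genes to roles and, for targets, the block
#'   index and the cell type in which the block is wired).
#' @export
build_two_type_grn <- function(n_genes = 100, n_blocks = 4, block_size = NULL,
                               hill_k = 2, strength = 2000,
                               mr_basal = 40, mr_decay = 0.2, mr_noise = 6,
                               target_basal = 5, target_decay = 0.8,
                               target_noise = 0.05, seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 4)
  assert_scalar_number(n_blocks, "n_blocks", lower = 1)
  n_blocks <- as.integer(n_blocks)
  if (n_genes < 2 * n_blocks + 2) {
    abort(sprintf("Need n_genes >= 2 * n_blocks + 2 (= %d), got %d.",
                  2 * n_blocks + 2, n_genes),
          class = "sceodesic_validation_error")
  }
  if (is.null(block_size)) block_size <- (n_genes - n_blocks) %/% (2L * n_blocks)
  block_size <- as.integer(block_size)
  n_mr <- n_blocks
  n_tg <- 2L * n_blocks * block_size
  if (block_size < 1L || n_mr + n_tg > n_genes) {
    abort(sprintf(
      "Infeasible block layout: %d genes cannot host %d regulators plus 2 x %d blocks of %d targets.",
      n_genes, n_mr, n_blocks, block_size),
      class = "sceodesic_validation_error")
  }
  target_idx <- n_mr + seq_len(n_tg)
  filler <- setdiff(seq_len(n_genes), c(seq_len(n_mr), target_idx))
  # block set 1 = first half of targets, set 2 = second half
  set_of <- rep(1:2, each = n_tg / 2L)
  block_of <- rep(rep(seq_len(n_blocks), each = block_size), 2L)

  H <- mr_basal / mr_decay  # half-saturation at the regulator mean
  mr_sd <- mr_noise * sqrt(mr_basal / mr_decay)
  comp <- if (strength > 0) {
    strength * expected_hill(H, mr_sd, hill_k, H)
  } else 0
  # fillers are unregulated high-expression genes: same mean as a driven
  # target so no gene's count scale stands out
  filler_basal <- target_basal + comp

  basal <- rep(target_basal, n_genes)
  basal[seq_len(n_mr)] <- mr_basal
  basal[filler] <- filler_basal
  decay <- rep(target_decay, n_genes)
  decay[seq_len(n_mr)] <- mr_decay
  amp <- rep(target_noise, n_genes)
  amp[seq_len(n_mr)] <- mr_noise

  make_spec <- function(active_set) {
    if (strength <= 0) return(grn_spec(n_genes, basal, NULL, decay, amp))
    b <- basal
    wired <- target_idx[set_of == active_set]
    unwired <- target_idx[set_of != active_set]
    b[unwired] <- b[unwired] + comp
    edges <- tibble::tibble(
      regulator = block_of[set_of == active_set],
      target = wired,
      strength = strength, hill_k = hill_k, half_sat = H)
    grn_spec(n_genes, b, edges, decay, amp)
  }
  blocks <- tibble::tibble(
    gene = seq_len(n_genes),
    role = dplyr::case_when(
      seq_len(n_genes) <= n_mr ~ "master_regulator",
      seq_len(n_genes) %in% target_idx ~ "target",
      TRUE ~ "filler"),
    block = NA_integer_,
    wired_in = NA_character_
  )
  blocks$block[target_idx] <- block_of
  blocks$wired_in[target_idx] <- c("A", "B")[set_of]
  list(type_a = make_spec(1L),
       type_b = make_spec(2L),
       blocks = blocks)
}

# Production rates for every cell (rows) given current expression levels.
# Edges sharing (regulator, strength, hill_k, half_sat) are evaluated once
# and broadcast to all their targets.
grn_production <- function(spec, X) {
  P <- matrix(spec$basal, nrow = nrow(X), ncol = spec$n_genes, byrow = TRUE)
  e <- spec$edges
  if (nrow(e)) {
    key <- paste(e$regulator, e$strength, e$hill_k, e$half_sat)
    for (grp in split(seq_len(nrow(e)), key)) {
      i <- grp[1]
      xk <- X[, e$regulator[i]]^e$hill_k[i]
      drive <- e$strength[i] * xk / (xk + e$half_sat[i]^e$hill_k[i])
      P[, e$target[grp]] <- P[, e$target[grp]] + drive
    }
  }
  P
}

#' Simulate steady-state expression and counts from a GRN
#'
#' Integrates the chemical Langevin equation by Euler-Maruyama from the
#' deterministic fixed point, one independent trajectory per cell, enforcing
#' nonnegativity by reflection at zero. After burn-in, per-gene mean drift
#' between the midpoint and the end of the run is checked against a
#' Monte-Carlo-aware tolerance; failure raises an error with diagnostics.
#' Observed counts are Poisson draws of the steady-state levels.
#'
#' @param spec A [grn_spec()].
#' @param n_cells Number of cells (independent trajectories).
#' @param seed Integer seed.
#' @param dt Integration step (default 0.05).
#' @param burn_in_steps Euler-Maruyama steps (default 120, i.e. 6 time units,
#'   several relaxation times of the fastest genes).
#' @param counts If `TRUE` (default) return Poisson counts; if `FALSE` return
#'   the continuous steady-state levels.
#' @param drift_tol Base relative drift tolerance (default 0.1; widened by
#'   the Monte-Carlo standard error at small `n_cells`).
#' @return An `n_cells x n_genes` matrix with cell/gene dimnames.
#' @export
simulate_expression <- function(spec, n_cells, seed = 1L, dt = 0.05,
                                burn_in_steps = 120L, counts = TRUE,
                                drift_tol = 0.1) {
  stopifnot(inherits(spec, "grn_spec"))
  assert_scalar_number(n_cells, "n_cells", lower = 1)
  n_cells <- as.integer(n_cells)
  G <- spec$n_genes
  # deterministic fixed point: iterate x <- production(x) / decay (graph is
  # acyclic, so this converges in at most `depth` sweeps)
  x0 <- spec$basal / spec$decay
  for (i in seq_len(20)) {
    x_new <- grn_production(spec, matrix(x0, 1))[1, ] / spec$decay
    if (max(abs(x_new - x0)) < 1e-10 * max(1, max(x0))) { x0 <- x_new; break }
    x0 <- x_new
  }
  X <- matrix(x0, nrow = n_cells, ncol = G, byrow = TRUE)
  amp <- matrix(spec$noise_amplitude, n_cells, G, byrow = TRUE)
  dec <- matrix(spec$decay, n_cells, G, byrow = TRUE)
  mid <- NULL
  mid_step <- max(1L, burn_in_steps %/% 2L)
  X <- with_seed(substream_seed(seed, "langevin"), {
    sqdt <- sqrt(dt)
    for (s in seq_len(burn_in_steps)) {
      P <- grn_production(spec, X)
      noise <- amp * sqrt(pmax(P + dec * X, 0)) *
        matrix(rnorm(n_cells * G), n_cells, G)
      X <- X + (P - dec * X) * dt + noise * sqdt
      X <- abs(X)  # reflection at 0
      if (s == mid_step) mid <- colMeans(X)
    }
    X
  })
  final <- colMeans(X)
  mc_se <- sqrt(mean(apply(X, 2, var))) / sqrt(n_cells)
  tol <- drift_tol * max(mean(final), 1) + 3 * mc_se
  drift <- max(abs(final - mid))
  if (n_cells >= 10 && drift > tol) {
    abort(sprintf(
      "Steady state not reached: max per-gene mean drift %.3g exceeds tolerance %.3g (burn_in_steps = %d, dt = %g).",
      drift, tol, burn_in_steps, dt),
      class = "sceodesic_convergence_error")
  }
  out <- if (counts) {
    with_seed(substream_seed(seed, "poisson"),
              matrix(rpois(n_cells * G, lambda = X), n_cells, G))
  } else X
  dimnames(out) <- list(paste0("cell_", seq_len(n_cells)),
                        paste0("gene_", seq_len(G)))
  out
}

#' Technical-noise specification
#'
#' Defaults follow common benchmark settings: outlier probability 0.01 with
#' log-normal factor Normal(0.5, 0.1) on the log scale, and dropout with mean
#' parameter 0.1 at the 5th percentile.
#'
#' @param outlier_prob Per-gene probability of being an outlier gene.
#' @param outlier_mean,outlier_sd Mean/sd of the Normal whose exponential
#'   multiplies an outlier gene's counts.
#' @param dropout_mean Location parameter of the logistic dropout propensity
#'   in log1p expression.
#' @param dropout_percentile Percentage of entries (lowest propensity) zeroed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(outlier_prob = 0.01, outlier_mean = 0.5,
                       outlier_sd = 0.1, dropout_mean = 0.1,
                       dropout_percentile = 5) {
  assert_scalar_number(outlier_prob, "outlier_prob", lower = 0, upper = 1)
  assert_scalar_number(dropout_percentile, "dropout_percentile",
                       lower = 0, upper = 100)
  structure(list(outlier_prob = outlier_prob, outlier_mean = outlier_mean,
                 outlier_sd = outlier_sd, dropout_mean = dropout_mean,
                 dropout_percentile = dropout_percentile),
            class = "noise_spec")
}

#' Apply outlier and dropout noise to a count matrix
#'
#' Outliers: each gene is independently selected with probability
#' `outlier_prob`; a selected gene's counts are multiplied by
#' `exp(Normal(outlier_mean, outlier_sd))`. Dropout: each entry gets a
#' logistic propensity in its log1p expression (location `dropout_mean`, with
#' seeded jitter to break count ties); the `dropout_percentile` percent of
#' entries with the lowest propensity are zeroed, so the zero fraction is
#' nondecreasing in the percentile.
#'
#' @param X Cell-by-gene count matrix.
#' @param noise A [noise_spec()]. Set `outlier_prob = 0` and
#'   `dropout_percentile = 0` for a no-op.
#' @param seed Integer seed.
#' @return A matrix of the same shape.
#' @export
apply_noise <- function(X, noise = noise_spec(), seed = 1L) {
  X <- as_dense_matrix(X)
  if (min(X) < 0) {
    abort("Counts must be nonnegative.", class = "sceodesic_validation_error")
  }
  stopifnot(inherits(noise, "noise_spec"))
  G <- ncol(X)
  if (noise$outlier_prob > 0) {
    X <- with_seed(substream_seed(seed, "outliers"), {
      sel <- runif(G) < noise$outlier_prob
      if (any(sel)) {
        fac <- exp(rnorm(sum(sel), noise$outlier_mean, noise$outlier_sd))
        X[, sel] <- sweep(X[, sel, drop = FALSE], 2, fac, "*")
      }
      X
    })
  }
  if (noise$dropout_percentile > 0) {
    X <- with_seed(substream_seed(seed, "dropout"), {
      prop <- stats::plogis(log1p(X) - noise$dropout_mean)
      prop <- prop + runif(length(prop)) * 1e-9  # break ties among equal counts
      thr <- quantile(prop, probs = noise$dropout_percentile / 100,
                      names = FALSE)
      X[prop < thr] <- 0
      X
    })
  }
  X
}
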