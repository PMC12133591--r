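# Build a tidy quant tibble from intensity / peptide matrices.
# `conditions` and `replicates` describe the columns.
make_quant <- function(intensity, peptides = NULL, conditions, replicates,
                       pdx_id = "pdx_test",
                       protein_id = sprintf("P%03d", seq_len(nrow(intensity)))) {
  if (is.null(peptides)) {
    peptides <- matrix(0L, nrow(intensity), ncol(intensity))
  }
  nr <- ncol(intensity)
  tibble::tibble(
    pdx_id = pdx_id,
    protein_id = rep(protein_id, times = nr),
    condition = rep(conditions, each = nrow(intensity)),
    replicate = rep(replicates, each = nrow(intensity)),
    intensity = as.vector(intensity),
    peptides = as.integer(as.vector(peptides))
  )
}

# Standard 4-biot vs 2-nb layout.
make_quant_4v2 <- function(intensity, peptides = NULL, ...) {
  make_quant(intensity, peptides,
             conditions = c(rep("biot", 4), rep("nb", 2)),
             replicates = c(1:4, 1:2), ...)
}

# Random complete 4v2 table: baseline + noise, `n_shift` proteins with an
# added biot effect.
random_quant_4v2 <- function(p = 30, n_shift = 0, shift = 3, sd = 0.5,
                             seed = 1) {
  withr::with_seed(seed, {
    base <- stats::rnorm(p, 25, 2)
    X <- base + matrix(stats::rnorm(p * 6, 0, sd), ncol = 6)
    if (n_shift > 0) {
      X[seq_len(n_shift), 1:4] <- X[seq_len(n_shift), 1:4] + shift
    }
    PEP <- matrix(stats::rpois(p * 6, 4), ncol = 6)
    make_quant_4v2(X, PEP)
  })
}

# Independent brute-force oracle for the pooled permutation test: plain
# loops, recomputing the moderated Welch statistic for every protein under
# every distinct relabeling, pooling all non-observed relabelings.
oracle_pooled_perm <- function(X, n1, s0) {
  n <- ncol(X)
  tstat <- function(x, g1) {
    a <- x[g1]
    b <- x[setdiff(seq_len(n), g1)]
    (mean(a) - mean(b)) /
      (sqrt(stats::var(a) / length(a) + stats::var(b) / length(b)) + s0)
  }
  t_obs <- apply(X, 1, tstat, g1 = seq_len(n1))
  combs <- utils::combn(n, n1)
  null_t <- c()
  for (j in seq_len(ncol(combs))) {
    g1 <- combs[, j]
    if (all(g1 == seq_len(n1))) next
    for (i in seq_len(nrow(X))) {
      null_t <- c(null_t, tstat(X[i, ], g1))
    }
  }
  p <- vapply(t_obs, function(t0) {
    max(sum(abs(null_t) >= abs(t0)), 1) / length(null_t)
  }, numeric(1))
  list(t = unname(t_obs), p = unname(p),
       n_relabelings = ncol(combs))
}

# Expand a truth table's planted_detected_in field into long form.
planted_long <- function(truth) {
  out <- truth[truth$is_surface, c("protein_id", "planted_detected_in")]
  parts <- strsplit(out$planted_detected_in, ";", fixed = TRUE)
  tibble::tibble(
    protein_id = rep(out$protein_id, lengths(parts)),
    pdx_id = unlist(parts)
  )
}
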