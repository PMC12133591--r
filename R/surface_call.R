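# Internal: long quant tibble -> protein x run matrices, biot columns first.
quant_matrices <- function(table) {
  table <- validate_quant_table(table)
  runs <- dplyr::arrange(
    dplyr::distinct(table, .data$condition, .data$replicate),
    dplyr::desc(.data$condition == "biot"), .data$replicate
  )
  run_key <- paste(runs$condition, runs$replicate, sep = ".")
  prot <- unique(table$protein_id)
  X <- matrix(NA_real_, nrow = length(prot), ncol = nrow(runs),
              dimnames = list(prot, run_key))
  PEP <- matrix(0L, nrow = length(prot), ncol = nrow(runs),
                dimnames = list(prot, run_key))
  key <- paste(table$condition, table$replicate, sep = ".")
  idx <- cbind(match(table$protein_id, prot), match(key, run_key))
  X[idx] <- table$intensity
  PEP[idx] <- dplyr::coalesce(table$peptides, 0L)
  list(X = X, PEP = PEP, protein_id = prot,
       condition = runs$condition, replicate = runs$replicate,
       pdx_id = table$pdx_id[1])
}

matrices_to_quant <- function(m) {
  nruns <- length(m$condition)
  tibble::tibble(
    pdx_id = m$pdx_id,
    protein_id = rep(m$protein_id, times = nruns),
    condition = rep(m$condition, each = length(m$protein_id)),
    replicate = rep(m$replicate, each = length(m$protein_id)),
    intensity = as.vector(m$X),
    peptides = as.integer(m$PEP)
  )
}

#' Median-normalize a quant table
#'
#' Shifts each run so that its median over observed log2 intensities equals
#' the grand median of all runs' pre-normalization medians. Missing cells
#' stay missing. A table whose runs already share one median is returned
#' unchanged (up to floating point).
#'
#' @param table A tidy quant tibble (log2 intensities).
#' @return The normalized quant tibble.
#' @export
median_normalize <- function(table) {
  m <- quant_matrices(table)
  meds <- apply(m$X, 2, stats::median, na.rm = TRUE)
  n_obs <- colSums(!is.na(m$X))
  if (any(n_obs == 0L)) {
    bad <- colnames(m$X)[which(n_obs == 0L)[1]]
    stop("median_normalize: run `", bad, "` has no observed values",
         call. = FALSE)
  }
  grand <- stats::median(meds)
  m$X <- sweep(m$X, 2, grand - meds, `+`)
  matrices_to_quant(m)
}

#' Impute left-censored missing intensities (downshifted Gaussian)
#'
#' Replaces every missing intensity in run `r` by a draw from
#' `Normal(mu_r - d * sigma_r, (w * sigma_r)^2)`, where `mu_r` and `sigma_r`
#' are the run's observed mean and standard deviation, `d =
#' impute_downshift`, and `w = impute_width`. Observed cells are untouched;
#' the draws are seeded from `params$seed` and reproducible.
#'
#' @param table A normalized tidy quant tibble.
#' @param params A [call_params()].
#' @return The imputed quant tibble (no missing intensities).
#' @export
impute_downshift <- function(table, params = call_params()) {
  m <- quant_matrices(table)
  n_obs <- colSums(!is.na(m$X))
  if (any(n_obs < 2L)) {
    bad <- colnames(m$X)[which(n_obs < 2L)[1]]
    stop("impute_downshift: run `", bad,
         "` has fewer than 2 observed values (sd undefined)", call. = FALSE)
  }
  if (!anyNA(m$X)) {
    return(matrices_to_quant(m))
  }
  withr::with_seed(params$seed, {
    for (j in seq_len(ncol(m$X))) {
      miss <- which(is.na(m$X[, j]))
      if (length(miss) == 0L) next
      obs <- m$X[!is.na(m$X[, j]), j]
      mu <- mean(obs)
      sg <- stats::sd(obs)
      m$X[miss, j] <- stats::rnorm(length(miss),
                                   mean = mu - params$impute_downshift * sg,
                                   sd = params$impute_width * sg)
    }
  })
  matrices_to_quant(m)
}

# Moderated Welch statistic for one relabeling: group1 columns `g1`.
welch_t <- function(X, g1, g2, s0) {
  n1 <- length(g1)
  n2 <- length(g2)
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  v1 <- pmax(rowSums(X[, g1, drop = FALSE]^2) - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(rowSums(X[, g2, drop = FALSE]^2) - n2 * m2^2, 0) / (n2 - 1)
  (m1 - m2) / (sqrt(v1 / n1 + v2 / n2) + s0)
}

# Count, for each x, how many pooled values are >= x (ties count).
count_ge <- function(x, pooled_sorted) {
  length(pooled_sorted) - findInterval(x, pooled_sorted, left.open = TRUE)
}

#' Moderated enrichment test with a pooled permutation null
#'
#' For each protein computes the moderated Welch statistic
#' `t = (m_biot - m_nb) / (SE_welch + s0)` contrasting biotinylated against
#' non-biotinylated runs of one PDX, on an imputed (complete) table.
#'
#' The two-sided permutation p-value comes from relabeling runs into groups
#' of the original sizes. When the number of distinct relabelings is at most
#' 1000 (for the 4-vs-2 design there are exactly `choose(6, 4) = 15`) every
#' non-observed relabeling is enumerated, making p-values exact and
#' deterministic; otherwise `n_perm` random relabelings are drawn (seeded).
#' Because a handful of relabelings cannot resolve small tail probabilities
#' protein-by-protein, the null pools the moderated statistics across all
#' proteins of the table — the statistics are comparable across proteins
#' precisely because `s0` moderates them — so `p_i` is the fraction of all
#' pooled null `|t|` values (every protein, every null relabeling) at or
#' above `|t_i|`, floored at one over the pool size. Ties count toward the
#' null (conservative) and p can never be zero. q-values are
#' Benjamini-Hochberg over these p-values within the PDX.
#'
#' @param table An imputed tidy quant tibble (no missing intensities, at
#'   least 2 runs per condition).
#' @param params A [call_params()].
#' @return A tibble: `pdx_id`, `protein_id`, `log2fc`, `t_stat`, `p_value`,
#'   `q_value`.
#' @export
enrichment_test <- function(table, params = call_params()) {
  m <- quant_matrices(table)
  if (anyNA(m$X)) {
    stop("enrichment_test: table contains missing intensities; impute first",
         call. = FALSE)
  }
  biot <- which(m$condition == "biot")
  nb <- which(m$condition == "nb")
  if (length(biot) < 2L || length(nb) < 2L) {
    stop("enrichment_test: need >= 2 runs per condition", call. = FALSE)
  }
  n <- length(biot) + length(nb)
  n1 <- length(biot)
  R_total <- choose(n, n1)
  if (R_total <= 1) {
    stop("enrichment_test: degenerate design (no distinct relabelings)",
         call. = FALSE)
  }

  cols <- c(biot, nb)  # observed labeling = first n1 of `cols`
  X <- m$X[, cols, drop = FALSE]
  t_obs <- welch_t(X, seq_len(n1), seq.int(n1 + 1L, n), params$s0)

  if (R_total <= 1000) {
    combs <- utils::combn(n, n1)
    # drop the observed labeling: the null pool holds permuted stats only
    is_obs <- apply(combs, 2, function(g1) all(g1 == seq_len(n1)))
    combs <- combs[, !is_obs, drop = FALSE]
    Tmat <- apply(combs, 2, function(g1) {
      welch_t(X, g1, setdiff(seq_len(n), g1), params$s0)
    })
  } else {
    perms <- withr::with_seed(params$seed, {
      replicate(params$n_perm, sample.int(n, n1), simplify = FALSE)
    })
    Tmat <- vapply(perms, function(g1) {
      welch_t(X, g1, setdiff(seq_len(n), g1), params$s0)
    }, numeric(nrow(X)))
  }
  n_pool <- length(Tmat)

  pooled <- sort(abs(as.vector(Tmat)))
  p <- pmax(count_ge(abs(t_obs), pooled), 1L) / n_pool
  q <- stats::p.adjust(p, method = "BH")

  tibble::tibble(
    pdx_id = m$pdx_id,
    protein_id = m$protein_id,
    log2fc = unname(rowMeans(X[, seq_len(n1), drop = FALSE]) -
                      rowMeans(X[, seq.int(n1 + 1L, n), drop = FALSE])),
    t_stat = unname(t_obs),
    p_value = unname(p),
    q_value = unname(q)
  )
}

#' Specific-peptide detection rule
#'
#' A protein passes when it has at least `min_pep_biot` specific peptides in
#' at least `min_pep_reps` biotinylated runs AND at most `max_pep_nb`
#' peptides in every non-biotinylated run. Absent counts are treated as 0.
#'
#' @param table A tidy quant tibble (peptide counts used, intensities
#'   ignored).
#' @param params A [call_params()].
#' @return A tibble: `protein_id`, `peptide_rule_pass`.
#' @export
peptide_rule <- function(table, params = call_params()) {
  m <- quant_matrices(table)
  biot <- m$PEP[, m$condition == "biot", drop = FALSE]
  nb <- m$PEP[, m$condition == "nb", drop = FALSE]
  pass <- (rowSums(biot >= params$min_pep_biot) >= params$min_pep_reps) &
    (rowSums(nb > params$max_pep_nb) == 0L)
  tibble::tibble(protein_id = m$protein_id, peptide_rule_pass = unname(pass))
}

#' Call surface-detected proteins for one PDX sample
#'
#' Runs the full per-sample chain on a raw quant table: median
#' normalization, downshifted-Gaussian imputation, the moderated enrichment
#' test with pooled permutation FDR, and the specific-peptide rule. The
#' `detected` flag is the intensity rule (`q_value <= q_max` and `log2fc >=
#' log2fc_min` and `n_biot_quantified >= min_biot_quantified`) for `mode =
#' "intensity"`, the peptide rule for `mode = "peptide"`, and their
#' disjunction for `mode = "either"`.
#'
#' @param table A raw tidy quant tibble for one PDX.
#' @param params A [call_params()].
#' @return A tibble of class `surface_calls`: `pdx_id`, `protein_id`,
#'   `log2fc`, `t_stat`, `p_value`, `q_value`, `n_biot_quantified`,
#'   `peptide_rule_pass`, `detected`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_proteins = 100, seed = 3))
#' calls <- call_surface(cohort$quant$pdx_1, call_params())
#' dplyr::count(calls, detected)
#' @export
call_surface <- function(table, params = call_params()) {
  m_raw <- quant_matrices(table)
  n_biot_q <- rowSums(!is.na(m_raw$X[, m_raw$condition == "biot",
                                     drop = FALSE]))

  normalized <- median_normalize(table)
  imputed <- impute_downshift(normalized, params)
  stats_tbl <- enrichment_test(imputed, params)
  pep <- peptide_rule(table, params)

  calls <- dplyr::left_join(stats_tbl, pep, by = "protein_id")
  calls$n_biot_quantified <- as.integer(
    n_biot_q[match(calls$protein_id, m_raw$protein_id)]
  )
  intensity_pass <- calls$q_value <= params$q_max &
    calls$log2fc >= params$log2fc_min &
    calls$n_biot_quantified >= params$min_biot_quantified
  calls$detected <- switch(params$mode,
    intensity = intensity_pass,
    peptide = calls$peptide_rule_pass,
    either = intensity_pass | calls$peptide_rule_pass
  )
  calls <- calls[, c("pdx_id", "protein_id", "log2fc", "t_stat", "p_value",
                     "q_value", "n_biot_quantified", "peptide_rule_pass",
                     "detected")]
  new_surface_calls(calls, params)
}

new_surface_calls <- function(calls, params) {
  structure(calls,
            class = c("surface_calls", class(tibble::as_tibble(calls))),
            call_params = params)
}

#' Call surface-detected proteins across a cohort
#'
#' Applies [call_surface()] to each PDX quant table with a per-PDX derived
#' seed (`seed + 10007 * pdx_index`, reduced modulo 2^31 - 1) so that the
#' cohort-level result is reproducible and independent of processing order.
#'
#' @param quant A named list of per-PDX quant tibbles (or a
#'   `surfaceome_cohort`, whose `quant` element is used).
#' @param params A [call_params()].
#' @return A combined `surface_calls` tibble.
#' @export
call_surface_cohort <- function(quant, params = call_params()) {
  if (inherits(quant, "surfaceome_cohort")) {
    quant <- quant$quant
  }
  calls <- purrr::imap_dfr(quant, function(tbl, nm) {
    k <- match(nm, names(quant))
    p_k <- params
    p_k$seed <- as.integer((as.double(params$seed) + 10007 * k) %% 2147483647)
    call_surface(tbl, p_k)
  })
  new_surface_calls(calls, params)
}
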