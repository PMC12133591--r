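#' Configuration for a synthetic surfaceome cohort
#'
#' Describes the statistical structure of a simulated biotinylation-enrichment
#' mass-spectrometry cohort: the number of patient-derived xenograft (PDX)
#' samples and proteins, the replicate design (biotinylated vs
#' non-biotinylated runs), the planted enrichment effect for true surface
#' proteins, intensity noise, left-censored missingness, and planted decoy
#' proteins used to exercise the downstream triage stages.
#'
#' @param n_pdx Number of PDX samples in the cohort.
#' @param n_proteins Number of proteins per quant table.
#' @param n_true_targets Number of planted surface targets with a
#'   lymphoid-restricted tissue archetype (the proteins the pipeline should
#'   recover).
#' @param n_biot_reps,n_nb_reps Runs per PDX: biotinylated replicates and
#'   non-biotinylated control replicates.
#' @param enrichment_log2fc Mean log2 intensity shift added to biotinylated
#'   runs of planted surface proteins.
#' @param baseline_mu,baseline_sigma Mean and SD of the per-protein baseline
#'   log2 intensity.
#' @param noise_sigma SD of per-run measurement noise on the log2 scale.
#' @param missing_censor_quantile Left-censoring level: per run, intensities
#'   falling below this quantile of the run's noise-free intensity
#'   distribution are recorded as missing. `0` disables censoring.
#' @param detect_dropout_rate Per-target, per-PDX probability that a planted
#'   surface protein is *not* planted (receives no enrichment) in that PDX.
#' @param n_decoy_tcell,n_decoy_myeloid,n_decoy_single_nonlymphoid,n_decoy_ubiquitous
#'   Planted enriched decoys: surface membrane proteins whose tissue or
#'   cell-type profile should cause rejection at a later triage stage
#'   (T-cell and myeloid archetypes at the cell-type exclusion stage,
#'   single-non-lymphoid and ubiquitous archetypes at the tissue stage).
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   cohort.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pdx = 6L,
                          n_proteins = 2000L,
                          n_true_targets = 20L,
                          n_biot_reps = 4L,
                          n_nb_reps = 2L,
                          enrichment_log2fc = 3.0,
                          baseline_mu = 25,
                          baseline_sigma = 2,
                          noise_sigma = 0.5,
                          missing_censor_quantile = 0.2,
                          detect_dropout_rate = 0.15,
                          n_decoy_tcell = 5L,
                          n_decoy_myeloid = 5L,
                          n_decoy_single_nonlymphoid = 5L,
                          n_decoy_ubiquitous = 5L,
                          seed = 1L) {
  cfg <- list(
    n_pdx = as.integer(n_pdx),
    n_proteins = as.integer(n_proteins),
    n_true_targets = as.integer(n_true_targets),
    n_biot_reps = as.integer(n_biot_reps),
    n_nb_reps = as.integer(n_nb_reps),
    enrichment_log2fc = as.numeric(enrichment_log2fc),
    baseline_mu = as.numeric(baseline_mu),
    baseline_sigma = as.numeric(baseline_sigma),
    noise_sigma = as.numeric(noise_sigma),
    missing_censor_quantile = as.numeric(missing_censor_quantile),
    detect_dropout_rate = as.numeric(detect_dropout_rate),
    n_decoy_tcell = as.integer(n_decoy_tcell),
    n_decoy_myeloid = as.integer(n_decoy_myeloid),
    n_decoy_single_nonlymphoid = as.integer(n_decoy_single_nonlymphoid),
    n_decoy_ubiquitous = as.integer(n_decoy_ubiquitous),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_pdx", "n_proteins", "n_true_targets", "n_biot_reps",
              "n_nb_reps", "n_decoy_tcell", "n_decoy_myeloid",
              "n_decoy_single_nonlymphoid", "n_decoy_ubiquitous")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) {
      stop("cohort_config: field `", f, "` must be a single non-negative count",
           call. = FALSE)
    }
  }
  for (f in c("missing_censor_quantile", "detect_dropout_rate")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("cohort_config: field `", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  for (f in c("baseline_sigma", "noise_sigma")) {
    if (cfg[[f]] < 0) {
      stop("cohort_config: field `", f, "` must be non-negative", call. = FALSE)
    }
  }
  n_planted <- cfg$n_true_targets + cfg$n_decoy_tcell + cfg$n_decoy_myeloid +
    cfg$n_decoy_single_nonlymphoid + cfg$n_decoy_ubiquitous
  if (n_planted > cfg$n_proteins) {
    stop("cohort_config: field `n_true_targets` (plus decoys) exceeds `n_proteins`",
         call. = FALSE)
  }
  if (cfg$n_biot_reps < 1L || cfg$n_nb_reps < 1L) {
    stop("cohort_config: field `n_biot_reps`/`n_nb_reps` must be >= 1",
         call. = FALSE)
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("cohort_config: field `seed` must be a single integer", call. = FALSE)
  }
  cfg
}

#' Parameters for per-sample surface-detection calling
#'
#' Controls the enrichment test of biotinylated (`biot`) against
#' non-biotinylated (`nb`) runs and the specific-peptide detection rule.
#'
#' @param s0 Moderation constant added to the Welch standard error in the
#'   denominator of the t-statistic; damps large statistics driven by tiny
#'   sample variances.
#' @param n_perm Number of random run relabelings used for the permutation
#'   null when complete enumeration (all distinct relabelings) would exceed
#'   1000; with the 4-vs-2 design enumeration is always used.
#' @param q_max Detection threshold on the Benjamini-Hochberg q-value.
#' @param log2fc_min Minimum log2 fold change (biot minus nb, after
#'   imputation) for intensity-based detection.
#' @param min_biot_quantified Minimum number of biot runs with an observed
#'   (non-missing, pre-imputation) intensity.
#' @param impute_width Width of the imputation distribution as a fraction of
#'   the run's observed SD.
#' @param impute_downshift Downshift of the imputation distribution in
#'   multiples of the run's observed SD.
#' @param min_pep_biot,min_pep_reps,max_pep_nb Specific-peptide rule: a
#'   protein passes when it has at least `min_pep_biot` peptides in at least
#'   `min_pep_reps` biot runs and at most `max_pep_nb` peptides in every nb
#'   run.
#' @param mode Which evidence defines `detected`: `"intensity"` (q-value,
#'   fold change and quantification coverage), `"peptide"` (the peptide
#'   rule), or `"either"` (their disjunction).
#' @param seed Integer seed for imputation draws and permutation sampling.
#'
#' @return A list of class `call_params`.
#' @export
call_params <- function(s0 = 0.1,
                        n_perm = 250L,
                        q_max = 0.05,
                        log2fc_min = 1.0,
                        min_biot_quantified = 3L,
                        impute_width = 0.3,
                        impute_downshift = 1.8,
                        min_pep_biot = 2L,
                        min_pep_reps = 3L,
                        max_pep_nb = 1L,
                        mode = c("intensity", "peptide", "either"),
                        seed = 1L) {
  mode <- match.arg(mode)
  p <- list(
    s0 = as.numeric(s0),
    n_perm = as.integer(n_perm),
    q_max = as.numeric(q_max),
    log2fc_min = as.numeric(log2fc_min),
    min_biot_quantified = as.integer(min_biot_quantified),
    impute_width = as.numeric(impute_width),
    impute_downshift = as.numeric(impute_downshift),
    min_pep_biot = as.integer(min_pep_biot),
    min_pep_reps = as.integer(min_pep_reps),
    max_pep_nb = as.integer(max_pep_nb),
    mode = mode,
    seed = as.integer(seed)
  )
  if (p$s0 < 0) stop("call_params: `s0` must be >= 0", call. = FALSE)
  if (p$n_perm < 1L) stop("call_params: `n_perm` must be >= 1", call. = FALSE)
  if (p$q_max < 0 || p$q_max > 1) {
    stop("call_params: `q_max` must lie in [0, 1]", call. = FALSE)
  }
  if (p$impute_width <= 0) {
    stop("call_params: `impute_width` must be > 0", call. = FALSE)
  }
  class(p) <- "call_params"
  p
}

#' Parameters for the candidate triage cascade
#'
#' Thresholds for the staged filter: cross-PDX prevalence, lymphoid
#' tissue-specificity, and cell-type exclusion.
#'
#' @param min_pdx Minimum number of PDX samples in which a protein must be
#'   called surface-detected.
#' @param tau_min Minimum tau tissue-specificity index.
#' @param lymphoid_fold_min Minimum ratio of the highest lymphoid-tissue
#'   expression to the highest non-lymphoid expression.
#' @param nonlymphoid_abs_max Maximum tolerated absolute expression
#'   (nTPM-like units) in any non-lymphoid tissue.
#' @param exclude_frac_max Maximum fraction of cells expressing the gene
#'   tolerated in any excluded cell type (T cells, granulocytes, HSC by
#'   default).
#' @param epsilon Small constant protecting the fold-change denominator.
#' @param use_tau,use_argmax_lymphoid,use_fold,use_abs Toggles for the four
#'   conjuncts of the specificity criterion.
#'
#' @return A list of class `triage_params`.
#' @export
triage_params <- function(min_pdx = 3L,
                          tau_min = 0.8,
                          lymphoid_fold_min = 4.0,
                          nonlymphoid_abs_max = 10.0,
                          exclude_frac_max = 0.10,
                          epsilon = 1e-6,
                          use_tau = TRUE,
                          use_argmax_lymphoid = TRUE,
                          use_fold = TRUE,
                          use_abs = TRUE) {
  p <- list(
    min_pdx = as.integer(min_pdx),
    tau_min = as.numeric(tau_min),
    lymphoid_fold_min = as.numeric(lymphoid_fold_min),
    nonlymphoid_abs_max = as.numeric(nonlymphoid_abs_max),
    exclude_frac_max = as.numeric(exclude_frac_max),
    epsilon = as.numeric(epsilon),
    use_tau = isTRUE(use_tau),
    use_argmax_lymphoid = isTRUE(use_argmax_lymphoid),
    use_fold = isTRUE(use_fold),
    use_abs = isTRUE(use_abs)
  )
  if (p$min_pdx < 1L) stop("triage_params: `min_pdx` must be >= 1", call. = FALSE)
  if (p$tau_min < 0 || p$tau_min > 1) {
    stop("triage_params: `tau_min` must lie in [0, 1]", call. = FALSE)
  }
  if (p$lymphoid_fold_min < 1) {
    stop("triage_params: `lymphoid_fold_min` must be >= 1", call. = FALSE)
  }
  if (p$exclude_frac_max < 0 || p$exclude_frac_max > 1) {
    stop("triage_params: `exclude_frac_max` must lie in [0, 1]", call. = FALSE)
  }
  if (p$epsilon <= 0) stop("triage_params: `epsilon` must be > 0", call. = FALSE)
  class(p) <- "triage_params"
  p
}
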