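#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Default atlas vocabulary. Lymphoid tissues follow the standard HPA grouping;
# the non-lymphoid panel is a representative organ set.
LYMPHOID_TISSUES <- c("bone_marrow", "spleen", "blood", "lymph_node",
                      "thymus", "tonsil")
NONLYMPHOID_TISSUES <- c("brain", "heart", "lung", "liver", "kidney",
                         "pancreas", "colon", "skin", "muscle", "testis")
ALL_TISSUES <- c(LYMPHOID_TISSUES, NONLYMPHOID_TISSUES)

ALL_CELLTYPES <- c("t_cell_cd4", "t_cell_cd8", "nk_cell", "b_cell",
                   "monocyte", "macrophage", "granulocyte", "dendritic_cell",
                   "hsc", "erythroid", "hepatocyte", "fibroblast")
EXCLUDED_CELLTYPES <- c("t_cell_cd4", "t_cell_cd8", "granulocyte", "hsc")

ARCHETYPES <- c("lymphoid_restricted", "myeloid", "t_cell", "ubiquitous",
                "single_nonlymphoid", "silent")

#' Generate a complete synthetic surfaceome cohort
#'
#' Simulates everything the pipeline consumes: one protein quant table per
#' PDX sample (log2 intensities with left-censored missingness and
#' specific-peptide counts), a protein annotation table, a tissue and
#' cell-type expression atlas, and the ground-truth labels.
#'
#' Intensities are generated on the log2 scale as a per-protein baseline
#' `Normal(baseline_mu, baseline_sigma)` plus the planted condition effect
#' plus run noise `Normal(0, noise_sigma)`. Planted surface proteins (true
#' targets and decoys) receive a `+enrichment_log2fc` mean shift in the
#' biotinylated runs of every PDX they are planted in; each PDX is skipped
#' independently with probability `detect_dropout_rate`. Missingness is
#' left-censored: per run, cells whose intensity falls below the
#' `missing_censor_quantile` of that run's noise-free intensity distribution
#' are recorded as missing. Specific-peptide counts are Poisson with rate
#' proportional to the linear-scale intensity (capped at 30), and 0 for
#' missing cells.
#'
#' A single global seed drives a per-PDX derived seed stream
#' (`seed + pdx_index`), so adding a PDX never perturbs earlier samples.
#'
#' @param config A [cohort_config()].
#' @return A list of class `surfaceome_cohort` with elements `quant` (named
#'   list of per-PDX quant tibbles), `annotations`, `atlas` (an
#'   [expression_atlas()]), `truth`, and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_proteins = 200, seed = 7))
#' names(cohort$quant)
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  P <- config$n_proteins

  cohort_level <- withr::with_seed(config$seed, {
    protein_id <- sprintf("P%05d", seq_len(P))
    gene_symbol <- sprintf("GENE%05d", seq_len(P))

    n_planted <- config$n_true_targets + config$n_decoy_tcell +
      config$n_decoy_myeloid + config$n_decoy_single_nonlymphoid +
      config$n_decoy_ubiquitous
    planted_idx <- if (n_planted > 0L) sample.int(P, n_planted) else integer(0)
    archetype <- rep(NA_character_, P)
    is_surface <- rep(FALSE, P)
    if (n_planted > 0L) {
      planted_arch <- rep(
        c("lymphoid_restricted", "t_cell", "myeloid", "single_nonlymphoid",
          "ubiquitous"),
        times = c(config$n_true_targets, config$n_decoy_tcell,
                  config$n_decoy_myeloid, config$n_decoy_single_nonlymphoid,
                  config$n_decoy_ubiquitous)
      )
      archetype[planted_idx] <- planted_arch
      is_surface[planted_idx] <- TRUE
    }
    bg <- which(!is_surface)
    archetype[bg] <- sample(
      ARCHETYPES, length(bg), replace = TRUE,
      prob = c(0.05, 0.10, 0.10, 0.45, 0.10, 0.20)
    )

    is_membrane <- is_surface | (stats::runif(P) < 0.3)
    known_car_target <- rep(FALSE, P)
    true_idx <- planted_idx[seq_len(config$n_true_targets)]
    if (config$n_true_targets > 0L) {
      known_car_target[true_idx] <- stats::runif(config$n_true_targets) < 0.25
    }

    keywords <- ifelse(
      is_membrane,
      "membrane;cell surface",
      sample(c("cytoplasm", "nucleus", "secreted", "mitochondrion"),
             P, replace = TRUE)
    )

    tissue <- t(vapply(archetype, archetype_tissue_profile,
                       numeric(length(ALL_TISSUES))))
    colnames(tissue) <- ALL_TISSUES
    celltype <- purrr::map_dfr(seq_len(P), function(i) {
      prof <- archetype_celltype_profile(archetype[i])
      tibble::tibble(gene_symbol = gene_symbol[i],
                     celltype = ALL_CELLTYPES,
                     frac_expressing = unname(prof),
                     mean_expr = unname(prof) *
                       stats::runif(length(prof), 1, 5))
    })

    list(protein_id = protein_id, gene_symbol = gene_symbol,
         archetype = archetype, is_surface = is_surface,
         is_membrane = is_membrane, known_car_target = known_car_target,
         keywords = keywords, tissue = tissue, celltype = celltype)
  })

  pdx_ids <- sprintf("pdx_%d", seq_len(config$n_pdx))
  planted_in <- matrix(FALSE, nrow = P, ncol = config$n_pdx)
  quant <- vector("list", config$n_pdx)
  names(quant) <- pdx_ids

  for (k in seq_len(config$n_pdx)) {
    res <- withr::with_seed(config$seed + k, {
      simulate_pdx(cohort_level, config, pdx_ids[k])
    })
    quant[[k]] <- res$quant
    planted_in[, k] <- res$planted_here
  }

  annotations <- tibble::tibble(
    protein_id = cohort_level$protein_id,
    gene_symbol = cohort_level$gene_symbol,
    is_membrane = cohort_level$is_membrane,
    subcellular_keywords = cohort_level$keywords,
    known_car_target = cohort_level$known_car_target
  )

  truth <- tibble::tibble(
    protein_id = cohort_level$protein_id,
    gene_symbol = cohort_level$gene_symbol,
    is_surface = cohort_level$is_surface,
    is_membrane_annotated = cohort_level$is_membrane,
    tissue_archetype = cohort_level$archetype,
    planted_detected_in = vapply(seq_len(P), function(i) {
      paste(pdx_ids[planted_in[i, ]], collapse = ";")
    }, character(1))
  )

  tissue_tbl <- tibble::as_tibble(cohort_level$tissue)
  tissue_tbl <- dplyr::bind_cols(
    tibble::tibble(gene_symbol = cohort_level$gene_symbol), tissue_tbl
  )

  atlas <- expression_atlas(
    tissue_matrix = tissue_tbl,
    celltype_summary = cohort_level$celltype,
    lymphoid_tissues = LYMPHOID_TISSUES,
    excluded_celltypes = EXCLUDED_CELLTYPES
  )

  structure(
    list(quant = quant, annotations = annotations, atlas = atlas,
         truth = truth, config = config),
    class = "surfaceome_cohort"
  )
}

# One PDX: baseline + planted effect + run noise; left-censoring; peptide
# counts coupled to linear-scale abundance.
simulate_pdx <- function(lvl, config, pdx_id) {
  P <- config$n_proteins
  B <- config$n_biot_reps
  C <- config$n_nb_reps
  baseline <- stats::rnorm(P, config$baseline_mu, config$baseline_sigma)
  planted_here <- lvl$is_surface &
    (stats::runif(P) >= config$detect_dropout_rate)

  cond <- c(rep("biot", B), rep("nb", C))
  repl <- c(seq_len(B), seq_len(C))
  effect <- outer(
    ifelse(planted_here, config$enrichment_log2fc, 0),
    as.numeric(cond == "biot")
  )
  noisefree <- baseline + effect
  noise <- matrix(stats::rnorm(P * (B + C), 0, config$noise_sigma),
                  nrow = P)
  intensity <- noisefree + noise

  if (config$missing_censor_quantile > 0) {
    thresh <- apply(noisefree, 2, stats::quantile,
                    probs = config$missing_censor_quantile, names = FALSE)
  } else {
    thresh <- rep(-Inf, B + C)
  }
  missing <- sweep(intensity, 2, thresh, `<`)
  intensity[missing] <- NA_real_

  lam <- pmin(2^(intensity - (config$baseline_mu - 2)), 30)
  peptides <- matrix(0L, nrow = P, ncol = B + C)
  obs <- which(!missing)
  peptides[obs] <- stats::rpois(length(obs), lam[obs])

  quant <- tibble::tibble(
    pdx_id = pdx_id,
    protein_id = rep(lvl$protein_id, times = B + C),
    condition = rep(cond, each = P),
    replicate = rep(repl, each = P),
    intensity = as.vector(intensity),
    peptides = as.integer(peptides)
  )
  list(quant = quant, planted_here = planted_here)
}

# Tissue profiles (nTPM-like). Lymphoid-style archetypes have one dominant
# lymphoid tissue and a decaying tail so the tau index stays >= 0.8.
archetype_tissue_profile <- function(archetype) {
  nL <- length(LYMPHOID_TISSUES)
  nN <- length(NONLYMPHOID_TISSUES)
  x <- numeric(nL + nN)
  names(x) <- ALL_TISSUES
  v <- stats::runif(1, 100, 300)
  if (archetype %in% c("lymphoid_restricted", "t_cell", "myeloid")) {
    dominant <- switch(archetype,
      lymphoid_restricted = sample(c("bone_marrow", "spleen", "lymph_node"), 1),
      t_cell = sample(c("thymus", "lymph_node"), 1),
      myeloid = "bone_marrow"
    )
    x[LYMPHOID_TISSUES] <- v * stats::runif(nL, 0.05, 0.4)
    x[dominant] <- v
    x[NONLYMPHOID_TISSUES] <- stats::runif(nN, 0, 2)
  } else if (archetype == "ubiquitous") {
    x[] <- v * stats::runif(nL + nN, 0.7, 1.0)
  } else if (archetype == "single_nonlymphoid") {
    x[sample(NONLYMPHOID_TISSUES, 1)] <- v
    x[x == 0] <- stats::runif(sum(x == 0), 0, 2)
  } else if (archetype == "silent") {
    # all zeros: exercises the undefined-tau path downstream
  } else {
    stop("unknown tissue archetype: ", archetype, call. = FALSE)
  }
  x
}

# Fraction-of-cells-expressing profiles per cell type.
archetype_celltype_profile <- function(archetype) {
  f <- stats::runif(length(ALL_CELLTYPES), 0, 0.05)
  names(f) <- ALL_CELLTYPES
  if (archetype == "lymphoid_restricted") {
    f["b_cell"] <- stats::runif(1, 0.4, 0.9)
    f["dendritic_cell"] <- stats::runif(1, 0, 0.08)
  } else if (archetype == "t_cell") {
    f[c("t_cell_cd4", "t_cell_cd8")] <- stats::runif(2, 0.4, 0.9)
    f["nk_cell"] <- stats::runif(1, 0.1, 0.4)
  } else if (archetype == "myeloid") {
    f["granulocyte"] <- stats::runif(1, 0.4, 0.9)
    f[c("monocyte", "macrophage")] <- stats::runif(2, 0.3, 0.8)
  } else if (archetype == "ubiquitous") {
    f[] <- stats::runif(length(f), 0.3, 0.8)
  } else if (archetype == "single_nonlymphoid") {
    f[c("hepatocyte", "fibroblast")] <- stats::runif(2, 0.3, 0.8)
  } else if (archetype == "silent") {
    f[] <- 0
  }
  f
}

#' @export
print.surfaceome_cohort <- function(x, ...) {
  cat("<surfaceome_cohort>\n")
  cat("  PDX samples: ", length(x$quant), "\n", sep = "")
  cat("  proteins:    ", nrow(x$annotations), "\n", sep = "")
  cat("  planted surface proteins: ", sum(x$truth$is_surface), "\n", sep = "")
  invisible(x)
}
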