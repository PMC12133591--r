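#' Tau tissue-specificity index
#'
#' `tau = sum(1 - x_i / max(x)) / (T - 1)` over `T` tissues: 0 for a
#' uniformly expressed gene, 1 for single-tissue expression. Scale-invariant
#' (`tau(c * x) = tau(x)` for `c > 0`).
#'
#' @param x Non-negative expression vector over at least 2 tissues with
#'   `max(x) > 0`.
#' @return The tau index in `[0, 1]`.
#' @examples
#' tau_specificity(c(1, 0.5, 0))  # 0.75
#' @export
tau_specificity <- function(x) {
  if (length(x) < 2L) {
    stop("tau_specificity: need at least 2 tissues", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0)) {
    stop("tau_specificity: expression must be non-negative and non-missing",
         call. = FALSE)
  }
  mx <- max(x)
  if (mx <= 0) {
    stop("tau_specificity: undefined for an all-zero expression vector",
         call. = FALSE)
  }
  sum(1 - x / mx) / (length(x) - 1L)
}

# Per-protein summary of a cohort's surface calls.
summarize_calls <- function(calls) {
  n_pdx <- dplyr::n_distinct(calls$pdx_id)
  out <- calls |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_pdx_detected = sum(.data$detected),
      mean_log2fc = if (any(.data$detected)) {
        mean(.data$log2fc[.data$detected])
      } else {
        mean(.data$log2fc)
      },
      .groups = "drop"
    )
  attr(out, "n_pdx") <- n_pdx
  out
}

#' Membrane-annotation filter
#'
#' First triage stage: keep proteins that are surface-detected in at least
#' one PDX *and* carry a membrane annotation. Detected proteins absent from
#' the annotation table are treated as non-membrane and reported in the
#' `unannotated` attribute rather than dropped silently.
#'
#' @param calls A `surface_calls` tibble covering the cohort.
#' @param annotations An annotation tibble (see [read_annotations()]).
#' @return A per-protein survivor tibble (`protein_id`, `gene_symbol`,
#'   `n_pdx_detected`, `mean_log2fc`) with attributes `unannotated`
#'   (character) and `n_pdx`.
#' @export
membrane_filter <- function(calls, annotations) {
  summ <- summarize_calls(calls)
  detected <- dplyr::filter(summ, .data$n_pdx_detected >= 1L)
  joined <- dplyr::left_join(
    detected,
    annotations[, c("protein_id", "gene_symbol", "is_membrane")],
    by = "protein_id"
  )
  unannotated <- joined$protein_id[is.na(joined$is_membrane)]
  survivors <- joined |>
    dplyr::filter(!is.na(.data$is_membrane) & .data$is_membrane) |>
    dplyr::select("protein_id", "gene_symbol", "n_pdx_detected",
                  "mean_log2fc")
  attr(survivors, "unannotated") <- unannotated
  attr(survivors, "n_pdx") <- attr(summ, "n_pdx")
  survivors
}

#' Cross-sample prevalence filter
#'
#' Retains proteins surface-detected in at least `min_pdx` PDX samples
#' (default 3 of 6, the "detected in at least three PDX samples" rule).
#'
#' @param survivors Survivor tibble from [membrane_filter()] (needs
#'   `n_pdx_detected` and the `n_pdx` attribute, or pass `n_pdx`).
#' @param params A [triage_params()].
#' @param n_pdx Number of PDX samples in the cohort; defaults to the
#'   attribute carried by `survivors`.
#' @return The filtered survivor tibble (attributes preserved).
#' @export
prevalence_filter <- function(survivors, params = triage_params(),
                              n_pdx = attr(survivors, "n_pdx")) {
  if (is.null(n_pdx)) {
    stop("prevalence_filter: cohort size `n_pdx` unknown", call. = FALSE)
  }
  if (params$min_pdx > n_pdx) {
    stop("prevalence_filter: `min_pdx` (", params$min_pdx,
         ") exceeds the number of PDX samples (", n_pdx, ")", call. = FALSE)
  }
  out <- dplyr::filter(survivors, .data$n_pdx_detected >= params$min_pdx)
  attr(out, "unannotated") <- attr(survivors, "unannotated")
  attr(out, "n_pdx") <- n_pdx
  out
}

# Specificity scores for a set of genes against the tissue matrix.
score_specificity <- function(genes, atlas, params) {
  tm <- atlas$tissue_matrix
  tissues <- setdiff(names(tm), "gene_symbol")
  if (length(atlas$lymphoid_tissues) == 0L) {
    stop("lymphoid_specificity_filter: empty lymphoid tissue set",
         call. = FALSE)
  }
  lym <- atlas$lymphoid_tissues
  nonlym <- setdiff(tissues, lym)
  empty <- tibble::tibble(gene_symbol = character(), tau = numeric(),
                          lymphoid_max = numeric(),
                          nonlymphoid_max = numeric(),
                          lymphoid_fold = numeric(),
                          argmax_tissue = character(),
                          passes_specificity = logical(),
                          resolved = logical())
  if (length(genes) == 0L) {
    return(empty)
  }
  idx <- match(genes, tm$gene_symbol)
  purrr::map_dfr(seq_along(genes), function(i) {
    if (is.na(idx[i])) {
      return(tibble::tibble(gene_symbol = genes[i], tau = NA_real_,
                            lymphoid_max = NA_real_,
                            nonlymphoid_max = NA_real_,
                            lymphoid_fold = NA_real_,
                            argmax_tissue = NA_character_,
                            passes_specificity = FALSE, resolved = FALSE))
    }
    x <- as.numeric(tm[idx[i], tissues])
    if (max(x) <= 0) {
      # expression silent everywhere: tau undefined, cannot pass
      return(tibble::tibble(gene_symbol = genes[i], tau = NA_real_,
                            lymphoid_max = 0, nonlymphoid_max = 0,
                            lymphoid_fold = NA_real_,
                            argmax_tissue = NA_character_,
                            passes_specificity = FALSE, resolved = TRUE))
    }
    tau <- tau_specificity(x)
    lmax <- if (length(lym) > 0) max(x[match(lym, tissues)]) else 0
    nmax <- if (length(nonlym) > 0) max(x[match(nonlym, tissues)]) else 0
    fold <- lmax / (nmax + params$epsilon)
    argmax <- tissues[which.max(x)]
    pass <- (!params$use_tau || tau >= params$tau_min) &&
      (!params$use_argmax_lymphoid || argmax %in% lym) &&
      (!params$use_fold || fold >= params$lymphoid_fold_min) &&
      (!params$use_abs || nmax <= params$nonlymphoid_abs_max)
    tibble::tibble(gene_symbol = genes[i], tau = tau, lymphoid_max = lmax,
                   nonlymphoid_max = nmax, lymphoid_fold = fold,
                   argmax_tissue = argmax, passes_specificity = pass,
                   resolved = TRUE)
  })
}

#' Lymphoid tissue-specificity filter
#'
#' Scores each survivor gene against the tissue expression matrix and keeps
#' genes satisfying (all toggles on by default): `tau >= tau_min`, the
#' highest-expressing tissue is lymphoid, the lymphoid-to-non-lymphoid fold
#' (`lymphoid_max / (nonlymphoid_max + epsilon)`) is at least
#' `lymphoid_fold_min`, and no non-lymphoid tissue exceeds
#' `nonlymphoid_abs_max`. Genes absent from the tissue matrix are dropped
#' and reported in the `unresolved` attribute.
#'
#' @param survivors Survivor tibble from [prevalence_filter()] (needs
#'   `gene_symbol`).
#' @param atlas An [expression_atlas()].
#' @param params A [triage_params()].
#' @return The survivor tibble joined with the specificity scores, filtered
#'   to passers; attributes `scores` (scores for every input gene) and
#'   `unresolved`.
#' @export
lymphoid_specificity_filter <- function(survivors, atlas,
                                        params = triage_params()) {
  scores <- score_specificity(survivors$gene_symbol, atlas, params)
  out <- dplyr::inner_join(
    survivors,
    dplyr::filter(scores, .data$passes_specificity) |>
      dplyr::select(-"resolved"),
    by = "gene_symbol"
  )
  attr(out, "scores") <- scores
  attr(out, "unresolved") <- scores$gene_symbol[!scores$resolved]
  attr(out, "n_pdx") <- attr(survivors, "n_pdx")
  out
}

#' Cell-type exclusion stage
#'
#' Drops genes whose fraction of expressing cells exceeds
#' `exclude_frac_max` in *any* excluded cell type (T-cell subsets,
#' granulocytes and HSC by default) — the codified form of the curation rule
#' that removed proteins expressed on granulocytes and T cells. The maximum
#' excluded-cell-type fraction is reported per gene.
#'
#' @param survivors Survivor tibble (needs `gene_symbol`).
#' @param atlas An [expression_atlas()].
#' @param params A [triage_params()].
#' @return The survivor tibble with a `max_excluded_frac` column, filtered
#'   to retained genes; attribute `excluded_fracs` holds the per-input-gene
#'   values.
#' @export
celltype_exclusion <- function(survivors, atlas, params = triage_params()) {
  cs <- atlas$celltype_summary
  excl <- dplyr::filter(cs, .data$celltype %in% atlas$excluded_celltypes)
  fracs <- excl |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(max_excluded_frac = max(.data$frac_expressing),
                     .groups = "drop")
  out <- dplyr::left_join(survivors, fracs, by = "gene_symbol")
  # genes absent from the cell-type summary have no exclusion evidence
  out$max_excluded_frac <- dplyr::coalesce(out$max_excluded_frac, 0)
  kept <- dplyr::filter(out, .data$max_excluded_frac <= params$exclude_frac_max)
  attr(kept, "excluded_fracs") <- out[, c("gene_symbol", "max_excluded_frac")]
  attr(kept, "n_pdx") <- attr(survivors, "n_pdx")
  kept
}

#' Dot-plot statistics for a gene across cell types
#'
#' Returns the per-cell-type fraction of cells expressing the gene and its
#' mean expression level — the quantities a single-cell dot plot encodes as
#' dot size and color. When raw per-cell vectors are supplied, the fraction
#' is the share of cells with expression `> 0` and the mean is taken over
#' expressing cells only (`(0, 0)` when no cell expresses the gene).
#'
#' @param atlas An [expression_atlas()] (or a celltype summary tibble).
#' @param gene Gene symbol to look up.
#' @param raw Optional named list of numeric per-cell expression vectors,
#'   one per cell type; overrides the stored summary.
#' @return A tibble: `celltype`, `frac_expressing`, `mean_expr`.
#' @export
dotplot_stats <- function(atlas, gene, raw = NULL) {
  if (!is.null(raw)) {
    return(purrr::imap_dfr(raw, function(v, ct) {
      expressing <- v > 0
      tibble::tibble(
        celltype = ct,
        frac_expressing = mean(expressing),
        mean_expr = if (any(expressing)) mean(v[expressing]) else 0
      )
    }))
  }
  cs <- if (inherits(atlas, "expression_atlas")) atlas$celltype_summary else atlas
  hit <- dplyr::filter(cs, .data$gene_symbol == gene)
  if (nrow(hit) == 0L) {
    stop("dotplot_stats: gene `", gene, "` not found in the cell-type summary",
         call. = FALSE)
  }
  dplyr::select(hit, "celltype", "frac_expressing", "mean_expr")
}

#' Rank triage survivors and assemble the candidate table
#'
#' The rank score is the sum of within-survivor standard scores:
#' `z(n_pdx_detected) + z(mean_log2fc) + z(tau) - z(max_excluded_frac)`; a
#' degenerate component (zero variance or a single survivor) contributes 0.
#' Ties are broken by lexicographic gene symbol.
#'
#' @param survivors Survivor tibble from [celltype_exclusion()].
#' @param annotations Annotation tibble (for `known_car_target`).
#' @return The survivor tibble with `known_car_target`, `rank_score`, and
#'   `rank`, ordered best-first.
#' @export
rank_candidates <- function(survivors, annotations) {
  zscore <- function(x) {
    if (length(x) < 2L) return(rep(0, length(x)))
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  out <- dplyr::left_join(
    survivors,
    annotations[, c("protein_id", "known_car_target")],
    by = "protein_id"
  )
  out$known_car_target <- dplyr::coalesce(out$known_car_target, FALSE)
  out$rank_score <- zscore(out$n_pdx_detected) + zscore(out$mean_log2fc) +
    zscore(out$tau) - zscore(out$max_excluded_frac)
  out <- dplyr::arrange(out, dplyr::desc(.data$rank_score), .data$gene_symbol)
  out$rank <- seq_len(nrow(out))
  out
}

#' Run the full candidate triage cascade
#'
#' Applies the staged filter in fixed order — surface detection in any PDX,
#' membrane annotation, cross-PDX prevalence, lymphoid tissue-specificity,
#' cell-type exclusion — then ranks the survivors. Stage flags are nested:
#' each stage is only evaluated on survivors of the previous one, so a later
#' flag `TRUE` implies all earlier flags `TRUE`, and the stage-count
#' waterfall is non-increasing.
#'
#' @param calls A cohort-level `surface_calls` tibble (see
#'   [call_surface_cohort()]).
#' @param annotations Annotation tibble.
#' @param atlas An [expression_atlas()].
#' @param params A [triage_params()].
#' @return A tibble of class `candidate_triage` with one row per protein in
#'   `calls`: per-stage flags (`surface_any`, `membrane`, `prevalent`,
#'   `lymphoid_specific`, `not_excluded`), scores, `rank_score` and `rank`
#'   (NA for non-survivors). Attributes: `waterfall` (stage-count tibble),
#'   `params`, `unannotated`, `unresolved`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_proteins = 300, seed = 11))
#' calls <- call_surface_cohort(cohort, call_params())
#' triage <- prioritize_candidates(calls, cohort$annotations, cohort$atlas)
#' attr(triage, "waterfall")
#' @export
prioritize_candidates <- function(calls, annotations, atlas,
                                  params = triage_params()) {
  summ <- summarize_calls(calls)
  s1 <- membrane_filter(calls, annotations)
  s2 <- prevalence_filter(s1, params)
  s3 <- lymphoid_specificity_filter(s2, atlas, params)
  s4 <- celltype_exclusion(s3, atlas, params)
  ranked <- rank_candidates(s4, annotations)

  base <- dplyr::left_join(
    summ,
    annotations[, c("protein_id", "gene_symbol", "is_membrane",
                    "known_car_target")],
    by = "protein_id"
  )
  base$known_car_target <- dplyr::coalesce(base$known_car_target, FALSE)
  base$surface_any <- base$n_pdx_detected >= 1L
  base$membrane <- base$protein_id %in% s1$protein_id
  base$prevalent <- base$protein_id %in% s2$protein_id
  base$lymphoid_specific <- base$protein_id %in% s3$protein_id
  base$not_excluded <- base$protein_id %in% s4$protein_id

  scores <- attr(s3, "scores")
  if (!is.null(scores) && nrow(scores) > 0L) {
    base <- dplyr::left_join(
      base,
      dplyr::select(scores, "gene_symbol", "tau", "lymphoid_max",
                    "nonlymphoid_max", "lymphoid_fold",
                    "passes_specificity"),
      by = "gene_symbol"
    )
  } else {
    base$tau <- NA_real_
    base$lymphoid_max <- NA_real_
    base$nonlymphoid_max <- NA_real_
    base$lymphoid_fold <- NA_real_
    base$passes_specificity <- NA
  }
  fracs <- attr(s4, "excluded_fracs")
  if (!is.null(fracs) && nrow(fracs) > 0L) {
    base <- dplyr::left_join(base, fracs, by = "gene_symbol")
  } else {
    base$max_excluded_frac <- NA_real_
  }
  base <- dplyr::left_join(
    base, ranked[, c("protein_id", "rank_score", "rank")], by = "protein_id"
  )
  base <- dplyr::arrange(base, dplyr::desc(.data$not_excluded), .data$rank,
                         .data$protein_id)

  waterfall <- tibble::tibble(
    stage = c("total", "surface_any", "membrane", "prevalent",
              "lymphoid_specific", "not_excluded"),
    n = c(nrow(base), sum(base$surface_any), sum(base$membrane),
          sum(base$prevalent), sum(base$lymphoid_specific),
          sum(base$not_excluded))
  )

  structure(base,
            class = c("candidate_triage", class(tibble::as_tibble(base))),
            waterfall = waterfall,
            params = params,
            unannotated = attr(s1, "unannotated"),
            unresolved = attr(s3, "unresolved"))
}
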