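#' Run the end-to-end discovery pipeline
#'
#' Orchestrates simulate (or load) -> per-PDX surface calling -> candidate
#' triage, writing `calls.tsv`, `candidates.tsv`, `waterfall.tsv` and a
#' markdown `report.md` into `out_dir`. With `input_dir = NULL` a synthetic
#' cohort is generated from `cohort`; otherwise the cohort is read from the
#' directory (see [read_cohort()]). A single global `seed`, when given,
#' overrides both the cohort seed and the calling seed so one integer
#' determines every stochastic step. On any stage error, partial outputs
#' are removed before the error propagates.
#'
#' @param out_dir Output directory (created if absent).
#' @param cohort A [cohort_config()] used when simulating.
#' @param call A [call_params()].
#' @param triage A [triage_params()].
#' @param input_dir Optional cohort directory to analyse instead of
#'   simulating.
#' @param seed Optional global integer seed overriding the component seeds.
#' @param top_k Number of top candidates summarized in the report.
#' @return Invisibly, a list: `candidates` (the `candidate_triage` table),
#'   `calls`, `waterfall`, `evaluation` (truth-based sensitivity/FDR, or
#'   `NULL`), and `report_path`.
#' @export
run_pipeline <- function(out_dir,
                         cohort = cohort_config(),
                         call = call_params(),
                         triage = triage_params(),
                         input_dir = NULL,
                         seed = NULL,
                         top_k = 10L) {
  if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
    call$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("calls.tsv", "candidates.tsv",
                                  "waterfall.tsv", "report.md"))
  tryCatch({
    if (is.null(input_dir)) {
      message("simulating cohort (seed ", cohort$seed, ")")
      data <- generate_cohort(cohort)
      quant <- data$quant
      annotations <- data$annotations
      atlas <- data$atlas
      truth <- data$truth
    } else {
      message("reading cohort from ", input_dir)
      data <- read_cohort(input_dir)
      quant <- data$quant
      annotations <- data$annotations
      atlas <- data$atlas
      truth <- data$truth
    }

    # validate triage parameters against the cohort before doing any work
    if (triage$min_pdx > length(quant)) {
      stop("run_pipeline: `min_pdx` (", triage$min_pdx,
           ") exceeds the number of PDX samples (", length(quant), ")",
           call. = FALSE)
    }

    message("calling surface proteins in ", length(quant), " PDX samples")
    calls <- call_surface_cohort(quant, call)
    message("triaging candidates")
    candidates <- prioritize_candidates(calls, annotations, atlas, triage)
    waterfall <- attr(candidates, "waterfall")

    evaluation <- if (!is.null(truth)) {
      evaluate_against_truth(candidates, truth)
    }

    readr::write_tsv(tibble::as_tibble(calls), outputs[1], na = "NA",
                     progress = FALSE)
    write_candidates(tibble::as_tibble(candidates), outputs[2])
    readr::write_tsv(waterfall, outputs[3], na = "NA", progress = FALSE)
    writeLines(
      render_report(candidates, waterfall, atlas, evaluation,
                    cohort = if (is.null(input_dir)) cohort,
                    call = call, triage = triage, top_k = top_k),
      outputs[4]
    )
    message("wrote ", paste(basename(outputs), collapse = ", "),
            " to ", out_dir)
    invisible(list(candidates = candidates, calls = calls,
                   waterfall = waterfall, evaluation = evaluation,
                   report_path = outputs[4]))
  }, error = function(e) {
    unlink(outputs)
    stop(e)
  })
}

#' Evaluate a triage result against synthetic ground truth
#'
#' A "true target" is a planted surface protein with the
#' lymphoid-restricted tissue archetype. Sensitivity is the fraction of true
#' targets among the final candidates; the false-discovery rate is the
#' fraction of final candidates that are not true targets.
#'
#' @param candidates A `candidate_triage` table.
#' @param truth A truth tibble from [generate_cohort()] (or `truth.tsv`).
#' @return A list: `sensitivity`, `fdr`, `n_true_targets`, `n_candidates`,
#'   `target_ranks` (tibble of planted targets with their final rank).
#' @export
evaluate_against_truth <- function(candidates, truth) {
  is_target <- truth$is_surface &
    truth$tissue_archetype == "lymphoid_restricted"
  targets <- truth$protein_id[is_target]
  final <- candidates$protein_id[candidates$not_excluded]
  sens <- if (length(targets) > 0) {
    mean(targets %in% final)
  } else {
    NA_real_
  }
  fdr <- if (length(final) > 0) mean(!(final %in% targets)) else 0
  list(
    sensitivity = sens,
    fdr = fdr,
    n_true_targets = length(targets),
    n_candidates = length(final),
    target_ranks = tibble::tibble(
      protein_id = targets,
      rank = candidates$rank[match(targets, candidates$protein_id)]
    )
  )
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, digits = 4),
                  FUN.VALUE = character(nrow(df)))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, rows)
}

render_report <- function(candidates, waterfall, atlas, evaluation,
                          cohort = NULL, call = NULL, triage = NULL,
                          top_k = 10L) {
  lines <- c("# Surfaceome candidate triage report", "")
  lines <- c(lines, "## Parameters", "")
  if (!is.null(cohort)) {
    lines <- c(lines, paste0("- cohort: ", paste(
      names(unclass(cohort)), unlist(unclass(cohort)), sep = "=",
      collapse = ", ")))
  }
  for (nm in c("call", "triage")) {
    p <- get(nm)
    if (!is.null(p)) {
      lines <- c(lines, paste0("- ", nm, ": ", paste(
        names(unclass(p)), unlist(unclass(p)), sep = "=", collapse = ", ")))
    }
  }
  lines <- c(lines, "", "## Stage waterfall", "", md_table(waterfall), "")

  unannot <- attr(candidates, "unannotated")
  unres <- attr(candidates, "unresolved")
  lines <- c(lines, "## Drop reasons", "",
             paste0("- detected but unannotated (treated as non-membrane): ",
                    length(unannot)),
             paste0("- prevalent but unresolved in the tissue matrix: ",
                    length(unres)), "")

  final <- dplyr::filter(tibble::as_tibble(candidates), .data$not_excluded)
  k <- min(top_k, nrow(final))
  lines <- c(lines, paste0("## Top ", k, " candidates"), "")
  if (k > 0L) {
    top <- final[seq_len(k), c("rank", "gene_symbol", "protein_id",
                               "n_pdx_detected", "mean_log2fc", "tau",
                               "max_excluded_frac", "known_car_target",
                               "rank_score")]
    lines <- c(lines, md_table(top), "")
    for (g in top$gene_symbol) {
      dp <- try(dotplot_stats(atlas, g), silent = TRUE)
      if (!inherits(dp, "try-error")) {
        lines <- c(lines, paste0("### Cell-type profile: ", g), "",
                   md_table(dp), "")
      }
    }
  } else {
    lines <- c(lines, "(no candidates survived the cascade)", "")
  }

  if (!is.null(evaluation)) {
    lines <- c(lines, "## Evaluation against planted truth", "",
               paste0("- planted true targets: ", evaluation$n_true_targets),
               paste0("- final candidates: ", evaluation$n_candidates),
               paste0("- sensitivity: ",
                      format(evaluation$sensitivity, digits = 4)),
               paste0("- false discovery rate: ",
                      format(evaluation$fdr, digits = 4)), "",
               md_table(evaluation$target_ranks), "")
  }
  lines
}
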