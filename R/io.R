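read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  readr::read_tsv(path, comment = "#", na = c("", "NA"), progress = FALSE,
                  show_col_types = FALSE, ...)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(what, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a per-PDX protein quant table
#'
#' Reads the tab-separated quant dialect: a `protein_id` column plus paired
#' run columns `intensity.<cond>.<rep>` and `peptides.<cond>.<rep>` with
#' condition tokens `biot` (biotinylated) and `nb` (non-biotinylated
#' control). Empty cells and `"NA"` become missing intensities, never zero.
#'
#' @param path Path to the TSV file (UTF-8, `#` comment lines ignored).
#' @param pdx_id Identifier attached to every row of the returned table.
#' @param linear If `TRUE` the file stores linear-scale intensities and
#'   `log2()` is applied on read (missing stays missing); the canonical
#'   dialect stores log2 intensities.
#' @return A tidy tibble with columns `pdx_id`, `protein_id`, `condition`,
#'   `replicate`, `intensity`, `peptides` (one row per protein per run).
#' @export
read_quant_table <- function(path, pdx_id, linear = FALSE) {
  df <- read_tsv_strict(path)
  require_columns(df, "protein_id", "quant table")

  dup <- which(duplicated(df$protein_id))
  if (length(dup) > 0L) {
    stop("quant table: duplicate protein_id `", df$protein_id[dup[1]],
         "` at data row ", dup[1], call. = FALSE)
  }

  run_cols <- setdiff(names(df), "protein_id")
  m <- regmatches(run_cols,
                  regexec("^(intensity|peptides)\\.([A-Za-z]+)\\.([0-9]+)$",
                          run_cols))
  bad <- run_cols[vapply(m, length, integer(1)) == 0L]
  if (length(bad) > 0L) {
    stop("quant table: unrecognized column `", bad[1],
         "` (expected intensity.<cond>.<rep> / peptides.<cond>.<rep>)",
         call. = FALSE)
  }
  kinds <- vapply(m, `[`, character(1), 2)
  conds <- vapply(m, `[`, character(1), 3)
  reps <- as.integer(vapply(m, `[`, character(1), 4))
  unknown <- setdiff(unique(conds), c("biot", "nb"))
  if (length(unknown) > 0L) {
    stop("quant table: unknown condition token `", unknown[1], "`",
         call. = FALSE)
  }
  if (!("biot" %in% conds) || !("nb" %in% conds)) {
    stop("quant table: need at least one biot and one nb run", call. = FALSE)
  }

  runs <- unique(data.frame(condition = conds, replicate = reps,
                            stringsAsFactors = FALSE))
  long <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    cond <- runs$condition[i]
    rep_i <- runs$replicate[i]
    icol <- sprintf("intensity.%s.%d", cond, rep_i)
    pcol <- sprintf("peptides.%s.%d", cond, rep_i)
    intensity <- if (icol %in% names(df)) as.numeric(df[[icol]]) else NA_real_
    peptides <- if (pcol %in% names(df)) as.integer(df[[pcol]]) else 0L
    tibble::tibble(
      pdx_id = pdx_id,
      protein_id = df$protein_id,
      condition = cond,
      replicate = rep_i,
      intensity = intensity,
      peptides = dplyr::coalesce(peptides, 0L)
    )
  })
  if (linear) {
    long$intensity <- log2(long$intensity)
  }
  validate_quant_table(long)
}

#' Write a per-PDX protein quant table
#'
#' Inverse of [read_quant_table()]: serializes the tidy table to the wide
#' TSV dialect, encoding missing intensities as `NA` (never zero).
#'
#' @param table A tidy quant tibble (see [read_quant_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  table <- validate_quant_table(table)
  ord <- dplyr::arrange(
    dplyr::distinct(table, .data$condition, .data$replicate),
    dplyr::desc(.data$condition == "biot"), .data$replicate
  )
  prot <- unique(table$protein_id)
  out <- tibble::tibble(protein_id = prot)
  for (what in c("intensity", "peptides")) {
    for (i in seq_len(nrow(ord))) {
      sub <- dplyr::filter(table, .data$condition == ord$condition[i],
                           .data$replicate == ord$replicate[i])
      col <- sprintf("%s.%s.%d", what, ord$condition[i], ord$replicate[i])
      out[[col]] <- sub[[what]][match(prot, sub$protein_id)]
    }
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

validate_quant_table <- function(table) {
  require_columns(table, c("pdx_id", "protein_id", "condition", "replicate",
                           "intensity", "peptides"), "quant table")
  if (!all(table$condition %in% c("biot", "nb"))) {
    stop("quant table: condition must be `biot` or `nb`", call. = FALSE)
  }
  if (any(table$peptides < 0, na.rm = TRUE)) {
    stop("quant table: negative peptide counts are forbidden", call. = FALSE)
  }
  runs <- dplyr::distinct(table, .data$condition, .data$replicate)
  if (!any(runs$condition == "biot") || !any(runs$condition == "nb")) {
    stop("quant table: need at least one biot and one nb run", call. = FALSE)
  }
  per_run <- dplyr::count(table, .data$condition, .data$replicate)
  if (length(unique(per_run$n)) > 1L) {
    stop("quant table: runs cover different protein sets", call. = FALSE)
  }
  dup <- dplyr::count(table, .data$protein_id, .data$condition,
                      .data$replicate)
  if (any(dup$n > 1L)) {
    stop("quant table: duplicate protein within a run", call. = FALSE)
  }
  tibble::as_tibble(table)
}

#' Read or write a protein annotation table
#'
#' Columns: `protein_id`, `gene_symbol`, `is_membrane`,
#' `subcellular_keywords` (`;`-separated), `known_car_target`. A keyword set
#' containing `"membrane"` with `is_membrane = FALSE` is a validation error.
#'
#' @param path TSV path.
#' @return A tibble (reader); `path` invisibly (writer).
#' @export
read_annotations <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      gene_symbol = readr::col_character(),
      is_membrane = readr::col_logical(),
      subcellular_keywords = readr::col_character(),
      known_car_target = readr::col_logical()
    )
  )
  require_columns(df, c("protein_id", "gene_symbol", "is_membrane",
                        "subcellular_keywords", "known_car_target"),
                  "annotations")
  if (anyDuplicated(df$protein_id)) {
    stop("annotations: duplicate protein_id", call. = FALSE)
  }
  df$subcellular_keywords <- dplyr::coalesce(df$subcellular_keywords, "")
  has_mem <- vapply(strsplit(df$subcellular_keywords, ";", fixed = TRUE),
                    function(k) "membrane" %in% k, logical(1))
  bad <- which(has_mem & !df$is_membrane)
  if (length(bad) > 0L) {
    stop("annotations: protein `", df$protein_id[bad[1]],
         "` has keyword `membrane` but is_membrane = FALSE", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_annotations
#' @param annotations Annotation tibble to serialize.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Construct a tissue / cell-type expression atlas
#'
#' Bundles a gene-by-tissue expression matrix (nTPM-like units, long-lived
#' HPA/GTEx-consensus style) with a gene-by-cell-type summary (fraction of
#' cells expressing and mean level, single-cell-atlas style), plus the sets
#' of lymphoid tissues and excluded cell types the triage stages consult.
#'
#' @param tissue_matrix Tibble: `gene_symbol` plus one numeric column per
#'   tissue, all values `>= 0`.
#' @param celltype_summary Long tibble: `gene_symbol`, `celltype`,
#'   `frac_expressing` in `[0, 1]`, `mean_expr >= 0`.
#' @param lymphoid_tissues Character subset of the tissue columns.
#' @param excluded_celltypes Character subset of the cell types present.
#' @return A list of class `expression_atlas`.
#' @export
expression_atlas <- function(tissue_matrix, celltype_summary,
                             lymphoid_tissues = LYMPHOID_TISSUES,
                             excluded_celltypes = EXCLUDED_CELLTYPES) {
  require_columns(tissue_matrix, "gene_symbol", "tissue matrix")
  tissues <- setdiff(names(tissue_matrix), "gene_symbol")
  if (length(tissues) < 1L) {
    stop("tissue matrix: no tissue columns", call. = FALSE)
  }
  vals <- as.matrix(tissue_matrix[, tissues])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("tissue matrix: negative expression values", call. = FALSE)
  }
  missing_lt <- setdiff(lymphoid_tissues, tissues)
  if (length(missing_lt) > 0L) {
    stop("atlas: lymphoid tissue(s) absent from the tissue matrix: ",
         paste(missing_lt, collapse = ", "), call. = FALSE)
  }
  require_columns(celltype_summary,
                  c("gene_symbol", "celltype", "frac_expressing", "mean_expr"),
                  "celltype summary")
  if (any(celltype_summary$frac_expressing < 0 |
          celltype_summary$frac_expressing > 1, na.rm = TRUE)) {
    stop("celltype summary: frac_expressing outside [0, 1]", call. = FALSE)
  }
  if (any(celltype_summary$mean_expr < 0, na.rm = TRUE)) {
    stop("celltype summary: negative mean_expr", call. = FALSE)
  }
  missing_ct <- setdiff(excluded_celltypes, unique(celltype_summary$celltype))
  if (length(missing_ct) > 0L) {
    stop("atlas: excluded cell type(s) absent from the summary: ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  }
  structure(
    list(tissue_matrix = tibble::as_tibble(tissue_matrix),
         celltype_summary = tibble::as_tibble(celltype_summary),
         lymphoid_tissues = lymphoid_tissues,
         excluded_celltypes = excluded_celltypes),
    class = "expression_atlas"
  )
}

#' Read an expression atlas from its two TSV files
#'
#' @param tissue_path TSV: `gene_symbol` + one column per tissue.
#' @param celltype_path TSV: `gene_symbol, celltype, frac_expressing,
#'   mean_expr` (long form).
#' @inheritParams expression_atlas
#' @return An [expression_atlas()].
#' @export
read_atlas <- function(tissue_path, celltype_path,
                       lymphoid_tissues = LYMPHOID_TISSUES,
                       excluded_celltypes = EXCLUDED_CELLTYPES) {
  tissue <- read_tsv_strict(tissue_path)
  celltype <- read_tsv_strict(celltype_path)
  expression_atlas(tissue, celltype, lymphoid_tissues, excluded_celltypes)
}

#' @rdname read_atlas
#' @param atlas An [expression_atlas()].
#' @export
write_atlas <- function(atlas, tissue_path, celltype_path) {
  readr::write_tsv(atlas$tissue_matrix, tissue_path, na = "NA",
                   progress = FALSE)
  readr::write_tsv(atlas$celltype_summary, celltype_path, na = "NA",
                   progress = FALSE)
  invisible(c(tissue_path, celltype_path))
}

#' Read or write a candidate table
#'
#' @param path TSV path.
#' @return A tibble (reader); `path` invisibly (writer).
#' @export
read_candidates <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("protein_id", "gene_symbol"), "candidate table")
  tibble::as_tibble(df)
}

#' @rdname read_candidates
#' @param table Candidate tibble to serialize.
#' @export
write_candidates <- function(table, path) {
  readr::write_tsv(table, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `pdx_<k>.quant.tsv`, `annotations.tsv`, `tissue_expression.tsv`,
#' `celltype_expression.tsv` and `truth.tsv` in the dialects the readers
#' accept unchanged.
#'
#' @param cohort A `surfaceome_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pdx in names(cohort$quant)) {
    write_quant_table(cohort$quant[[pdx]],
                      file.path(dir, paste0(pdx, ".quant.tsv")))
  }
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  write_atlas(cohort$atlas,
              file.path(dir, "tissue_expression.tsv"),
              file.path(dir, "celltype_expression.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), na = "NA",
                   progress = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory holding `pdx_*.quant.tsv`, `annotations.tsv`,
#'   `tissue_expression.tsv`, `celltype_expression.tsv`, and optionally
#'   `truth.tsv`.
#' @inheritParams expression_atlas
#' @return A list with `quant`, `annotations`, `atlas`, and `truth` (`NULL`
#'   when no truth file is present).
#' @export
read_cohort <- function(dir,
                        lymphoid_tissues = LYMPHOID_TISSUES,
                        excluded_celltypes = EXCLUDED_CELLTYPES) {
  qfiles <- sort(list.files(dir, pattern = "\\.quant\\.tsv$",
                            full.names = TRUE))
  if (length(qfiles) == 0L) {
    stop("read_cohort: no *.quant.tsv files in ", dir, call. = FALSE)
  }
  pdx_ids <- sub("\\.quant\\.tsv$", "", basename(qfiles))
  quant <- purrr::map2(qfiles, pdx_ids, read_quant_table)
  names(quant) <- pdx_ids
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv_strict(truth_path) else NULL
  list(
    quant = quant,
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    atlas = read_atlas(file.path(dir, "tissue_expression.tsv"),
                       file.path(dir, "celltype_expression.tsv"),
                       lymphoid_tissues, excluded_celltypes),
    truth = truth
  )
}
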