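test_that("tau matches its closed forms and is scale-invariant", {
  expect_equal(tau_specificity(rep(3.7, 10)), 0)
  expect_equal(tau_specificity(c(5, 0, 0, 0)), 1)
  expect_equal(tau_specificity(c(1, 0.5, 0)), 0.75)
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- runif(sample(2:20, 1), 0, 100)
      c_pos <- runif(1, 0.01, 50)
      expect_equal(tau_specificity(c_pos * x), tau_specificity(x))
    }
  })
  expect_error(tau_specificity(c(0, 0, 0)), "all-zero")
  expect_error(tau_specificity(c(1)), "at least 2")
  expect_error(tau_specificity(c(1, -1)), "non-negative")
})

# a minimal calls table: proteins detected in the given numbers of PDX
fake_calls <- function(detected_in, n_pdx = 6) {
  prots <- names(detected_in)
  purrr::map_dfr(seq_len(n_pdx), function(k) {
    tibble::tibble(
      pdx_id = paste0("pdx_", k),
      protein_id = prots,
      log2fc = 3,
      t_stat = 5, p_value = 0.001, q_value = 0.01,
      n_biot_quantified = 4L, peptide_rule_pass = FALSE,
      detected = k <= unlist(detected_in)
    )
  })
}

fake_annotations <- function(prots, membrane = TRUE) {
  tibble::tibble(
    protein_id = prots,
    gene_symbol = paste0("G_", prots),
    is_membrane = membrane,
    subcellular_keywords = ifelse(membrane, "membrane", "cytoplasm"),
    known_car_target = FALSE
  )
}

test_that("membrane filter keeps detected, annotated membrane proteins", {
  calls <- fake_calls(list(A = 4, B = 3, C = 0, D = 2))
  ann <- fake_annotations(c("A", "B", "C"), membrane = c(TRUE, FALSE, TRUE))
  out <- membrane_filter(calls, ann)
  expect_setequal(out$protein_id, "A")        # B non-membrane, C undetected
  expect_equal(attr(out, "unannotated"), "D") # detected but unannotated
})

test_that("membrane filter equals set algebra on synthetic truth", {
  cohort <- generate_cohort(cohort_config(n_proteins = 300, seed = 19))
  calls <- call_surface_cohort(cohort, call_params())
  out <- membrane_filter(calls, cohort$annotations)
  detected_any <- unique(calls$protein_id[calls$detected])
  membrane <- cohort$truth$protein_id[cohort$truth$is_membrane_annotated]
  expect_setequal(out$protein_id, intersect(detected_any, membrane))
})

test_that("prevalence threshold behaves exactly at its boundary", {
  calls <- fake_calls(list(A = 3, B = 2, C = 6))
  ann <- fake_annotations(c("A", "B", "C"))
  surv <- membrane_filter(calls, ann)
  out <- prevalence_filter(surv, triage_params(min_pdx = 3))
  expect_setequal(out$protein_id, c("A", "C"))  # 3 of 6 retained, 2 of 6 not
  # vacuous threshold returns the membrane-filtered input
  out1 <- prevalence_filter(surv, triage_params(min_pdx = 1))
  expect_setequal(out1$protein_id, surv$protein_id)
  expect_error(prevalence_filter(surv, triage_params(min_pdx = 7)),
               "exceeds")
})

test_that("lymphoid specificity separates the tissue archetypes", {
  tissues <- c("bone_marrow", "spleen", "blood", "lymph_node", "thymus",
               "tonsil", "brain", "liver")
  tm <- tibble::tibble(
    gene_symbol = c("LYMPH", "UBIQ", "BRAIN"),
    !!!stats::setNames(as.data.frame(rbind(
      c(120, 80, 0, 0, 0, 0, 0, 0),    # bone marrow + spleen only
      rep(50, 8),                      # flat
      c(0, 0, 0, 0, 0, 0, 200, 0)      # single non-lymphoid tissue
    )), tissues)
  )
  ct <- tibble::tibble(gene_symbol = rep(c("LYMPH", "UBIQ", "BRAIN"), 2),
                       celltype = rep(c("t_cell_cd4", "b_cell"), each = 3),
                       frac_expressing = 0, mean_expr = 0)
  atlas <- expression_atlas(tm, ct,
                            lymphoid_tissues = tissues[1:6],
                            excluded_celltypes = "t_cell_cd4")
  surv <- tibble::tibble(protein_id = c("P1", "P2", "P3"),
                         gene_symbol = c("LYMPH", "UBIQ", "BRAIN"),
                         n_pdx_detected = 3L, mean_log2fc = 3)
  out <- lymphoid_specificity_filter(surv, atlas, triage_params())
  expect_setequal(out$gene_symbol, "LYMPH")
  scores <- attr(out, "scores")
  expect_equal(scores$tau[scores$gene_symbol == "UBIQ"], 0)
  expect_equal(scores$tau[scores$gene_symbol == "BRAIN"], 1)
  expect_false(scores$passes_specificity[scores$gene_symbol == "BRAIN"])
})

test_that("planted archetypes pass/fail the tissue stage per truth labels", {
  cohort <- generate_cohort(cohort_config(n_proteins = 400, seed = 20))
  truth <- cohort$truth
  surv <- tibble::tibble(
    protein_id = truth$protein_id[truth$is_surface],
    gene_symbol = truth$gene_symbol[truth$is_surface]
  )
  surv$n_pdx_detected <- 6L
  surv$mean_log2fc <- 3
  out <- lymphoid_specificity_filter(surv, cohort$atlas, triage_params())
  arch <- truth$tissue_archetype[match(out$protein_id, truth$protein_id)]
  lr <- truth$protein_id[truth$is_surface &
                           truth$tissue_archetype == "lymphoid_restricted"]
  snl <- truth$protein_id[truth$is_surface &
                            truth$tissue_archetype == "single_nonlymphoid"]
  ubi <- truth$protein_id[truth$is_surface &
                            truth$tissue_archetype == "ubiquitous"]
  expect_true(all(lr %in% out$protein_id))
  expect_false(any(snl %in% out$protein_id))
  expect_false(any(ubi %in% out$protein_id))
})

test_that("cell-type exclusion drops genes expressed in excluded types", {
  ct <- tibble::tibble(
    gene_symbol = rep(c("GA", "GB"), each = 2),
    celltype = rep(c("t_cell_cd4", "b_cell"), 2),
    frac_expressing = c(0.40, 0.6, 0, 0.7),
    mean_expr = 1
  )
  tm <- tibble::tibble(gene_symbol = c("GA", "GB"), bone_marrow = 10,
                       brain = 0)
  atlas <- expression_atlas(tm, ct, lymphoid_tissues = "bone_marrow",
                            excluded_celltypes = "t_cell_cd4")
  surv <- tibble::tibble(protein_id = c("PA", "PB"),
                         gene_symbol = c("GA", "GB"),
                         n_pdx_detected = 3L, mean_log2fc = 3, tau = 1)
  out <- celltype_exclusion(surv, atlas, triage_params())
  expect_setequal(out$gene_symbol, "GB")
  fr <- attr(out, "excluded_fracs")
  expect_equal(fr$max_excluded_frac[fr$gene_symbol == "GA"], 0.40)
  expect_equal(fr$max_excluded_frac[fr$gene_symbol == "GB"], 0)
})

test_that("t_cell archetype proteins are always excluded at the cell-type stage", {
  cohort <- generate_cohort(cohort_config(n_proteins = 300, seed = 21))
  truth <- cohort$truth
  tcell <- truth[truth$tissue_archetype == "t_cell", ]
  surv <- tibble::tibble(protein_id = tcell$protein_id,
                         gene_symbol = tcell$gene_symbol,
                         n_pdx_detected = 6L, mean_log2fc = 3, tau = 0.9)
  out <- celltype_exclusion(surv, cohort$atlas, triage_params())
  expect_equal(nrow(out), 0L)
})

test_that("dotplot statistics come from summaries or raw vectors", {
  raw <- list(t_cell = c(0, 0, 0, 0), b_cell = c(0, 0, 2, 4))
  out <- dotplot_stats(NULL, "any", raw = raw)
  expect_equal(out$frac_expressing, c(0, 0.5))
  expect_equal(out$mean_expr, c(0, 3))

  # summaries computed from raw, stored, then looked up round-trip
  stored <- tibble::tibble(gene_symbol = "G1", celltype = out$celltype,
                           frac_expressing = out$frac_expressing,
                           mean_expr = out$mean_expr)
  back <- dotplot_stats(stored, "G1")
  expect_equal(back$frac_expressing, out$frac_expressing)
  expect_equal(back$mean_expr, out$mean_expr)
  expect_error(dotplot_stats(stored, "NOPE"), "not found")
})

test_that("ranking handles degenerate z-scores and breaks ties by symbol", {
  ann <- fake_annotations(c("PX", "PY"))
  single <- tibble::tibble(protein_id = "PX", gene_symbol = "G_PX",
                           n_pdx_detected = 4L, mean_log2fc = 3, tau = 0.9,
                           max_excluded_frac = 0)
  r1 <- rank_candidates(single, ann)
  expect_equal(r1$rank_score, 0)
  expect_equal(r1$rank, 1L)

  twins <- tibble::tibble(protein_id = c("PY", "PX"),
                          gene_symbol = c("G_PY", "G_PX"),
                          n_pdx_detected = 4L, mean_log2fc = 3, tau = 0.9,
                          max_excluded_frac = 0)
  r2 <- rank_candidates(twins, ann)
  expect_equal(r2$gene_symbol, c("G_PX", "G_PY"))
})

test_that("stronger planted targets outrank borderline ones", {
  ann <- fake_annotations(c("STRONG", "WEAK"))
  surv <- tibble::tibble(
    protein_id = c("STRONG", "WEAK"),
    gene_symbol = c("G_STRONG", "G_WEAK"),
    n_pdx_detected = c(6L, 3L),
    mean_log2fc = c(3.2, 2.1),
    tau = c(0.97, 0.82),
    max_excluded_frac = c(0.0, 0.05)
  )
  r <- rank_candidates(surv, ann)
  expect_equal(r$protein_id[1], "STRONG")
  expect_gt(r$rank_score[1], r$rank_score[2])
})

test_that("cascade flags are nested and the waterfall is monotone", {
  withr::with_seed(30, {
    for (i in 1:8) {
      cfg <- cohort_config(
        n_proteins = sample(60:150, 1),
        n_pdx = sample(2:4, 1),
        n_true_targets = sample(0:8, 1),
        n_decoy_tcell = sample(0:3, 1),
        n_decoy_myeloid = sample(0:3, 1),
        n_decoy_single_nonlymphoid = sample(0:3, 1),
        n_decoy_ubiquitous = sample(0:3, 1),
        noise_sigma = runif(1, 0.2, 0.8),
        missing_censor_quantile = runif(1, 0, 0.3),
        detect_dropout_rate = runif(1, 0, 0.3),
        seed = sample.int(1e6, 1)
      )
      cohort <- generate_cohort(cfg)
      calls <- call_surface_cohort(cohort, call_params(seed = i))
      tri <- prioritize_candidates(calls, cohort$annotations, cohort$atlas,
                                   triage_params(min_pdx = min(3, cfg$n_pdx)))
      wf <- attr(tri, "waterfall")
      expect_true(all(diff(wf$n) <= 0))
      expect_true(all(!tri$membrane | tri$surface_any))
      expect_true(all(!tri$prevalent | tri$membrane))
      expect_true(all(!tri$lymphoid_specific | tri$prevalent))
      expect_true(all(!tri$not_excluded | tri$lymphoid_specific))
    }
  })
})
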