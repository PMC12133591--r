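Package: surfacer
Title: Surfaceome-Based Discovery and Triage of CAR Target Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for cell-surface proteomics (surfaceome)
    screens that nominate chimeric antigen receptor (CAR) target antigens
    from biotinylation-enrichment mass-spectrometry experiments on
    patient-derived samples. Per-sample surface-detection calls are made by a
    moderated two-sample test of biotinylated against non-biotinylated runs
    with a pooled permutation null and Benjamini-Hochberg false-discovery
    control, after median normalization and downshifted-Gaussian imputation
    of left-censored missing intensities; a specific-peptide-count detection
    rule is available as an alternative or complementary criterion.
    Candidates are then triaged through a staged cascade: membrane
    annotation, cross-sample prevalence, lymphoid tissue-specificity (tau
    index), and cell-type exclusion (T cells, granulocytes, hematopoietic
    stem cells), ending in a ranked candidate table with a stage-count
    waterfall. A synthetic-cohort generator with planted surface targets,
    archetypal tissue and cell-type expression profiles, and
    intensity-dependent missingness makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
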