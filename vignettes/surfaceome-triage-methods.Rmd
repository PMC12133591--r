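---
title: "Methods: surfaceome-based CAR-target discovery and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surfaceome-based CAR-target discovery and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfacer)
```

## The problem

Chimeric antigen receptor (CAR) T-cell therapy needs a surface antigen that
is present on the tumor and absent, or nearly so, from tissues and cell
types whose loss a patient cannot tolerate. Transcript abundance is a poor
proxy for surface exposure, so a direct route is cell-surface proteomics:
intact cells are chemically biotinylated, surface proteins are enriched on
an avidin resin, and label-free quantitative mass spectrometry compares
biotinylated runs (`biot`) with non-biotinylated background controls
(`nb`). A protein genuinely exposed on the surface is *enriched* in the
biot runs; everything downstream of that call is a safety triage.

`surfacer` implements that analysis as a tested pipeline over tabular
data: per-sample protein quant tables in, ranked candidate antigens out.
The intended design matches a multi-sample leukemia screen:
patient-derived xenograft (PDX) samples, each measured in 4 biotinylated
technical replicates and 2 non-biotinylated controls.

## Per-sample surface calling

### Normalization and imputation

Intensities are analyzed on the log2 scale. Each run is shifted so its
median over observed values equals the grand median of the runs'
pre-normalization medians; this removes loading differences without
touching missing cells.

Label-free data are left-censored: low-abundance proteins drop below the
detection limit. Missing cells are therefore imputed from a
downshifted Gaussian, the standard treatment for censored LFQ values: a
missing cell in run $r$ is drawn from

$$\mathcal{N}\!\left(\mu_r - d\,\sigma_r,\ (w\,\sigma_r)^2\right)$$

where $\mu_r,\sigma_r$ are the run's observed mean and standard deviation,
with downshift $d = 1.8$ and width $w = 0.3$ (in units of the run SD).
These are the conventional defaults for this imputation family; both are
exposed in `call_params()`. Imputation is applied to both conditions and
is seeded, so a fixed seed reproduces the imputed table exactly. A run
needs at least two observed values (otherwise $\sigma_r$ is undefined and
the function stops).

### The moderated enrichment test

For each protein the contrast is a moderated Welch statistic

$$t = \frac{\bar{x}_{\mathrm{biot}} - \bar{x}_{\mathrm{nb}}}
        {\sqrt{s^2_{\mathrm{biot}}/n_{\mathrm{biot}} +
               s^2_{\mathrm{nb}}/n_{\mathrm{nb}}} + s_0}$$

with $s_0 = 0.1$ by default. The constant damps statistics that are large
only because two or four replicates happened to agree closely — the classic
failure mode of per-protein t-tests at this replicate count. With
$s_0 = 0$ and complete data the statistic reduces exactly to the classical
Welch t, and the test suite asserts that closed form.

Significance comes from a permutation null over relabelings of the runs
into groups of the original sizes. For the 4-vs-2 design there are exactly
$\binom{6}{4} = 15$ distinct relabelings; whenever the count is at most
1000 all of them are enumerated, so p-values are exact and deterministic.
Larger designs fall back to `n_perm` seeded random relabelings.

A design decision worth spelling out: the null **pools the permuted
statistics across all proteins** of the table, rather than comparing each
protein only with its own 14 non-observed relabelings. A per-protein null
at this design size has resolution $1/15 \approx 0.067$, which makes any
5% false-discovery threshold unreachable in principle — no protein,
however enriched, could ever clear it. Pooling is legitimate here because
$s_0$ makes the statistics comparable across proteins, and it is precisely
how randomization-based FDR procedures in the proteomics tools this
pipeline emulates obtain sub-$1/R$ resolution. The observed labeling is
excluded from the pool (the null holds permuted statistics only);
otherwise every strongly enriched protein would inflate the null tail for
all the others. Ties count toward the null and p is floored at one over
the pool size, so it is conservative and never zero. q-values are
Benjamini–Hochberg over these pooled p-values within the sample.

### Detection rules

`detected` is configurable through `mode`:

* `"intensity"` (default): $q \le 0.05$, $\log_2\mathrm{FC} \ge 1$, and at
  least 3 of the biot runs quantified before imputation;
* `"peptide"`: at least 2 specific peptides in at least 3 biot runs *and*
  at most 1 peptide in every nb run — the evidence pattern a
  specific-peptide table displays for a genuine surface protein;
* `"either"`: the disjunction.

The intensity route is the default because it is the quantitative,
FDR-controlled reading; the peptide rule is kept as a first-class
alternative because peptide-count evidence is how such calls are commonly
displayed and audited.

## The triage cascade

Stages run in fixed order, each only on survivors of the previous one, so
stage flags are nested and the stage-count waterfall is non-increasing:

1. **surface_any** — detected in at least one PDX sample;
2. **membrane** — annotated membrane-associated. Detected proteins missing
   from the annotation table are treated as non-membrane but reported,
   never silently dropped;
3. **prevalent** — detected in at least `min_pdx` samples (default 3 of
   6). The boundary is sharp: 3 of 6 is retained, 2 of 6 is not;
4. **lymphoid_specific** — tissue-specificity against a gene-by-tissue
   expression matrix (nTPM-like units). Four conjuncts, each toggleable:
   the tau index $\tau = \sum_i (1 - x_i/\max_j x_j)/(T-1) \ge 0.8$; the
   top tissue is lymphoid (bone marrow, spleen, blood, lymph node, thymus,
   tonsil by default); the lymphoid-to-non-lymphoid fold
   $\max_{\mathrm{lym}} / (\max_{\mathrm{nonlym}} + \varepsilon) \ge 4$;
   and $\max_{\mathrm{nonlym}} \le 10$. Tau is 0 for uniform expression, 1
   for single-tissue expression, and scale-invariant; it is undefined
   (an error for the scalar function, an automatic fail inside the filter)
   for an all-zero profile;
5. **not_excluded** — the codified form of manual curation: a candidate is
   dropped if its fraction of expressing cells exceeds 10% in any excluded
   cell type. T-cell subsets and granulocytes are excluded because CAR
   killing of those populations is self-defeating or dangerous;
   hematopoietic stem cells are in the default exclusion set too but can
   be toggled out, since their status as a formal criterion versus a
   post-hoc check is a judgment call.

Survivors are ranked by a sum of within-survivor standard scores,
$z(\text{samples detected}) + z(\text{mean log2FC}) + z(\tau) -
z(\text{max excluded-cell fraction})$; a zero-variance component
contributes 0 and ties break lexicographically by gene symbol, so the
ordering is fully deterministic. The thresholds above quantify a published
qualitative procedure whose exact database criteria were not stated; all
of them are exposed in `triage_params()` with these documented defaults.

## The synthetic cohort generator

Real screens of this kind cannot be re-run at desk scale, so
`generate_cohort()` produces cohorts with the statistical structure the
pipeline assumes, plus ground truth for evaluation:

* log2 intensities are protein baseline
  $\mathcal{N}(\mu_b = 25, \sigma_b = 2)$ plus condition effect plus run
  noise $\mathcal{N}(0, 0.5)$ — the log-normal behaviour LFQ pipelines
  assume;
* planted surface proteins gain $+3$ log2 units in biot runs of each PDX
  they are planted in; each PDX is skipped independently with probability
  0.15 (`detect_dropout_rate`), emulating sample-to-sample heterogeneity;
* missingness is left-censored: per run, cells below the 20% quantile of
  the run's noise-free intensity distribution are missing (never zero —
  zero-versus-missing ambiguity is a classic pitfall this dialect refuses
  to create). Setting the quantile to 0 disables censoring entirely;
* specific-peptide counts are Poisson with rate proportional to
  linear-scale intensity, capped at 30 and zero when the cell is missing.
  Only threshold logic consumes the counts, so the exact law is a
  convenience, not a claim;
* tissue and cell-type profiles follow archetypes: lymphoid-restricted
  (constructed so tau is always at least 0.8), T-cell, myeloid,
  ubiquitous, single non-lymphoid tissue, and silent (all-zero, which
  exercises the undefined-tau path). Besides the 20 true
  lymphoid-restricted targets, the default cohort plants 5 enriched decoys
  of each of four archetypes so that every later triage stage has
  something real to reject — T-cell and myeloid decoys must fall at the
  cell-type stage, ubiquitous and single-tissue decoys at the tissue
  stage;
* one global seed drives a per-PDX derived stream (`seed + pdx_index`), so
  adding a sample never perturbs earlier ones, and identical
  configurations are byte-identical end to end.

What the generator does **not** emulate: correlated protein abundances,
batch effects, shared-peptide/protein-inference ambiguity,
match-between-runs artifacts, or real annotation noise. Passing tests
therefore demonstrate that the statistical machinery behaves as specified
under its own assumptions, not that any particular real dataset would
yield a particular candidate list.

## Numerical choices and edge cases

* Permutation p-values: enumeration whenever the relabeling count is at
  most 1000; tie counting is conservative; minimum p is one over the pool
  size; two-sided throughout via $|t|$.
* Normalization errors on a run with no observed values; imputation on a
  run with fewer than two.
* An all-zero tissue profile fails specificity rather than crashing the
  cascade; genes missing from the tissue matrix or the annotation table
  are reported (`unresolved`, `unannotated` attributes), not silently
  dropped.
* Detection (`n_biot_quantified`) counts pre-imputation observations, so
  imputed values can never satisfy the quantification-coverage criterion
  on their own.

## Problem sizes used by the test suite

Unit tests run on cohorts of 40–600 proteins and 1–6 samples. The
statistical validation uses the full design size: the brute-force
permutation oracle on 50-protein fixtures; type-I calibration on ten null
cohorts of 2000 proteins by 6 PDX; imputation-law checks on 150,000
draws; 100 randomized cohorts for cascade-invariant fuzzing; and ten
default cohorts (2000 proteins, 20 targets, 20 decoys, 6 PDX) for
end-to-end recovery. These sizes were chosen to estimate each quantity
with comfortable Monte-Carlo error while keeping the suite quick to run.

## Known limitations

* With 4-vs-2 replicates, two control runs give a 1-degree-of-freedom
  variance estimate; even with moderation, per-sample detection power at a
  5% FDR is intrinsically limited for 8-fold planted enrichment at run
  noise 0.5 — under those default simulation conditions the end-to-end
  pipeline recovers roughly two-thirds of planted targets (with
  essentially no false discoveries), and recovery rises quickly with lower
  noise, larger effects, or more control replicates.
* The cascade reproduces a procedure's *shape* (broad detection, then
  membrane, prevalence, tissue, cell-type stages with shrinking counts);
  reproducing any published candidate list would additionally require the
  original raw data and version-pinned annotation and atlas snapshots.
* Purely literature-based curation judgments are out of scope by design;
  the report surfaces the evidence (dot-plot statistics per candidate) for
  a human to act on.
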