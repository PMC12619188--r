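---
title: "Methods: first-trimester metabolomics biomarker discovery for GDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-trimester metabolomics biomarker discovery for GDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

`metabogdm` implements a complete discovery pipeline for untargeted LC-MS
plasma metabolomics in a nested case-control pregnancy cohort: 50 women who
later develop gestational diabetes mellitus (GDM) and 50 who remain
normoglycemic, group-matched on age and pre-pregnancy BMI, profiled in
early pregnancy across three acquisitions (polar metabolites, non-polar
positive mode, non-polar negative mode). The outcome label is the OGTT
diagnosis at 24--28 weeks; the scientific question is whether
early-pregnancy metabolite abundances predict it.

The pipeline assumes the usual working model for peak-area data: abundances
are approximately log-normal per metabolite, with technical variability
quantified by repeated injections of a pooled-QC sample, batch-level
location/scale distortions, and two missingness mechanisms —
limit-of-detection left-censoring (MNAR) and random dropout (MCAR).

## Preprocessing

Stages run in a fixed order per acquisition dataset, then the three
datasets are merged:

1. **Pooled-QC RSD filter.** RSD = 100·SD/mean across QC injections
   (sample SD, n−1). Metabolites with RSD strictly above 20% have their
   biological values nulled; exactly 20% passes. A zero QC mean yields an
   infinite RSD and always fails. RSDs are pooled over all QC injections
   of a dataset rather than computed per batch; with three batches and ten
   injections a per-batch RSD would rest on three values, and the pooled
   estimate is the dominant QC convention.
2. **Missingness filter.** Metabolites missing in strictly more than 40%
   of biological samples are removed (so RSD-nulled columns leave here,
   which keeps the stage ledger additive:
   input = nulled + dropped + retained).
3. **Half-minimum imputation** on the raw scale, before the log
   transform: each missing cell receives half the metabolite's minimum
   observed value, a limit-of-detection surrogate matched to the
   left-censoring mechanism.
4. **Log transform** `ln(x + 1)`; the +1 keeps zeros finite. The log base
   is a monotone choice; downstream rank-based quantities are unaffected.
5. **Batch correction** by parametric empirical-Bayes location/scale
   adjustment (ComBat, via the sva package). The case/control label is
   protected as a model covariate by default so that genuine group
   differences are not absorbed into batch estimates; an unprotected mode
   reproduces the plain default. A single batch is a no-op. Designs in
   which the label is *perfectly* confounded with batch are rejected by
   the rank check of the underlying model — no location/scale adjustment
   can separate batch from group in that case, and the error is
   surfaced rather than silently absorbed.
6. **Standardization** to zero mean, unit variance (n−1 SD); constant
   metabolites are dropped with a warning.
7. **PCA** on the standardized matrix for inspection, with metabolites
   ranked by absolute loading on a chosen component.
8. **Merge** by inner join on (batch ID, sample ID); name collisions
   across datasets get a dataset-of-origin suffix.

Boundary semantics are strict on purpose (RSD > 20 nulled, missing > 40%
dropped): both rules are stated as strict inequalities in the field's
usual phrasing, and the tests pin the boundary cases (20.00 retained,
20.01 nulled; 40/100 retained, 41/100 dropped).

## Univariate association

One logistic regression per standardized metabolite (outcome ~ metabolite,
optionally + covariates such as parity for sensitivity analyses), with
Wald SEs, symmetric 95% CIs and two-sided p values, adjusted across
metabolites by Benjamini-Hochberg. The reported `estimate` is the log-odds
coefficient per 1 SD of the metabolite; the odds ratio `exp(estimate)` is
a separate field — coefficient-scale values such as −0.40 cannot
themselves be odds ratios, and the symmetric CIs bracket the coefficient.
Separated or non-converged fits are flagged and excluded from the FDR
ranking rather than reported with meaningless Wald SEs.

Associations between metabolites and continuous clinical variables
(OGTT glucose values, HbA1c, BMI and the like) use per-pair ordinary least
squares with BH-FDR within each clinical variable; direction is the slope
sign when the FDR p is below α, `no-change` otherwise. The association
method for this display is a design choice (correlation, regression and
group contrasts all plausibly fit the study's display); OLS was chosen
because it handles the continuous outcomes directly and its t test is
exactly the correlation test in the single-predictor case.

## Panel discovery

The discovery procedure mirrors the repeated-split random forest design:

- **Splits.** Ten stratified 70/30 train/test partitions, seeded
  per-iteration.
- **Tuning.** Inside each training subset only: stratified 10-fold CV
  over a grid of `mtry` ∈ {⌊√p⌋, ⌊p/3⌋, ⌊p/2⌋} and `ntree` ∈ {250, 500,
  1000} (the grid dimensions are fixed, the candidate values are package
  defaults), maximizing mean inner-CV AUC; ties take the first grid point
  in (mtry, ntree) order.
- **Ranking.** Permutation importance of the tuned forest (Gini impurity
  available as an option); ties break by metabolite name. Each iteration
  re-ranks on its own training subset.
- **Candidates.** Top-k panels for k = 1..10 per iteration, pooled across
  iterations with identical member sets merged. Top-k construction is the
  package's documented choice for "panels constructed from rankings";
  exhaustive small-k search is available.
- **Bootstrap stability.** Every candidate is refit on B stratified
  resamples with replacement and evaluated on the out-of-resample
  samples (resubstitution would report SD ≈ 0 and defeat the stability
  rule); sensitivity/specificity/accuracy/F1 are taken at the
  Youden-optimal threshold of each resample's out-of-resample ROC.
  Within each panel size the candidate with the lowest bootstrap AUC-SD
  is flagged most stable (SD ties → higher mean AUC → name order), and
  the final panel is the flagged candidate with the highest bootstrap
  mean AUC (ties → smaller panel → name order).
- **Headline ROC.** A logistic model on the final panel over the full
  cohort, summarized with AUC, DeLong 95% CI, and Youden-point
  sensitivity/specificity.
- **Permutation test.** Labels shuffled P times with the full modeling
  metric recomputed per shuffle; the empirical p uses the add-one
  convention (1 + #{null ≥ observed})/(1 + P), which is never zero.

Implementation note: the B bootstrap refits of a panel are realized as
blocks of trees inside larger ranger forests sharing one resample per
block (ranger's `inbag` interface). This is the same estimator as B
separate forest fits — each block of trees sees exactly one resample —
at roughly a tenth of the call overhead, which is what makes
1000-replicate validation of dozens of candidate panels tractable on one
CPU.

## Clinical models

Three logistic prediction models reproduce the conventional-versus-
integrated comparison: model 1a (age, pre-pregnancy BMI, family history
of diabetes, venous HbA1c), model 1b (waist-to-height ratio substituted
for BMI), and model 1c (1b covariates plus the selected metabolite
panel). The study's description of the covariate sets is internally
inconsistent between the text and the figure captions, so the covariate
lists are fully configurable and the package's defaults are the sets
above. Models are compared on the identical complete-case sample
intersection, with in-sample (apparent) ROC and DeLong CIs matching the
reporting style of the comparison; a cross-validated AUC is available
via `cv_auc_metric()` for honest out-of-sample estimates. Note that
in-sample AUC of nested logistic models is not strictly monotone (the
fit maximizes likelihood, not AUC), so comparisons should read AUC
differences below ~0.01 as noise.

## Pathway enrichment

Over-representation is tested per pathway with the one-sided Fisher exact
test on the 2×2 table (k, n−k, K−k, N−K−n+k), which is identical to the
hypergeometric upper tail — the two names under which this test is
usually reported. The background universe defaults to all measured
metabolites that carry a compound ID (configurable). Annotations come
from local KEGG-style tables (TSV: pathway id, name, member compounds);
no live KEGG access is performed, keeping runs network-free and
version-pinned. The study's enrichment p values depend on the KEGG snapshot
and an unstated universe and are therefore not recomputable; the suite
instead tests null calibration and planted-pathway recovery.

## The synthetic cohort generator

Because no raw data are deposited, the generator is the package's study
stand-in, and its defaults are the study conditions: 50 cases / 50
controls; 651 metabolites split 151/300/200 across polar, non-polar
positive and non-polar negative datasets; 3 batches assigned round-robin
(label-balanced by construction); 10 pooled-QC injections per dataset;
technical CVs drawn uniformly on (0.05, 0.40), which straddles the 20%
RSD threshold and yields an expected pass fraction of ~0.43 — the same
shape as the study's 651 → 278 QC attrition; left-censoring below each
metabolite's 5% quantile plus 2% MCAR dropout; 49 effect metabolites, of
which a strong subset of 8 carries a 1.0-SD log-scale shift and the rest
draw shifts uniformly from (0.4, 1.1) — the coefficient range of the
study's reported per-metabolite estimates, used as a calibration choice since
standardized effect sizes are not otherwise reported. Clinical covariates
are drawn from the study's per-arm moments (age 26/27 ± 2.4/2.6, BMI
22.8/23.8, family history 40%/54%, OGTT shifts in the case arm, etc.);
age and BMI are *matched* draws — case values reuse permuted control
draws rescaled to the case arm's moments — so the realized group
difference equals the configured difference without sampling noise,
emulating the matched selection design. Shift magnitudes are Cohen's-d
style: expressed in units of the metabolite's within-group log-SD.

What the generator does **not** emulate: correlated metabolite blocks
(lipid co-regulation), retention-time drift within batches, heteroscedastic
technical error, non-log-normal heavy tails, or any real biochemical link
between the clinical covariates and the metabolome. Passing recovery
tests therefore demonstrates that the machinery finds the signals it is
pointed at under the assumed noise model — not that the study's reported panel
is biologically right.

`generate_pathway_db()` builds a local annotation table whose first
pathway contains a planted compound set (so enrichment recovery is well
defined) and whose remaining pathways sample the universe uniformly.

## Numerical choices and test scales

- Sample-SD (n−1) convention throughout (RSD, standardization).
- AUC in resampling loops is the rank-form Mann-Whitney statistic with
  ties counted half; it is asserted against brute-force pair counting and
  against pROC. ROC curves and CIs (DeLong) come from pROC.
- The Youden threshold scans midpoints between adjacent distinct scores;
  J ties resolve toward higher sensitivity, then the lower threshold.
  With constant scores every sample is called positive, which keeps F1
  defined.
- Stage seeds derive from one global seed by fixed offsets, so each stage
  is independently reproducible and forests are fit with `num.threads = 1`
  for bit-reproducibility.
- The test suite runs the full designs at desk scale: bootstrap B = 200
  with 16-tree refits in the 20-seed recovery suite, P = 99/199
  permutations with a logistic CV-AUC metric in the calibration suite,
  500 all-null cohorts of 100 × 200 for FDR control. These replicate
  counts are the package's chosen test problem sizes; the production
  defaults (B = 1000, P = 1000, 100-tree refits) are what `run_pipeline()`
  uses unless configured otherwise.

## Known limitations

- The univariate screen feeds panel discovery in `run_pipeline()` (the
  study design fits forests on the significant set); with weak
  signals and small cohorts the screen is the power bottleneck, and
  `discover_panels()` can equally be run on the full standardized matrix.
- Bootstrap and permutation loops are sequential; runtimes scale linearly
  in B, P and candidate count.
- The enrichment layer maps metabolites to pathways by compound ID only;
  name-to-ID resolution is out of scope.
- The study's headline numbers that depend on the undeposited raw data
  (significant-metabolite count, specific AUC values, enrichment p
  values) are design targets for the machinery, not reproducible
  quantities; the synthetic cohort reproduces their *shape* (QC
  attrition fraction, optimism gap direction, clinical < integrated AUC
  ordering), which is what the acceptance checks assert.
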