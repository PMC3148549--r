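---
title: "Predicting severe asthma exacerbations from genome-wide SNPs with random forests"
author: "snpforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting severe asthma exacerbations from genome-wide SNPs with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpforest)
```

## The problem

Severe asthma exacerbations — emergency-room visits or hospitalizations for
asthma — are a binary clinical outcome that is hard to predict from clinical
traits alone. In a cohort of childhood asthmatics, about 30% of children
experience at least one severe exacerbation during follow-up, and the four
routinely available covariates (age, sex, pre-bronchodilator FEV1 percent
predicted, and treatment group) each explain only a small part of the risk.
The working hypothesis behind this package is that risk is polygenic: many
SNPs of individually small effect, plus the clinical traits, jointly carry
usable signal, and an ensemble learner that tolerates hundreds of weak,
possibly interacting predictors can extract it where single-marker
regression cannot.

`snpforest` implements that analysis end to end: genome-wide random-forest
(RF) screening of SNPs by variable importance, top-k SNP + clinical-trait
forest models scored by tree vote fractions, two null controls, a
control-frequency imputation rule for missing genotypes, and rank-statistic
ROC/AUC evaluation with significance against chance. Because the motivating
cohort's genotypes are not publicly available, the package also ships a
synthetic two-stage cohort generator so the whole pipeline runs, and is
tested, at desk scale.

## Data model

The central container is `GwasCohort`, a `SummarizedExperiment` whose
`"genotype"` assay is a SNPs x samples matrix of minor-allele counts
(0/1/2, `NA` = missing call), whose `rowData` carries the SNP metadata
(identifier, chromosome 1–22/X, base-pair position, and the two alleles),
and whose `colData` carries the binary outcome and the four clinical
covariates. Two conventions matter:

* **Additive coding.** Genotypes enter the forests as counts of the minor
  allele. The counted allele is the empirically minor one among non-missing
  calls, with exact-tie conflicts resolved to the lexicographically smaller
  allele; a SNP where only one allele is ever observed has an unknowable
  second allele, recorded as `"0"` (the missing-allele placeholder of the
  PLINK text dialect) and an all-zero column. This canonical orientation
  makes `writePedMap()`/`readPedMap()` an exact round trip.
* **Chromosomal order.** SNPs are stored chromosome-block by
  chromosome-block with non-decreasing positions; the stage-1 screening
  scan chunks the panel in this order.

Files are read and written in the PLINK 1.x text dialect (.ped/.map), with
the phenotype in .ped column 6 (1 = control, 2 = case) and covariates in a
separate header CSV/TSV. Covariates are validated, never imputed; only
genotypes are ever imputed.

## Two-stage importance screening

With hundreds of thousands of SNPs, one forest over the whole panel is
neither computable nor statistically sensible at a few hundred samples.
The screening procedure is therefore two-staged:

1. **Chunked scan** (`chunkedImportanceScan`): the panel is partitioned
   into consecutive chunks of 4,000 SNPs in chromosomal order; one forest
   is fitted per chunk with that chunk's SNPs as the only predictors, and
   every SNP's importance score is recorded. Scores from different chunks
   are compared on their raw scale to form one global ranking — this
   mirrors the original procedure and is a pragmatic device, not a claim
   that importance scales are exactly exchangeable across chunks.
2. **Re-ranking** (`rerankTop`): the global top 4,000 SNPs are refitted in
   one joint forest and re-ranked by its importance; `selectTop` then takes
   the top k.

Screening uses SNPs only; the clinical covariates enter at the prediction
stage. Were they included during screening, their (real) signal would
compete with every SNP in every chunk and the selected panel would no
longer reflect marginal SNP utility.

The importance measure defaults to the mean decrease in Gini impurity —
what the RF implementation reports without extra options — with out-of-bag
permutation importance available via
`rfControl(importanceMeasure = "permutation")`. Forest defaults follow the
study protocol: `ntree = 1500`, `mtry = floor(sqrt(p))`.

**Determinism.** Every stochastic step draws its seed from a master seed
through a fixed linear-congruential mix (`chunk i` uses stream `i`, the
stage-2 refit a reserved stream), so results are bit-reproducible and
independent of how the scan is split across calls. Rank ties break by
stage-1 score and then chromosomal position, never by memory order.

## Prediction models and evaluation

`buildPredictionModel` fits a forest over the selected SNP columns plus,
by default, the four clinical covariates (sex and treatment enter as
fixed-level factors; age and FEV1% as numerics). The per-sample prediction
score is the fraction of trees voting "case" (`predictScores`), a value in
[0, 1] with granularity 1/ntree. Three AUCs are reported per model size by
`runSnpLadder` over the ladder k in {10, 40, 160, 320} (plus the
clinical-only model, k = 0):

* **training** — resubstitution on the Stage 1 samples;
* **internal cross-validation** — one stratified 90/10 split per seed
  (stratification keeps both outcome classes in a 10% fold at n in the
  hundreds with ~30% cases; a repeat count is configurable because a single
  split is noisy);
* **independent replication** — fit on all of Stage 1, scored on Stage 2.

Missing Stage 2 genotypes are imputed per SNP by drawing from the genotype
frequency distribution observed among the *non-exacerbation Stage 1
(control) samples* (`imputeMissingFromControls`); the same rule fills any
Stage 1 missingness before screening, since the trees accept no missing
values. A SNP with no non-missing control calls falls back to pooled
training frequencies with a warning. Imputation never touches an observed
call.

ROC/AUC machinery is rank-based: AUC = P(case score > control score) +
half-credit for ties, identical (to 1e-12) to the trapezoidal area under
the tie-grouped ROC curve. The p-value against AUC = 0.5 uses the normal
approximation to the Mann-Whitney statistic under the null, with tie
correction and a continuity correction of half a discrete step — at the
small replication sizes this analysis targets, the uncorrected
approximation visibly disagrees with the exact permutation distribution,
which is available as `aucPvalue(method = "permutation")` (exhaustive at
small n, Monte-Carlo beyond). The standard error reported alongside the
point estimate is Hanley–McNeil.

`operatingPoint` applies Bayes' rule at a (sensitivity, specificity,
prevalence) triple. At (0.20, 0.95, 0.30) it gives NPV = 0.735 and
PPV = 0.632. Note that a PPV of 0.81 sometimes quoted for this operating
point is not consistent with Bayes' rule (it would require specificity
around 0.98); the package implements the formula and documents the
discrepancy rather than reproducing it.

## Null controls

Two controls calibrate the pipeline (`permutationControl`,
`randomSnpControl`), each iterated 10 times by default:

* the **permutation control** shuffles the training outcome labels while
  keeping every predictor attached to its sample, then — by default —
  re-runs the *entire* selection (chunked scan, re-ranking, top-k) on the
  permuted labels before building and scoring the model on the untouched
  replication set. Re-running selection inside the null is essential:
  reusing SNPs selected on the real labels would leak selection signal
  into the "null" and bias it above 0.5. The cheaper variant is available
  via `reuseSelection = TRUE`.
* the **random-SNP control** keeps the true labels but replaces the
  selected panel with k SNPs drawn uniformly from the whole panel. With
  informative clinical covariates in the model its AUC sits slightly above
  0.5 — that residual signal is the covariates', not the SNPs'.

## The synthetic cohort generator

`simulateCohort` emulates the two-stage study design: a training stage
(default n = 417, the size of the motivating trio-proband cohort) and an
independent replication stage (default n = 164) drawn from one generative
law over a shared SNP panel.

* **Genotypes**: independent SNPs in Hardy–Weinberg equilibrium, MAF drawn
  uniformly per SNP from a configurable range, laid out in 22 chromosome
  blocks. An optional block-copy LD mode was considered and rejected:
  screening behaviour under LD is interesting but not asserted anywhere in
  the validation suite, and independent SNPs keep every null calibration
  argument exact.
* **Covariates**: age ~ Normal(8.7, 2.1) truncated above 5 years;
  FEV1% ~ Normal(93.3, 14) truncated above 40; sex 1/2 with 63% male;
  treatment uniform on {1, 2, 3}. These are the pooled case/control
  moments of the motivating cohort's baseline table.
* **Outcome**: logistic in the minor-allele counts of the planted causal
  SNPs (log-odds per allele), optional pairwise product terms for
  epistasis, and linear terms in the raw coded covariates. The intercept
  is calibrated by bisection so the expected case fraction hits the 30%
  target within 0.005; calibration failure (unreachable prevalence under
  extreme effects) is an error, not a silent miss. Default covariate
  effects are small and direction-matched to the baseline table (cases
  younger, more often male, lower FEV1, more often on placebo), so a
  clinical-only model scores slightly above chance — mirroring the weak
  clinical-trait signal the real analysis reports.
* **Missingness**: completely at random per cell at a configurable rate.
  Because removing calls can shift an empirical allele frequency across
  the 0.5 boundary, orientation is re-canonicalized afterwards.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population structure, genotyping batch effects,
informative missingness, and any particular architecture of real
exacerbation risk (no effect-size distribution for true loci is known).
Passing tests therefore demonstrate that the pipeline's machinery is
correct and calibrated under its own assumptions — not that the real
cohort's AUC values are reproduced, which would require the original
genotypes.

## Problem sizes and numerical choices in the validation suite

The test suite exercises the pipeline at desk scale, chosen so the full
suite runs in minutes while keeping each check statistically meaningful:

* permutation-control calibration: n_train = 400 (30% cases), p = 1,000
  SNPs (20 causal, log-odds 1–2), n_test = 160, k = 40, ntree = 300,
  10 iterations; the mean replication AUC is required to lie within
  0.45–0.55.
* planted-SNP recovery: 20 causal SNPs (log-odds 1.0–2.0, MAF 0.2–0.4)
  among p = 5,000, n = 400, ntree = 300, averaged over 10 seeds, against
  a recovery threshold of 80% in the stage-2 top 160.
* ladder trend: p = 400 with 200 weak causal SNPs (log-odds 0.15–0.6),
  n = 400/164, ntree = 300, 10 seeds; the mean replication AUC at k = 160
  must exceed k = 10, and mean training AUC must not fall below mean
  replication AUC.
* AUC oracle equivalence: 1,000 random score/label fixtures (n ≤ 50, with
  deliberate ties) against brute-force pairwise and trapezoidal oracles at
  1e-12.

Other numerical choices: seeds derived from the master seed stay below
2^31; the bisection for the prevalence intercept runs on [-30, 30] with a
0.005 acceptance band; minor-allele and rank ties break lexicographically
or by genomic position so that no result depends on platform sort
stability.

## Limitations

* Importance scores from different stage-1 chunks are compared on a raw
  scale; this follows the original procedure but has no guarantee of
  cross-chunk comparability when chunk compositions differ strongly.
* A single 90/10 split is a noisy estimate of out-of-sample AUC; use
  `repeats` for anything beyond qualitative comparison.
* The generator's independence assumptions (no LD, no structure) make the
  recovery and calibration results best-case statements about the
  screening machinery, not about real GWAS panels.
* Real-data headline AUC values cannot be checked without the original
  cohort; the suite checks trends (more SNPs help on rich-signal data;
  training ≥ replication) and calibration (nulls at chance) instead.
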