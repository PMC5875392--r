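---
title: "Methods: biomarker screening and neural-network cascade modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker screening and neural-network cascade modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
```

## The problem and the pipeline

`mircascade` implements a biomarker-panel discovery pipeline for two-class
expression cohorts, of the kind used to screen circulating miRNAs for
disease detection in large microarray cohorts (thousands of participants,
a few thousand features). The pipeline has five stages:

1. **Split.** The cohort is divided into modeling and validation partitions
   at an integer ratio (default 2:1), stratified by class. Within each
   class the modeling partition receives `round(n * 2/3)` samples (round
   half up). Stratification is an inference: with 1,288 cases and 2,686
   controls this rule reproduces the canonical 859/1,791 and 429/895
   partition counts exactly, and unstratified splitting could not.
2. **Screening.** Every feature is evaluated alone by ROC analysis on the
   modeling set. Candidates must satisfy `AUC >= 0.95` *and* `p < 1e-4`
   (conjunctive). The boundary is inclusive (`>=`); both thresholds are
   parameters. No multiple-testing correction is applied — deliberately,
   to mirror the published procedure rather than improve on it silently.
3. **Collinearity pruning.** Pairwise Spearman correlations among
   candidates define a network with edges at `|rho| > 0.5`. Nodes are
   visited in descending AUC (ties broken lexicographically) and retained
   iff they have no edge *in the original network* to an already-retained
   node. This greedy rule generalizes the published pairwise rule ("of two
   collinear features keep the larger AUC") to chains and cliques and
   reduces to it on isolated pairs. A consequence worth knowing: in a
   chain A–B, B–C with descending AUCs, C is retained because its only
   edge points at the dropped B. The `|rho|` reading was chosen over a
   figure caption that writes the same threshold as `rho^2 > 0.5`; the
   threshold is a parameter either way.
4. **Modeling.** A neural-network cascade (NNC) and a stepwise multiple
   linear regression (MLR) baseline are fitted on the retained panel.
5. **Validation.** Stratified tenfold cross-validation of the cascade and
   independent evaluation of both models on the held-out partition, with
   sensitivity, specificity and accuracy reported as percentages.

## The RBF unit and the cascade

The cascade's building block is a radial-basis-function network with fixed
`n`-11-1 architecture (`n` = 1 or 2 inputs, 11 Gaussian hidden units, one
linear output):

$$y(x) = w_0 + \sum_{j=1}^{11} w_j \exp\!\left(-\frac{\lVert x - c_j\rVert^2}{2\sigma_j^2}\right)$$

The original analysis trained these units with a proprietary "Intelligent
Problem Solver" whose internals are unspecified, so the standard RBF recipe
is used instead, with every constant exposed as a parameter:

* **Centers** `c_j`: seeded k-means (k = 11) on the training subset; k is
  reduced (with a warning) when fewer distinct points exist.
* **Widths** `sigma_j`: mean distance from each center to its 2 nearest
  fellow centers, floored at `1e-3` to keep the Gaussian well-conditioned.
* **Output weights**: ridge-regularized least squares (`lambda = 1e-6`,
  intercept unpenalized) of the 0/1 status on the hidden-layer design.
* **Hold-out**: each training call performs an internal stratified 2:1:1
  training/verification/testing split (per class: `round(n/2)`,
  `round(n/4)`, remainder; every class must have at least 8 samples so all
  subsets keep both classes). Five random restarts differ in center
  placement; the restart with the highest verification correlation is
  kept. The testing subset is never used for any selection — it only
  produces the generalization diagnostic `R_Te`, reported next to `R_Tr`.
  The report correlates unit output with the 0/1 *status*; the source
  description of `R_Te` is ambiguous (it literally mentions correlation
  with expression values), and correlation-with-target is the standard
  reading of such training reports.

The cascade wires units in layers: layer 1 is the 1-input unit of the
highest-AUC candidate; each later layer trains a fresh 2-input combiner on
(previous cascade output, candidate unit output) for every remaining
candidate, and accepts the candidate with the maximum AUC gain on the full
modeling set iff the gain exceeds `epsilon = 1e-4`. `epsilon`
operationalizes "no further increase in AUC" under floating point. Three
accepted biomarkers therefore always produce exactly three 1-input units
and two 2-input combiners. Candidate 1-input units are trained once and
cached, matching that printed unit count; the greedy gain is measured on
the full modeling set because the source never names an internal
evaluation subset for this step. The decision cutoff is the Youden-optimal
cutoff of the final cascade output on the modeling set, frozen into the
model.

## Statistical conventions

* **AUC** is the Mann–Whitney statistic (ties count 1/2), always reported
  `>= 0.5` with a recorded polarity so down-regulated features are handled
  symmetrically. Its standard error uses the Hanley–McNeil formula; the
  p-value against AUC = 0.5 is a two-sided normal approximation with the
  tie-corrected Mann–Whitney variance. Whether the original analysis used
  this variance or DeLong's is unknowable from the text; at the targeted
  cohort sizes (n in the thousands) the approximation is accurate, and the
  exact pairwise count serves as the test oracle instead of a runtime
  path.
* **Operating points** use the Youden index (J = sensitivity +
  specificity − 1) maximized over midpoints between adjacent distinct
  scores with infinite sentinels; J ties break toward the lowest cutoff
  (J values within 1e-9 are treated as tied, since the true J granularity
  is `1/(n1*n0)` and double rounding otherwise breaks determinism). Youden
  is the default criterion of the ROC software named in the source, which
  does not state its setting.
* **Spearman** is Pearson on midranks, identical to the
  `1 − 6Σd²/(n(n²−1))` formula without ties.
* **Normality** uses the D'Agostino–Pearson omnibus test: the D'Agostino
  skewness transform plus the Anscombe–Glynn kurtosis transform, combined
  as K² with 2 chi-square degrees of freedom, on biased sample moments;
  n ≥ 8 is required. An exactly symmetric sample contributes 0 through the
  skewness term.
* **Stepwise MLR** is a linear probability model (OLS of 0/1 status), not
  logistic regression — the baseline being mirrored is explicitly
  *linear*. Entry/removal use partial-F probabilities 0.05/0.10, the
  defaults of the statistical package named in the source; candidates are
  examined in descending screening AUC so the procedure is deterministic,
  and perfectly collinear candidates are skipped with a warning.
* **Cross-validation** retrains cascade *weights* per fold with the panel
  fixed; greedy re-selection is available behind a flag but is not the
  default, because the established model's panel is what the repeated
  "model training" plausibly refers to. Folds are stratified (unstratified
  folds can go single-class and break ROC pooling, which the source's
  "randomly divided" wording presumably never encountered); the pooled
  out-of-fold scores give a single CV ROC curve.

## The synthetic cohort generator

Real cohorts of this scale cannot ship with a package, so every stage is
exercised against a seeded Gaussian-copula generator with a ground-truth
manifest:

* Each sample draws a latent normal vector; features in a collinear block
  share a factor (`latent = sqrt(r) f + sqrt(1-r) e`, within-block
  correlation `r = 0.9` by default).
* Case samples add `delta = sqrt(2) * qnorm(target_auc)` to planted-marker
  latents, making the theoretical AUC exactly `target_auc`.
* Margins apply a strictly increasing transform; the default is lognormal
  (`exp(sigma z)`, `sigma = 1`) because the real intensity data failed
  omnibus normality testing, so the synthetic default must fail it too.
  Rank statistics (AUC, Spearman) are invariant to the margin, which keeps
  the calibration closed-form.

### Why "non-collinear strong markers" need a negative cross-block term

A subtle and, to our knowledge, underappreciated fact drove one design
decision. Take two features that are *conditionally independent given
class*, each with AUC 0.97, in a cohort with case fraction 1/3. Writing
`F` for the pooled CDF, the pooled Spearman correlation is
`12 E[F(X)F(Y)] − 3`, and under conditional independence only the
class-conditional means of `F(X)` enter. Those means are pinned by the AUC
and the class fraction, giving a pooled Spearman of about **0.59 —
regardless of the marginal distributions**. The class mixture itself acts
as a shared factor. Consequently a generator cannot plant "mutually
non-collinear markers at AUC 0.97" (pooled `|rho| <= 0.5`) while keeping
them conditionally independent; the stated structure *requires* negative
within-class dependence. The generator therefore exposes `cross_block_r`,
an exchangeable correlation between block factors: the desk preset uses
−0.45, which the closed-form pooled-covariance expression places the
marker–marker Spearman near 0.43, safely below the 0.5 edge threshold,
while within-block pairs stay near 0.95.

Positive-definiteness caps the mutual correlation of B factors at
`−1/(B−1)`. With eight marker blocks the cap (−1/7) leaves the pooled
cross-marker Spearman near 0.54 at these AUCs — so a full-size cohort with
*eight* mutually non-collinear markers at AUC 0.96–0.99 is mathematically
unattainable in this model family. The `"paper"`-shaped preset (8 markers
plus duplicates at the published AUC range and cohort dimensions) uses the
feasible extreme (−0.14) and is intended for end-to-end shape testing, not
marker-count recovery. It is a striking corollary that the real cohort
this emulates did exhibit eight mutually non-collinear strong markers:
their within-class dependence must be strongly negative in exactly the way
conditional independence forbids.

### What a green test does and does not establish

The generator emulates: per-feature AUC levels, heavy rank-correlation
blocks among discriminative features, right-skewed non-Gaussian margins,
class imbalance, and exact reproducibility. It does **not** emulate:
probe-level noise, batch effects, intensity-dependent variance, missing
values, or real miRNA identities. A passing recovery test therefore
establishes that the pipeline's logic is correct in a well-specified
world, not that it would select the published markers from the real
accession.

## Degenerate inputs and numerical edges

* Constant feature on the training partition → hard error at
  normalization (naming the feature); any NaN at read time is a hard
  error, never imputed.
* Constant score vector → AUC 0.5, p = 1 (tie convention), Youden cutoff
  falls to the `-Inf` sentinel, classifying everything positive.
* Fewer than 11 distinct training points → hidden layer shrinks to the
  number of distinct points, with a warning recorded.
* p-values are floored at the smallest positive double rather than 0.
* All JSON model files serialize numerics with 17 significant digits, so a
  save/load round trip reproduces predictions bit-exactly; model files are
  schema-versioned and refuse unknown schemas.
* Every CLI output embeds the resolved configuration hash and seed and
  nothing time-dependent, making identical-config reruns byte-identical.

## Known limitations

* The RBF recipe is a faithful *standard* reconstruction, not a bit-level
  reimplementation of the proprietary trainer the source used; published
  real-data coefficients are out of reach by construction.
* The greedy cascade examines one new feature per layer; no beam or
  exhaustive panel search.
* The Mann–Whitney normal approximation is inaccurate below roughly 10
  samples per class; at such sizes the exact pairwise count (the test
  oracle) should be preferred.
* MLR is a linear probability model; predicted scores are not
  probabilities and may leave [0, 1].
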