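# mircascade

Biomarker-panel discovery for two-class expression cohorts: per-feature
ROC/AUC screening, Spearman collinearity-network pruning, and greedy
construction of a **neural-network cascade** (NNC) of small radial-basis
function units, benchmarked against a stepwise multiple linear regression
(MLR) baseline. The package targets the kind of analysis used for
circulating-miRNA disease screening in large microarray cohorts (thousands
of participants, ~2,500 miRNA probes), where the question is: *how few
markers can a panel contain without losing diagnostic accuracy?*

## The method in brief

Given a feature-by-sample matrix `X` and binary status `y` (0 = control,
1 = case):

1. **Stratified 2:1 split** into modeling and validation partitions
   (per class, round-half-up; a 1,288/2,686 cohort gives 859/1,791 vs
   429/895).
2. **Screening** — for every feature, the Mann–Whitney AUC
   (polarity-adjusted to ≥ 0.5), Hanley–McNeil SE, and a tie-corrected
   normal p-value against AUC = 0.5; candidates need `AUC ≥ 0.95` and
   `p < 10⁻⁴`.
3. **Collinearity pruning** — edges at Spearman `|ρ| > 0.5` among
   candidates; nodes visited by descending AUC, retained iff not linked to
   an already-retained node.
4. **NNC** — layer 1 is a 1-11-1 RBF unit (11 Gaussian hidden units,
   k-means centers, nearest-center widths, ridge least-squares output) on
   the best marker; each later layer trains 2-11-1 combiners on (cascade
   output, candidate unit output) and keeps the candidate with the largest
   AUC gain, stopping when the gain drops below ε = 10⁻⁴. A k-marker
   cascade has exactly k single-input units and k−1 combiners.
5. **Validation** — stratified tenfold CV (pooled out-of-fold ROC) and
   independent-set evaluation: sensitivity, specificity, accuracy at each
   model's frozen Youden cutoff.

A seeded Gaussian-copula cohort generator with closed-form AUC calibration
(`delta = sqrt(2) * qnorm(target_auc)`), collinear latent blocks and
lognormal margins makes the whole pipeline testable offline; every planted
property is recorded in a ground-truth manifest. See the methods vignette
(`vignettes/biomarker-cascade-methods.Rmd`) for assumptions, parameter
meanings, and the (surprisingly subtle) design of "non-collinear strong
markers".

## Worked example

```r
library(mircascade)

cohort <- generate_cohort(synthetic_preset("desk", seed = 1))  # 600/1200 x 200
split  <- stratified_split(cohort$labels, c(2, 1), seed = 1)
train  <- subset_matrix(cohort$matrix, samples = split$train_ids)
train_labels <- cohort_labels(split$train_ids,
                              unname(cohort$labels$status[split$train_ids]))

screening <- screen_features(train, train_labels)
screening
#> screening_report: 200 features screened, 7 candidates (AUC >= 0.95 & p < 1e-04 )

network <- build_network(train, screening$candidates)
network
#> collinearity_network: 7 nodes, 6 edges (|rho| > 0.5 )
panel <- prune_network(network)
panel
#> [1] "miR-sim-0001" "miR-sim-0003" "miR-sim-0002"

cand <- screening$candidates[screening$candidates$feature_id %in% panel, ]
nnc <- build_cascade(train, train_labels, cand, seed = 1)
nnc
#> cascade_model: panel [miR-sim-0001, miR-sim-0003, miR-sim-0002],
#>   3 x 1-input + 2 x 2-input units, AUC trace 0.9712 -> 0.9968 -> 0.9999

val <- subset_matrix(cohort$matrix, samples = split$validation_ids)
val_labels <- cohort_labels(split$validation_ids,
                            unname(cohort$labels$status[split$validation_ids]))
evaluate_model(nnc, val, val_labels)
#> evaluation_report [cascade_model, validation]: AUC 0.9998, sens 98.0%,
#>   spec 100.0%, ACC 99.3% (n = 600)

mlr <- fit_stepwise_mlr(train, train_labels, cand)
evaluate_model(mlr, val, val_labels)
#> evaluation_report [mlr_model, validation]: AUC 1.0000, sens 100.0%,
#>   spec 99.8%, ACC 99.8% (n = 600)

tenfold_cv(train, train_labels, nnc$panel, seed = 1)
#> cv_result: 10 folds, pooled AUC 0.9998
```

Reading the numbers: the desk cohort plants three true markers at AUC 0.97
with two collinear decoys each. Screening admits markers and decoys (7
candidates under this seed — decoys sit near the 0.95 boundary), pruning
collapses each collinear block to its strongest member, and the cascade's
AUC trace climbs from the single best marker (0.971) to the 3-marker panel
(0.9999). Both models then classify the held-out third of the cohort with
≥ 99% accuracy.

## Command line

```sh
Rscript inst/exec/mircascade pipeline --out run1 --seed 7
# subcommands: simulate screen prune train-nnc train-mlr crossval evaluate pipeline
```

All thresholds default to the published values (`auc_threshold 0.95`,
`p_threshold 1e-4`, `rho_threshold 0.5`, ratio 2:1, ε 1e-4, 10 folds) and
can be overridden by a JSON config (`--config`) or flags
(`--auc_threshold 0.97`). Outputs are stamped with the config hash and
seed; identical config + seed reruns are byte-identical.

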