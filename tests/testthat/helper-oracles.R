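# Independent oracles and small cohort builders shared by the test files.
# Oracles are deliberately brute-force / closed-form and never call the code
# paths they check.

# AUC by explicit counting over all case-control pairs (ties = 1/2).
brute_auc <- function(scores, status) {
  cases <- scores[status == 1]
  controls <- scores[status == 0]
  s <- 0
  for (a in cases) {
    for (b in controls) s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(controls))
}

# Spearman via the no-ties closed form 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Best achievable Youden J by exhaustive enumeration of every observed value
# as a threshold (rule: positive iff score > t), plus the all-positive and
# all-negative extremes.
youden_enum_j <- function(scores, status) {
  cand <- c(-Inf, sort(unique(scores)))
  best <- -Inf
  for (t in cand) {
    sens <- mean(scores[status == 1] > t)
    spec <- mean(scores[status == 0] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Tiny two-class cohort: first `n_informative` features shifted by `delta`
# in cases, the rest null; Gaussian margins, no blocks.
make_cohort <- function(n_cases, n_controls, n_features, n_informative = 0,
                        target_auc = 0.97, seed = 1) {
  planted <- if (n_informative > 0) {
    data.frame(feature_id = sprintf("miR-sim-%04d", seq_len(n_informative)),
               target_auc = rep(target_auc, n_informative))
  } else NULL
  generate_cohort(synthetic_spec(n_cases, n_controls, n_features,
                                 planted_markers = planted,
                                 margin = "normal", seed = seed))
}

labels_subset <- function(labels, ids) {
  cohort_labels(ids, unname(labels$status[ids]))
}

# Deterministic hand-built unit for forward-pass checks (internal ctor).
toy_unit <- function(centers, widths, weights, bias) {
  mircascade:::rbf_unit(matrix(centers, ncol = 1), widths, weights, bias, "x")
}
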