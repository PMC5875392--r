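# Layered validation: stratified tenfold cross-validation of the cascade and
# independent-set evaluation of any fitted model.

#' Stratified k-fold assignment
#'
#' Per class, samples are shuffled (seeded) and dealt round-robin so fold
#' sizes within each class differ by at most one.
#'
#' @param labels A [cohort_labels()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Named integer vector: fold index (1..n_folds) per sample ID.
#' @export
fold_assignments <- function(labels, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(labels, "cohort_labels"))
  n_folds <- as.integer(n_folds)
  folds <- integer(0)
  ids <- character(0)
  for (cls in c(1L, 0L)) {
    cid <- labels$sample_ids[labels$status == cls]
    if (length(cid) < n_folds) {
      stop2("class ", cls, " has ", length(cid), " samples; fewer than ",
            n_folds, " folds")
    }
    perm <- with_seed(derive_seed(seed, 81L, cls),
                      sample(cid, length(cid)))
    ids <- c(ids, perm)
    # deal cases ascending and controls descending so the leftover samples
    # of the two classes land in different folds (859 + 1,791 at 10 folds
    # gives ten groups of exactly 265)
    deal <- if (cls == 1L) seq_len(n_folds) else rev(seq_len(n_folds))
    folds <- c(folds, rep_len(deal, length(cid)))
  }
  stats::setNames(folds, ids)[labels$sample_ids]
}

#' Tenfold cross-validation of a fixed-panel cascade
#'
#' Partitions the modeling cohort into `n_folds` stratified, mutually
#' exclusive groups of nearly equal size.  For each fold, the cascade weights
#' are retrained on the other folds with the FIXED panel (greedy selection is
#' not re-run unless `reselect = TRUE`), normalization is refitted on the
#' same folds, and the held-out fold is scored.  The pooled out-of-fold
#' scores yield a single ROC/AUC; per-fold metrics use each fold model's own
#' frozen cutoff.
#'
#' @param matrix An [expression_matrix()] of the modeling cohort (raw scale).
#' @param labels A [cohort_labels()].
#' @param panel Ordered feature IDs of the established cascade (when
#'   `reselect = TRUE`, the candidate pool for per-fold greedy selection;
#'   per-fold screening AUCs then order the candidates).
#' @param seed Integer seed.
#' @param n_folds Number of folds (default 10).
#' @param reselect Re-run greedy panel selection within each fold
#'   (default `FALSE`).
#' @param restarts,k,epsilon Passed to the cascade trainer.
#' @return Object of class `cv_result`: `n_folds`, `fold_assignments`,
#'   `pooled_scores` (out-of-fold, named by sample), `pooled_auc`,
#'   `per_fold` (data.frame: fold, n, auc, sensitivity, specificity,
#'   accuracy), `seed`.
#' @export
tenfold_cv <- function(matrix, labels, panel, seed = 1L, n_folds = 10L,
                       reselect = FALSE, restarts = 5L, k = 11L,
                       epsilon = 1e-4) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(labels, "cohort_labels"))
  panel <- as.character(panel)
  if (!length(panel)) stop2("empty panel")
  assign <- fold_assignments(labels, n_folds, derive_seed(seed, 91L))
  status_all <- status_for(labels, matrix$sample_ids)
  pooled <- stats::setNames(rep(NA_real_, length(matrix$sample_ids)),
                            matrix$sample_ids)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- names(assign)[assign == f]
    rest <- setdiff(matrix$sample_ids, held)
    m_tr <- subset_matrix(matrix, features = panel, samples = rest)
    lab_tr <- cohort_labels(rest, status_for(labels, rest))
    fold_seed <- derive_seed(seed, 92L, f)
    model <- if (reselect) {
      aucs <- vapply(panel, function(fid) {
        roc_auc(m_tr$values[fid, ], lab_tr$status,
                compute_cutoff = FALSE)$auc
      }, numeric(1))
      build_cascade(m_tr, lab_tr,
                    data.frame(feature_id = panel, auc = unname(aucs)),
                    epsilon = epsilon, seed = fold_seed, restarts = restarts,
                    k = k)
    } else {
      train_cascade_fixed(m_tr, lab_tr, panel, seed = fold_seed,
                          restarts = restarts, k = k)
    }
    pred <- predict_cascade(model,
                            subset_matrix(matrix, features = panel,
                                          samples = held))
    pooled[held] <- pred$scores
    st <- status_for(labels, held)
    cc <- confusion_counts(pred$classes, st)
    met <- classification_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    per_fold[[f]] <- data.frame(
      fold = f, n = length(held),
      auc = roc_auc(pred$scores, st, compute_cutoff = FALSE)$auc,
      sensitivity = met$sensitivity, specificity = met$specificity,
      accuracy = met$accuracy)
  }
  pooled_auc <- roc_auc(unname(pooled), status_all,
                        compute_cutoff = FALSE)$auc
  structure(list(n_folds = n_folds, fold_assignments = assign,
                 pooled_scores = pooled, pooled_auc = pooled_auc,
                 per_fold = do.call(rbind, per_fold),
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, pooled AUC %.4f\n", x$n_folds,
              x$pooled_auc))
  invisible(x)
}

#' Evaluate a fitted model on a labeled cohort
#'
#' Scores the cohort with the model's own predictor and frozen decision
#' cutoff, tabulates the confusion counts and reports AUC, sensitivity,
#' specificity and accuracy (percentages).
#'
#' @param model A `cascade_model` or `mlr_model`.
#' @param matrix An [expression_matrix()] containing the model's features.
#' @param labels A [cohort_labels()].
#' @param cohort_label Free-text tag recorded in the report (e.g.
#'   `"training"`, `"validation"`).
#' @return Object of class `evaluation_report`: `model_id`, `cohort`, `n`,
#'   `auc`, `sensitivity`, `specificity`, `accuracy`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_model <- function(model, matrix, labels,
                           cohort_label = "validation") {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(labels, "cohort_labels"))
  pred <- if (inherits(model, "cascade_model")) {
    predict_cascade(model, matrix)
  } else if (inherits(model, "mlr_model")) {
    predict_mlr(model, matrix)
  } else stop2("model must be a cascade_model or mlr_model")
  st <- status_for(labels, matrix$sample_ids)
  cc <- confusion_counts(pred$classes, st)
  met <- classification_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
  auc <- roc_auc(unname(pred$scores), st, compute_cutoff = FALSE)$auc
  structure(c(list(model_id = class(model)[1], cohort = cohort_label,
                   n = length(st), auc = auc), met, cc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report [%s, %s]: AUC %.4f, sens %.1f%%, spec %.1f%%, ACC %.1f%% (n = %d)\n",
    x$model_id, x$cohort, x$auc, x$sensitivity, x$specificity, x$accuracy,
    x$n))
  invisible(x)
}

#' Write evaluation reports as a TSV table
#' @param reports A single `evaluation_report` or a list of them.
#' @param path Output TSV path.
#' @param comment Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_evaluation_reports <- function(reports, path, comment = NULL) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  }))
  write_tsv_table(df, path, comment)
}
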