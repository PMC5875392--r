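# Stage 1: independent per-feature ROC evaluation on the training set and
# selection of high-AUC candidates.

#' Screen every feature as an individual biomarker
#'
#' Runs [roc_auc()] on each feature's expression over the given samples and
#' selects candidates satisfying `auc >= auc_threshold` AND
#' `p_value < p_threshold` (both criteria conjunctive).  Also bins the AUC
#' distribution into width-0.01 bins over `[0.5, 1]` (half-open bins, final
#' bin closed at 1.0), the usual screening summary figure.  No multiple-testing
#' correction is applied.
#'
#' @param matrix An [expression_matrix()] restricted to the training samples.
#' @param labels A [cohort_labels()] covering all samples of `matrix`.
#' @param auc_threshold Minimum polarity-adjusted AUC (default 0.95).
#' @param p_threshold Maximum p-value, exclusive (default 1e-4).
#' @return Object of class `screening_report`: list with
#'   `results` (data.frame: feature_id, auc, se, p_value, polarity, cutoff,
#'   sensitivity, specificity), `histogram` (data.frame: lower, upper, count),
#'   `candidates` (data.frame: feature_id, auc — ordered by descending AUC,
#'   ties broken by ID), and the thresholds used.
#' @export
screen_features <- function(matrix, labels, auc_threshold = 0.95,
                            p_threshold = 1e-4) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(labels, "cohort_labels"))
  if (!is.numeric(auc_threshold) || auc_threshold < 0.5 || auc_threshold > 1) {
    stop2("auc_threshold must lie in [0.5, 1]")
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop2("p_threshold must lie in (0, 1]")
  }
  status <- status_for(labels, matrix$sample_ids)
  n_feat <- length(matrix$feature_ids)
  rows <- vector("list", n_feat)
  for (i in seq_len(n_feat)) {
    fid <- matrix$feature_ids[i]
    rr <- tryCatch(roc_auc(matrix$values[i, ], status),
                   error = function(e) {
                     stop2("feature '", fid, "': ", conditionMessage(e))
                   })
    rows[[i]] <- data.frame(feature_id = fid, auc = rr$auc, se = rr$se,
                            p_value = rr$p_value, polarity = rr$polarity,
                            cutoff = rr$cutoff, sensitivity = rr$sensitivity,
                            specificity = rr$specificity,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)

  lower <- seq(0.5, 0.99, by = 0.01)
  bin <- pmin(floor((results$auc - 0.5) / 0.01) + 1L, length(lower))
  histogram <- data.frame(lower = lower, upper = lower + 0.01,
                          count = tabulate(bin, nbins = length(lower)))

  keep <- results$auc >= auc_threshold & results$p_value < p_threshold
  cand <- results[keep, c("feature_id", "auc")]
  cand <- cand[order(-cand$auc, cand$feature_id), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(results = results, histogram = histogram, candidates = cand,
                 auc_threshold = auc_threshold, p_threshold = p_threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report:", nrow(x$results), "features screened,",
      nrow(x$candidates), "candidates (AUC >=", x$auc_threshold,
      "& p <", x$p_threshold, ")\n")
  invisible(x)
}

#' Write a screening report to TSV files
#'
#' Emits `screening_report.tsv` (one row per feature), `auc_histogram.tsv`
#' and `candidates.txt` (one candidate ID per line) into `dir`.
#'
#' @param report A `screening_report`.
#' @param dir Output directory (created if needed).
#' @param comment Optional `#` header lines stamped into each file.
#' @return Character vector of the three paths, invisibly.
#' @export
write_screening_report <- function(report, dir, comment = NULL) {
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "screening_report.tsv")
  p2 <- file.path(dir, "auc_histogram.tsv")
  p3 <- file.path(dir, "candidates.txt")
  write_tsv_table(report$results, p1, comment)
  write_tsv_table(report$histogram, p2, comment)
  con <- file(p3, "w")
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(report$candidates$feature_id, con)
  close(con)
  invisible(c(p1, p2, p3))
}

# Deterministic full-precision TSV writer for small report tables.
write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.double(col)) num_chr(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
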