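# Core containers: expression matrix and cohort labels.

#' Construct an expression matrix
#'
#' A feature-by-sample matrix of normalized expression values with unique
#' feature and sample identifiers.  All values must be finite: processed
#' microarray matrices carry no missing values, and any `NA`/`NaN` is treated
#' as a data error rather than silently imputed.
#'
#' @param values Numeric matrix, rows = features, columns = samples.
#' @param feature_ids Character vector of unique row identifiers
#'   (default: `rownames(values)`).
#' @param sample_ids Character vector of unique column identifiers
#'   (default: `colnames(values)`).
#' @return An object of class `expression_matrix`: a list with elements
#'   `feature_ids`, `sample_ids` and `values` (a matrix carrying both as
#'   dimnames).
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))))
#' dim(m$values)
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix")
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop2("feature and sample identifiers are required")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop2("length of feature_ids (", length(feature_ids),
          ") does not match nrow(values) (", nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop2("length of sample_ids (", length(sample_ids),
          ") does not match ncol(values) (", ncol(values), ")")
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop2("duplicate feature ID: ", dup[1])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop2("duplicate sample ID: ", dup[1])
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop2("non-finite value at feature '", feature_ids[bad[1]],
          "', sample '", sample_ids[bad[2]], "'")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(feature_ids = feature_ids, sample_ids = sample_ids,
                 values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$feature_ids), "features x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature and/or sample IDs
#'
#' @param x An `expression_matrix`.
#' @param features,samples Character vectors of IDs to keep (`NULL` = all).
#' @return An `expression_matrix`.
#' @export
subset_matrix <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  f <- if (is.null(features)) x$feature_ids else as.character(features)
  s <- if (is.null(samples)) x$sample_ids else as.character(samples)
  missing_f <- setdiff(f, x$feature_ids)
  if (length(missing_f)) stop2("unknown feature ID: ", missing_f[1])
  missing_s <- setdiff(s, x$sample_ids)
  if (length(missing_s)) stop2("unknown sample ID: ", missing_s[1])
  expression_matrix(x$values[f, s, drop = FALSE], f, s)
}

#' Construct cohort labels
#'
#' Maps sample IDs to binary disease status, coded `0` (healthy control) and
#' `1` (case).
#'
#' @param sample_ids Character vector of unique sample IDs.
#' @param status Integer vector of 0/1 statuses, same length.
#' @return An object of class `cohort_labels` with elements `sample_ids` and
#'   `status` (named integer vector).
#' @export
cohort_labels <- function(sample_ids, status) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop2("duplicate sample ID: ", sample_ids[duplicated(sample_ids)][1])
  }
  if (length(status) != length(sample_ids)) {
    stop2("sample_ids and status lengths differ")
  }
  status <- as.integer(status)
  if (anyNA(status) || !all(status %in% c(0L, 1L))) {
    stop2("status must be coded 0 (control) or 1 (case)")
  }
  names(status) <- sample_ids
  structure(list(sample_ids = sample_ids, status = status),
            class = "cohort_labels")
}

#' @export
print.cohort_labels <- function(x, ...) {
  cat("cohort_labels:", sum(x$status == 1L), "cases /",
      sum(x$status == 0L), "controls\n")
  invisible(x)
}

# 0/1 status vector for a given sample ID set, in that order.
status_for <- function(labels, ids) {
  stopifnot(inherits(labels, "cohort_labels"))
  ids <- as.character(ids)
  missing <- setdiff(ids, labels$sample_ids)
  if (length(missing)) stop2("no label for sample ID: ", missing[1])
  unname(labels$status[ids])
}
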