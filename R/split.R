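# Cohort partitioning: the 2:1 modeling/validation split and 0-1 feature
# normalization fitted on the training partition.

#' Stratified two-way split of a labeled cohort
#'
#' Splits a cohort into training and validation partitions at an integer
#' ratio, independently within each class, so the class balance is preserved.
#' Within each class the training partition receives
#' `round(n_class * r_train / (r_train + r_val))` samples (round half up) and
#' the validation partition the remainder; membership is a seeded uniform
#' shuffle.  At the default 2:1 ratio a cohort of 1,288 cases and 2,686
#' controls yields the canonical 859/1,791 training and 429/895 validation
#' class counts.
#'
#' @param labels A [cohort_labels()] object; both classes must have >= 2
#'   samples.
#' @param ratio Integer pair `c(r_train, r_val)`, both positive.
#' @param seed Integer RNG seed.
#' @return An object of class `split_assignment`: list with `train_ids`,
#'   `validation_ids`, `ratio`, `seed`.
#' @export
stratified_split <- function(labels, ratio = c(2L, 1L), seed = 1L) {
  stopifnot(inherits(labels, "cohort_labels"))
  ratio <- as.integer(ratio)
  if (length(ratio) != 2L || anyNA(ratio) || any(ratio <= 0L)) {
    stop2("`ratio` must be two positive integers")
  }
  train_ids <- character(0)
  validation_ids <- character(0)
  for (cls in c(1L, 0L)) {
    ids <- labels$sample_ids[labels$status == cls]
    n <- length(ids)
    if (n < 2L) {
      stop2("class ", cls, " has ", n, " sample(s); cannot stratify")
    }
    n_tr <- round_half_up(n * ratio[1] / sum(ratio))
    perm <- with_seed(derive_seed(seed, 11L, cls), sample.int(n))
    train_ids <- c(train_ids, ids[perm[seq_len(n_tr)]])
    validation_ids <- c(validation_ids, ids[perm[seq_len(n - n_tr) + n_tr]])
  }
  structure(list(train_ids = train_ids, validation_ids = validation_ids,
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("split_assignment:", length(x$train_ids), "train /",
      length(x$validation_ids), "validation (ratio ",
      paste(x$ratio, collapse = ":"), ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a split assignment as JSON
#' @param split A `split_assignment`.
#' @param path JSON path.
#' @return `path` (write) or the `split_assignment` (read).
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 validation_ids = as.character(x$validation_ids),
                 ratio = as.integer(x$ratio), seed = as.integer(x$seed)),
            class = "split_assignment")
}

#' Fit per-feature 0-1 normalization on the training partition
#'
#' Records each feature's minimum and maximum over the training samples only,
#' so that validation data are scaled into the model's fitted domain without
#' information leakage.
#'
#' @param matrix An [expression_matrix()].
#' @param train_ids Sample IDs of the training partition.
#' @return An object of class `normalization_params`: list with named numeric
#'   vectors `min` and `max`.
#' @export
fit_normalization <- function(matrix, train_ids) {
  stopifnot(inherits(matrix, "expression_matrix"))
  train_ids <- as.character(train_ids)
  missing <- setdiff(train_ids, matrix$sample_ids)
  if (length(missing)) stop2("unknown training sample ID: ", missing[1])
  sub <- matrix$values[, train_ids, drop = FALSE]
  mins <- apply(sub, 1L, min)
  maxs <- apply(sub, 1L, max)
  flat <- which(maxs <= mins)
  if (length(flat)) {
    stop2("feature '", matrix$feature_ids[flat[1]],
          "' is constant on the training partition")
  }
  structure(list(min = mins, max = maxs), class = "normalization_params")
}

#' Apply 0-1 normalization, clipping out-of-range values
#'
#' Computes `(x - min) / (max - min)` per feature using stored training-set
#' parameters; values outside `[0, 1]` (validation samples beyond the training
#' range) are clipped to the boundary.
#'
#' @param matrix An [expression_matrix()]; every feature must be covered by
#'   `params`.
#' @param params A `normalization_params` object from [fit_normalization()].
#' @return A normalized [expression_matrix()] with values in `[0, 1]`.
#' @export
apply_normalization <- function(matrix, params) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(params, "normalization_params"))
  missing <- setdiff(matrix$feature_ids, names(params$min))
  if (length(missing)) {
    stop2("feature '", missing[1], "' missing from normalization params")
  }
  lo <- params$min[matrix$feature_ids]
  hi <- params$max[matrix$feature_ids]
  v <- (matrix$values - lo) / (hi - lo)
  v[v < 0] <- 0
  v[v > 1] <- 1
  expression_matrix(v, matrix$feature_ids, matrix$sample_ids)
}
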