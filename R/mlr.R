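# Stepwise multiple linear regression baseline (linear probability model:
# ordinary least squares of the 0/1 status on normalized expression values).
# Classic stepwise selection with probability-of-F thresholds: at each step
# the excluded candidate with the smallest partial-F p-value enters if
# p < entry_p, then any included feature with p > removal_p is removed;
# iterated to a fixed point.

# Least-squares fit via QR; returns coefficients, RSS and residual df.
ols_fit <- function(x, y) {
  qr_ <- qr(x)
  if (qr_$rank < ncol(x)) return(NULL) # rank-deficient design
  coef <- qr.coef(qr_, y)
  res <- y - x %*% coef
  list(coef = as.numeric(coef), rss = sum(res^2),
       df = length(y) - ncol(x))
}

# p-value of the partial F-test comparing nested OLS models.
partial_f_p <- function(rss_small, rss_big, df_big) {
  if (df_big <= 0) return(NA_real_)
  if (rss_big <= .Machine$double.eps * max(1, rss_small)) return(0)
  f <- (rss_small - rss_big) / (rss_big / df_big)
  stats::pf(max(f, 0), 1, df_big, lower.tail = FALSE)
}

#' Fit a stepwise multiple linear regression model
#'
#' @param matrix An [expression_matrix()] of the modeling samples (raw scale
#'   unless `normalization` is given).
#' @param labels A [cohort_labels()].
#' @param candidates Data frame `feature_id`, `auc`; candidates are examined
#'   in descending-AUC order (ties by ID) so the procedure is deterministic.
#' @param entry_p Probability-of-F to enter (default 0.05).
#' @param removal_p Probability-of-F to remove (default 0.10); must exceed
#'   `entry_p` to avoid cycling.
#' @param normalization Optional [fit_normalization()] result; fitted on
#'   `matrix` when `NULL`.
#' @return Object of class `mlr_model`: `included_features`, `coefficients`
#'   (named, ordered as included), `intercept`, `entry_p`, `removal_p`,
#'   `decision_cutoff`, `polarity`, `normalization`.  Candidates whose entry
#'   would make the design rank-deficient are skipped with a warning.
#' @export
fit_stepwise_mlr <- function(matrix, labels, candidates, entry_p = 0.05,
                             removal_p = 0.10, normalization = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(labels, "cohort_labels"))
  if (entry_p > removal_p) stop2("entry_p must be <= removal_p")
  cand <- candidate_table(candidates)
  if (is.null(normalization)) {
    normalization <- fit_normalization(
      subset_matrix(matrix, features = cand$feature_id), matrix$sample_ids)
  }
  norm <- apply_normalization(
    subset_matrix(matrix, features = cand$feature_id), normalization)
  y <- status_for(labels, norm$sample_ids)
  n <- length(y)
  if (n <= nrow(cand) + 1L) {
    stop2("need more observations (", n, ") than candidates + 1 (",
          nrow(cand) + 1L, ")")
  }
  xall <- t(norm$values) # samples x features

  included <- character(0)
  design <- function(feats) cbind(`(intercept)` = 1,
                                  xall[, feats, drop = FALSE])
  base_fit <- ols_fit(design(included), y)
  warned <- character(0)
  for (iter in seq_len(10L * nrow(cand) + 10L)) {
    changed <- FALSE
    # Entry step
    excluded <- setdiff(cand$feature_id, included)
    if (length(excluded) && entry_p > 0) {
      ps <- rep(NA_real_, length(excluded))
      fits <- vector("list", length(excluded))
      for (j in seq_along(excluded)) {
        f <- ols_fit(design(c(included, excluded[j])), y)
        if (is.null(f)) {
          if (!excluded[j] %in% warned) {
            warning("skipping '", excluded[j],
                    "': collinear with already-entered features",
                    call. = FALSE)
            warned <- c(warned, excluded[j])
          }
          next
        }
        fits[[j]] <- f
        ps[j] <- partial_f_p(base_fit$rss, f$rss, f$df)
      }
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < entry_p) {
        j <- which.min(ps) # candidate order breaks exact ties
        included <- c(included, excluded[j])
        base_fit <- fits[[j]]
        changed <- TRUE
      }
    }
    # Removal step (repeat until stable)
    repeat {
      if (!length(included)) break
      ps <- vapply(seq_along(included), function(j) {
        f <- ols_fit(design(included[-j]), y)
        partial_f_p(f$rss, base_fit$rss, base_fit$df)
      }, numeric(1))
      worst <- which.max(ps)
      if (ps[worst] > removal_p) {
        included <- included[-worst]
        base_fit <- ols_fit(design(included), y)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  coefs <- base_fit$coef
  fitted <- as.numeric(design(included) %*% coefs)
  rr <- roc_auc(fitted, y)
  structure(list(schema = "mircascade-mlr-1",
                 included_features = included,
                 coefficients = if (length(included))
                   stats::setNames(coefs[-1], included) else numeric(0),
                 intercept = coefs[1], entry_p = entry_p,
                 removal_p = removal_p, decision_cutoff = rr$cutoff,
                 polarity = rr$polarity, normalization = normalization),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("mlr_model:", length(x$included_features), "features [",
      paste(x$included_features, collapse = ", "), "]\n")
  invisible(x)
}

#' Predict with a stepwise MLR model
#'
#' `score = intercept + sum(beta_i * x_i)` on normalized inputs;
#' `class = 1` when the polarity-oriented score exceeds the frozen Youden
#' cutoff.
#'
#' @param model An `mlr_model`.
#' @param matrix An [expression_matrix()] containing all included features.
#' @return List with `scores` and `classes` as in [predict_cascade()].
#' @export
predict_mlr <- function(model, matrix) {
  stopifnot(inherits(model, "mlr_model"),
            inherits(matrix, "expression_matrix"))
  feats <- model$included_features
  if (length(feats)) {
    missing <- setdiff(feats, matrix$feature_ids)
    if (length(missing)) stop2("model feature missing from matrix: ",
                               missing[1])
    keep <- intersect(names(model$normalization$min), matrix$feature_ids)
    params <- structure(list(min = model$normalization$min[keep],
                             max = model$normalization$max[keep]),
                        class = "normalization_params")
    norm <- apply_normalization(subset_matrix(matrix, features = feats),
                                params)
    scores <- model$intercept +
      as.numeric(t(norm$values) %*% model$coefficients)
  } else {
    scores <- rep(model$intercept, length(matrix$sample_ids))
  }
  names(scores) <- matrix$sample_ids
  classes <- as.integer(model$polarity * scores > model$decision_cutoff)
  list(scores = scores, classes = classes)
}

#' Save / load an MLR model as versioned JSON
#' @param model An `mlr_model`.
#' @param path JSON file path.
#' @return `path` (save) or the reloaded `mlr_model` (load).
#' @export
save_mlr <- function(model, path) {
  stopifnot(inherits(model, "mlr_model"))
  x <- unclass(model)
  x$coefficients <- as.list(x$coefficients)
  x$normalization <- list(min = as.list(x$normalization$min),
                          max = as.list(x$normalization$max))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_mlr
#' @export
load_mlr <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop2("cannot parse model file: ",
                                          conditionMessage(e)))
  if (!identical(x$schema, "mircascade-mlr-1")) {
    stop2("unrecognized model schema: ",
          if (is.null(x$schema)) "<missing>" else x$schema)
  }
  structure(list(schema = x$schema,
                 included_features = as.character(x$included_features),
                 coefficients = unlist(x$coefficients),
                 intercept = x$intercept, entry_p = x$entry_p,
                 removal_p = x$removal_p,
                 decision_cutoff = x$decision_cutoff, polarity = x$polarity,
                 normalization = structure(
                   list(min = unlist(x$normalization$min),
                        max = unlist(x$normalization$max)),
                   class = "normalization_params")),
            class = "mlr_model")
}
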