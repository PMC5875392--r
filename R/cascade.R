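# Neural-network cascade: an ordered panel of biomarkers wired as one
# 1-input RBF unit per panel member plus one 2-input combiner per layer >= 2
# (combiner inputs = previous cascade output, new feature unit's output).
# The panel is grown greedily: at each layer the remaining candidate whose
# combiner yields the maximum AUC gain on the modeling set is accepted iff
# the gain exceeds epsilon.

candidate_table <- function(candidates) {
  candidates <- as.data.frame(candidates)
  if (!all(c("feature_id", "auc") %in% names(candidates))) {
    stop2("`candidates` needs columns feature_id and auc")
  }
  candidates$feature_id <- as.character(candidates$feature_id)
  candidates <- candidates[order(-candidates$auc, candidates$feature_id), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

new_cascade_model <- function(panel, feature_units, combiner_units, trace,
                              epsilon, normalization, cutoff, polarity,
                              seed) {
  structure(list(schema = "mircascade-cascade-1", panel = panel,
                 feature_units = feature_units,
                 combiner_units = combiner_units,
                 layer_auc_trace = trace, epsilon = epsilon,
                 normalization = normalization, decision_cutoff = cutoff,
                 polarity = polarity, seed = as.integer(seed)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("cascade_model: panel [", paste(x$panel, collapse = ", "), "], ",
      length(x$feature_units), " x 1-input + ", length(x$combiner_units),
      " x 2-input units, AUC trace ",
      paste(sprintf("%.4f", x$layer_auc_trace), collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

cascade_finalize <- function(matrix_norm, status, panel, units, combiners,
                             trace, epsilon, params, seed, scores) {
  rr <- roc_auc(scores, status)
  new_cascade_model(panel, units, combiners, trace, epsilon, params,
                    rr$cutoff, rr$polarity, seed)
}

#' Build a neural-network cascade by greedy AUC-gain selection
#'
#' Layer 1 is a 1-input RBF unit trained on the highest-AUC candidate.  Every
#' candidate's 1-input unit is trained once up front and cached; at each
#' subsequent layer each remaining candidate's cached unit output is paired
#' with the current cascade output into a freshly trained 2-input combiner,
#' and the candidate maximizing the cascade AUC on the full modeling set is
#' accepted iff the gain exceeds `epsilon`, otherwise the build terminates.
#' The decision cutoff is the Youden-optimal cutoff of the final cascade
#' output on the modeling set, frozen into the model.
#'
#' @param matrix An [expression_matrix()] holding the modeling samples (raw
#'   scale unless `normalization` is supplied).
#' @param labels A [cohort_labels()].
#' @param candidates Data frame `feature_id`, `auc` (screening AUCs; entry
#'   order for tie-breaking is descending AUC then lexicographic ID).
#' @param epsilon Minimum AUC gain to accept a new layer (default 1e-4).
#' @param seed Integer seed.
#' @param normalization Optional [fit_normalization()] result.  When `NULL`,
#'   parameters are fitted on `matrix` itself and stored in the model.
#' @param restarts,k Passed to [train_rbf()].
#' @return A `cascade_model` with fields `panel`, `feature_units`,
#'   `combiner_units`, `layer_auc_trace`, `epsilon`, `normalization`,
#'   `decision_cutoff`, `polarity`, `seed`.
#' @export
build_cascade <- function(matrix, labels, candidates, epsilon = 1e-4,
                          seed = 1L, normalization = NULL, restarts = 5L,
                          k = 11L) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(labels, "cohort_labels"))
  cand <- candidate_table(candidates)
  if (!nrow(cand)) stop2("no candidate features")
  if (is.null(normalization)) {
    normalization <- fit_normalization(
      subset_matrix(matrix, features = cand$feature_id), matrix$sample_ids)
  }
  norm <- apply_normalization(
    subset_matrix(matrix, features = cand$feature_id), normalization)
  status <- status_for(labels, norm$sample_ids)

  # Cache one 1-input unit (and its modeling-set output) per candidate.
  units <- list()
  outputs <- list()
  for (i in seq_len(nrow(cand))) {
    fid <- cand$feature_id[i]
    fit <- train_rbf(norm$values[fid, ], status,
                     seed = derive_seed(seed, 61L, i), restarts = restarts,
                     k = k)
    fit$unit$input_refs <- fid
    units[[fid]] <- fit$unit
    outputs[[fid]] <- predict_rbf(fit$unit, norm$values[fid, ])
  }

  panel <- cand$feature_id[1]
  current <- outputs[[panel]]
  trace <- roc_auc(current, status, compute_cutoff = FALSE)$auc
  combiners <- list()
  remaining <- setdiff(cand$feature_id, panel)
  layer <- 1L
  while (length(remaining)) {
    layer <- layer + 1L
    best <- NULL
    for (fid in remaining) {
      idx <- match(fid, cand$feature_id)
      fit <- train_rbf(cbind(current, outputs[[fid]]), status,
                       seed = derive_seed(seed, 71L, layer, idx),
                       restarts = restarts, k = k)
      fit$unit$input_refs <- c("cascade", fid)
      out <- predict_rbf(fit$unit, cbind(current, outputs[[fid]]))
      auc <- roc_auc(out, status, compute_cutoff = FALSE)$auc
      # remaining is already in entry order, so strict > keeps the
      # highest-screening-AUC candidate on ties
      if (is.null(best) || auc > best$auc) {
        best <- list(fid = fid, unit = fit$unit, out = out, auc = auc)
      }
    }
    if (best$auc - trace[length(trace)] <= epsilon) break
    panel <- c(panel, best$fid)
    combiners[[length(combiners) + 1L]] <- best$unit
    current <- best$out
    trace <- c(trace, best$auc)
    remaining <- setdiff(remaining, best$fid)
  }
  cascade_finalize(norm, status, panel, units[panel], combiners, trace,
                   epsilon, normalization, seed, current)
}

#' Train a cascade with a fixed, pre-selected panel
#'
#' Re-trains all unit weights for a given ordered panel without re-running
#' the greedy selection — the operation cross-validation repeats on each
#' fold.  The AUC trace is recorded per layer but no gain requirement is
#' imposed.
#'
#' @inheritParams build_cascade
#' @param panel Ordered character vector of panel feature IDs.
#' @return A `cascade_model`.
#' @export
train_cascade_fixed <- function(matrix, labels, panel, seed = 1L,
                                normalization = NULL, restarts = 5L,
                                k = 11L) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(labels, "cohort_labels"))
  panel <- as.character(panel)
  if (!length(panel)) stop2("empty panel")
  if (is.null(normalization)) {
    normalization <- fit_normalization(
      subset_matrix(matrix, features = panel), matrix$sample_ids)
  }
  norm <- apply_normalization(subset_matrix(matrix, features = panel),
                              normalization)
  status <- status_for(labels, norm$sample_ids)
  units <- list()
  combiners <- list()
  trace <- numeric(0)
  current <- NULL
  for (i in seq_along(panel)) {
    fid <- panel[i]
    fit <- train_rbf(norm$values[fid, ], status,
                     seed = derive_seed(seed, 61L, i), restarts = restarts,
                     k = k)
    fit$unit$input_refs <- fid
    units[[fid]] <- fit$unit
    out <- predict_rbf(fit$unit, norm$values[fid, ])
    if (i == 1L) {
      current <- out
    } else {
      cfit <- train_rbf(cbind(current, out), status,
                        seed = derive_seed(seed, 71L, i), restarts = restarts,
                        k = k)
      cfit$unit$input_refs <- c("cascade", fid)
      combiners[[i - 1L]] <- cfit$unit
      current <- predict_rbf(cfit$unit, cbind(current, out))
    }
    trace <- c(trace, roc_auc(current, status, compute_cutoff = FALSE)$auc)
  }
  cascade_finalize(norm, status, panel, units, combiners, trace, NA_real_,
                   normalization, seed, current)
}

#' Predict with a cascade model
#'
#' Normalizes the panel features with the model's stored parameters (values
#' outside the training range are clipped), runs the forward pass through
#' feature units and combiners in layer order, and thresholds the final
#' score at the frozen decision cutoff.
#'
#' @param model A `cascade_model`.
#' @param matrix An [expression_matrix()] containing every panel feature.
#' @return List with `scores` (raw cascade outputs, named by sample) and
#'   `classes` (0/1 integer vector).
#' @export
predict_cascade <- function(model, matrix) {
  stopifnot(inherits(model, "cascade_model"),
            inherits(matrix, "expression_matrix"))
  missing <- setdiff(model$panel, matrix$feature_ids)
  if (length(missing)) stop2("panel feature missing from matrix: ",
                             missing[1])
  norm <- apply_normalization(subset_matrix(matrix, features = model$panel),
                              model$normalization)
  current <- NULL
  for (i in seq_along(model$panel)) {
    fid <- model$panel[i]
    out <- predict_rbf(model$feature_units[[i]], norm$values[fid, ])
    current <- if (i == 1L) out
               else predict_rbf(model$combiner_units[[i - 1L]],
                                cbind(current, out))
  }
  names(current) <- matrix$sample_ids
  classes <- as.integer(model$polarity * current > model$decision_cutoff)
  list(scores = current, classes = classes)
}

#' Save / load a cascade model as versioned JSON
#'
#' Numeric fields survive the round trip bit-exactly (17 significant digits),
#' so a reloaded model yields identical predictions.
#'
#' @param model A `cascade_model`.
#' @param path JSON file path.
#' @return `path` (save) or the reloaded `cascade_model` (load).
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  x <- unclass(model)
  x$feature_units <- lapply(x$feature_units, rbf_to_list)
  x$combiner_units <- lapply(x$combiner_units, rbf_to_list)
  x$normalization <- list(min = as.list(x$normalization$min),
                          max = as.list(x$normalization$max))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop2("cannot parse model file: ",
                                          conditionMessage(e)))
  if (!identical(x$schema, "mircascade-cascade-1")) {
    stop2("unrecognized model schema: ",
          if (is.null(x$schema)) "<missing>" else x$schema)
  }
  f_units <- lapply(seq_len(nrow_or_len(x$feature_units)),
                    function(i) rbf_from_list(pluck_row(x$feature_units, i)))
  c_units <- lapply(seq_len(nrow_or_len(x$combiner_units)),
                    function(i) rbf_from_list(pluck_row(x$combiner_units, i)))
  params <- structure(list(min = unlist(x$normalization$min),
                           max = unlist(x$normalization$max)),
                      class = "normalization_params")
  new_cascade_model(as.character(x$panel), f_units, c_units,
                    as.numeric(x$layer_auc_trace), x$epsilon, params,
                    x$decision_cutoff, x$polarity, x$seed)
}

# jsonlite may simplify a homogeneous list of unit records into a data frame;
# normalize access either way.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pluck_row <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col) {
    v <- col[i]
    if (is.list(v)) v[[1]] else v
  }) else x[[i]]
}
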