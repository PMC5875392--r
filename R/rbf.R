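# A single radial-basis-function network unit with fixed n-11-1 architecture
# (n = 1 or 2 inputs, 11 Gaussian hidden units, 1 linear output).
#
# Training recipe: hidden-unit centers by seeded k-means on the training
# subset; width sigma_j = mean distance from center j to its 2 nearest
# fellow centers (floored at 1e-3); output layer by ridge-regularized least
# squares (lambda = 1e-6, intercept unpenalized) of the 0/1 targets on the
# Gaussian design.  Each call performs an internal stratified 2:1:1
# training/verification/testing hold-out; the verification subset selects
# among random restarts, the testing subset is never used for any selection.

#' Stratified 2:1:1 hold-out split
#'
#' Per class: the training subset receives `round(n/2)` samples (half up),
#' the verification subset `round(n/4)`, the testing subset the remainder;
#' assignment is a seeded shuffle.  Each class must have at least 8 samples
#' so that every subset holds both classes with >= 2 members.
#'
#' @param ids Sample ID vector.
#' @param labels A [cohort_labels()] covering `ids`.
#' @param seed Integer seed.
#' @return List with `train`, `verification`, `test` ID vectors.
#' @export
holdout_split <- function(ids, labels, seed = 1L) {
  ids <- as.character(ids)
  status <- status_for(labels, ids)
  out <- list(train = character(0), verification = character(0),
              test = character(0))
  for (cls in c(1L, 0L)) {
    cid <- ids[status == cls]
    n <- length(cid)
    if (n < 8L) {
      stop2("class ", cls, " has ", n,
            " samples; need >= 8 to populate a 2:1:1 hold-out")
    }
    n_tr <- round_half_up(n / 2)
    n_ve <- round_half_up(n / 4)
    perm <- with_seed(derive_seed(seed, 21L, cls), sample.int(n))
    out$train <- c(out$train, cid[perm[seq_len(n_tr)]])
    out$verification <- c(out$verification, cid[perm[n_tr + seq_len(n_ve)]])
    out$test <- c(out$test, cid[perm[(n_tr + n_ve + 1L):n]])
  }
  out
}

# Integer-index variant used internally when observations have no IDs.
holdout_split_idx <- function(status, seed) {
  ids <- as.character(seq_along(status))
  labels <- cohort_labels(ids, status)
  lapply(holdout_split(ids, labels, seed), as.integer)
}

rbf_unit <- function(centers, widths, weights, bias, input_refs) {
  centers <- as.matrix(centers)
  stopifnot(length(widths) == nrow(centers),
            length(weights) == nrow(centers), all(widths > 0))
  structure(list(n_inputs = ncol(centers), centers = unname(centers),
                 widths = as.numeric(widths), weights = as.numeric(weights),
                 bias = as.numeric(bias),
                 input_refs = as.character(input_refs)),
            class = "rbf_unit")
}

#' @export
print.rbf_unit <- function(x, ...) {
  cat("rbf_unit:", x$n_inputs, "-", nrow(x$centers), "- 1 (inputs: ",
      paste(x$input_refs, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

rbf_design <- function(unit_or_centers, widths, x) {
  x <- as.matrix(x)
  centers <- unit_or_centers
  k <- nrow(centers)
  phi <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    d2 <- rowSums((x - matrix(centers[j, ], nrow(x), ncol(x),
                              byrow = TRUE))^2)
    phi[, j] <- exp(-d2 / (2 * widths[j]^2))
  }
  phi
}

#' Forward pass of an RBF unit
#'
#' `y_i = bias + sum_j w_j * exp(-||x_i - c_j||^2 / (2 sigma_j^2))`; outputs
#' are raw reals (no clamping or thresholding).
#'
#' @param unit An `rbf_unit`.
#' @param inputs Numeric vector (1-input unit) or matrix with `n_inputs`
#'   columns.
#' @return Numeric vector of outputs.
#' @export
predict_rbf <- function(unit, inputs) {
  stopifnot(inherits(unit, "rbf_unit"))
  x <- if (is.null(dim(inputs))) matrix(as.numeric(inputs), ncol = 1L)
       else as.matrix(inputs)
  if (ncol(x) != unit$n_inputs) {
    stop2("input has ", ncol(x), " columns; unit expects ", unit$n_inputs)
  }
  phi <- rbf_design(unit$centers, unit$widths, x)
  as.numeric(unit$bias + phi %*% unit$weights)
}

# Seeded k-means with distinct initial centers; retries on the rare
# empty-cluster failure, falling back to MacQueen.
seeded_kmeans <- function(x, k, seed) {
  x <- as.matrix(x)
  ux <- unique(x)
  k <- min(k, nrow(ux))
  for (attempt in 1:6) {
    init <- with_seed(derive_seed(seed, 31L, attempt),
                      ux[sample.int(nrow(ux), k), , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 50L,
                                     algorithm = if (attempt <= 3)
                                       "Hartigan-Wong" else "MacQueen")),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit$centers)
  }
  stop2("k-means failed to converge for k = ", k)
}

fit_rbf_layer <- function(x_tr, y_tr, k, width_neighbors, lambda, seed,
                          input_refs) {
  centers <- seeded_kmeans(x_tr, k, seed)
  k_eff <- nrow(centers)
  if (k_eff < k) {
    warning("reduced hidden layer to ", k_eff,
            " units (only ", k_eff, " distinct centers)", call. = FALSE)
  }
  if (k_eff >= 2L) {
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    widths <- apply(d, 1L, function(r) {
      mean(sort(r)[seq_len(min(width_neighbors, k_eff - 1L))])
    })
  } else {
    widths <- stats::sd(as.numeric(x_tr))
  }
  widths <- pmax(widths, 1e-3)
  phi <- rbf_design(centers, widths, x_tr)
  a <- cbind(1, phi)
  pen <- diag(c(0, rep(lambda, k_eff)))
  beta <- solve(crossprod(a) + pen, crossprod(a, y_tr))
  rbf_unit(centers, widths, beta[-1], beta[1], input_refs)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Train an RBF unit with internal hold-out and random restarts
#'
#' Performs a stratified 2:1:1 hold-out of the observations, trains
#' `restarts` candidate units on the training subset (k-means center
#' placement differs per restart), keeps the restart with the highest
#' verification-subset correlation between unit output and target status,
#' and reports the training/verification/testing correlations R_Tr, R_Ve,
#' R_Te of the kept unit.  Similar R_Tr and R_Te indicate the unit
#' generalizes.
#'
#' @param inputs Numeric vector or matrix (`n_obs x n_inputs`, `n_inputs`
#'   1 or 2), normally normalized to `[0, 1]`.
#' @param targets 0/1 status vector.
#' @param seed Integer seed (drives both the hold-out and the restarts).
#' @param restarts Number of random restarts (default 5).
#' @param k Hidden-layer size (default 11; reduced with a warning when the
#'   training subset has fewer distinct points).
#' @param width_neighbors Number of nearest centers averaged into each width
#'   (default 2).
#' @param lambda Ridge penalty on the output weights (default 1e-6).
#' @return List with `unit` (an `rbf_unit`) and `report` (class
#'   `training_report`: `r_tr`, `r_ve`, `r_te`, `subset_sizes`, `seed`).
#' @export
train_rbf <- function(inputs, targets, seed = 1L, restarts = 5L, k = 11L,
                      width_neighbors = 2L, lambda = 1e-6) {
  x <- if (is.null(dim(inputs))) matrix(as.numeric(inputs), ncol = 1L)
       else as.matrix(inputs)
  if (!ncol(x) %in% 1:2) stop2("n_inputs must be 1 or 2")
  y <- as.integer(targets)
  if (nrow(x) != length(y)) stop2("inputs/targets length mismatch")
  if (nrow(unique(x)) < 2L) stop2("fewer than 2 distinct input points")
  parts <- holdout_split_idx(y, derive_seed(seed, 41L))
  x_tr <- x[parts$train, , drop = FALSE]
  y_tr <- y[parts$train]

  best <- NULL
  best_rve <- -Inf
  for (r in seq_len(restarts)) {
    unit <- fit_rbf_layer(x_tr, y_tr, k, width_neighbors, lambda,
                          derive_seed(seed, 51L, r), input_refs = "")
    rve <- safe_cor(predict_rbf(unit, x[parts$verification, , drop = FALSE]),
                    y[parts$verification])
    score <- if (is.na(rve)) -Inf else rve
    if (score > best_rve) {
      best_rve <- score
      best <- unit
    }
  }
  report <- structure(list(
    r_tr = safe_cor(predict_rbf(best, x_tr), y_tr),
    r_ve = safe_cor(predict_rbf(best, x[parts$verification, , drop = FALSE]),
                    y[parts$verification]),
    r_te = safe_cor(predict_rbf(best, x[parts$test, , drop = FALSE]),
                    y[parts$test]),
    subset_sizes = lengths(parts), seed = as.integer(seed)),
    class = "training_report")
  list(unit = best, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("training_report: R_Tr %.3f, R_Ve %.3f, R_Te %.3f (n = %s)\n",
              x$r_tr, x$r_ve, x$r_te,
              paste(x$subset_sizes, collapse = "/")))
  invisible(x)
}

# JSON-friendly (de)serialization used by the cascade model.
rbf_to_list <- function(unit) {
  list(n_inputs = unit$n_inputs, centers = unit$centers,
       widths = unit$widths, weights = unit$weights, bias = unit$bias,
       input_refs = unit$input_refs)
}

rbf_from_list <- function(x) {
  centers <- matrix(unlist(x$centers), ncol = x$n_inputs)
  rbf_unit(centers, x$widths, x$weights, x$bias, x$input_refs)
}
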