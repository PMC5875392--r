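# ROC/AUC with significance, Youden operating point, classification metrics.
#
# The AUC is the Mann-Whitney two-sample statistic: the probability that a
# random case scores above a random control (ties count 1/2).  Its standard
# error follows Hanley & McNeil; the p-value against AUC = 0.5 is a two-sided
# normal test using the tie-corrected Mann-Whitney variance, which is accurate
# at the cohort sizes this pipeline targets (thousands of samples).

#' ROC curve analysis of a score vector against binary status
#'
#' @param scores Numeric vector.
#' @param status 0/1 vector of the same length; both classes must be present.
#' @param compute_cutoff If `TRUE` (default) also locate the Youden-optimal
#'   cutoff and its sensitivity/specificity.
#' @return An object of class `roc_result`: list with `auc` (polarity-adjusted,
#'   in `[0.5, 1]`), `se` (Hanley-McNeil), `p_value`, `polarity` (+1 if high
#'   scores indicate cases, -1 if the orientation was flipped), `cutoff`
#'   (on the polarity-oriented scale, i.e. applied to `polarity * scores`),
#'   `sensitivity`, `specificity`, `n_cases`, `n_controls`.
#' @details Down-regulated features are handled by polarity flipping: the AUC
#'   is always reported >= 0.5 together with the orientation that achieves it.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3, 0.5, 0.2), c(1, 1, 1, 0, 0, 0))$auc  # 8/9
roc_auc <- function(scores, status, compute_cutoff = TRUE) {
  scores <- as.numeric(scores)
  status <- as.integer(status)
  if (!length(scores)) stop2("empty input")
  if (length(scores) != length(status)) stop2("scores/status length mismatch")
  if (anyNA(scores) || anyNA(status)) stop2("NA in scores or status")
  if (!all(status %in% c(0L, 1L))) stop2("status must be 0/1")
  n1 <- as.numeric(sum(status == 1L)) # double: n1 * n0 overflows int32
  n0 <- as.numeric(sum(status == 0L))
  if (n1 == 0 || n0 == 0) stop2("both classes must be present")
  r <- rank(scores) # midranks
  auc_raw <- (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  polarity <- if (auc_raw >= 0.5) 1L else -1L
  auc <- max(auc_raw, 1 - auc_raw)

  # Hanley-McNeil standard error of the polarity-adjusted AUC.
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))

  # Two-sided Mann-Whitney test of AUC = 0.5 with tie correction.
  n <- n1 + n0
  ties <- table(scores)
  v <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (v <= 0) 1 else {
    z <- (auc_raw * n1 * n0 - n1 * n0 / 2) / sqrt(v)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  if (p == 0) p <- .Machine$double.xmin

  res <- list(auc = auc, se = se, p_value = p, polarity = polarity,
              cutoff = NA_real_, sensitivity = NA_real_,
              specificity = NA_real_, n_cases = n1, n_controls = n0)
  if (compute_cutoff) {
    yc <- youden_cutoff(scores, status, polarity)
    res$cutoff <- yc$cutoff
    res$sensitivity <- yc$sensitivity
    res$specificity <- yc$specificity
  }
  structure(res, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: AUC %.4f (SE %.4f, p %.3g, polarity %+d), cutoff %.4g, sens %.3f, spec %.3f\n",
    x$auc, x$se, x$p_value, x$polarity, x$cutoff, x$sensitivity,
    x$specificity))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over all midpoints between
#' adjacent distinct polarity-oriented scores, with `-Inf`/`+Inf` sentinels at
#' the extremes.  A sample is called positive when its oriented score exceeds
#' the cutoff.  Ties in J are broken toward the lowest cutoff, so the result
#' is deterministic.
#'
#' @inheritParams roc_auc
#' @param polarity +1 or -1; the cutoff is searched on `polarity * scores`.
#' @return List with `cutoff` (oriented scale), `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, status, polarity = 1L) {
  scores <- as.numeric(scores)
  status <- as.integer(status)
  if (!length(scores)) stop2("empty input")
  if (!polarity %in% c(-1L, 1L)) stop2("polarity must be +1 or -1")
  n1 <- sum(status == 1L)
  n0 <- sum(status == 0L)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present")
  s <- polarity * scores
  us <- sort(unique(s))
  cuts <- c(-Inf, if (length(us) > 1L) (us[-1] + us[-length(us)]) / 2, Inf)
  cases <- sort(s[status == 1L])
  controls <- sort(s[status == 0L])
  # sens(c) = P(case > c), spec(c) = P(control <= c)
  sens <- 1 - findInterval(cuts, cases) / n1
  spec <- findInterval(cuts, controls) / n0
  j <- sens + spec - 1
  # J values differing by < 1e-9 are ties (floating-point noise; the true J
  # granularity is ~1/(n_cases * n_controls)); pick the lowest such cutoff.
  best <- which(j >= max(j) - 1e-9)[1]
  list(cutoff = cuts[best], sensitivity = sens[best], specificity = spec[best])
}

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / total, each expressed as a percentage.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts.
#' @return List with `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
#' @examples
#' classification_metrics(95, 3, 97, 5) # 95%, 97%, 96%
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop2("confusion counts must be non-negative integers")
  }
  if (tp + fn == 0) stop2("no positive samples (tp + fn = 0)")
  if (tn + fp == 0) stop2("no negative samples (tn + fp = 0)")
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / (tp + fp + tn + fn))
}

confusion_counts <- function(predicted, status) {
  predicted <- as.integer(predicted)
  status <- as.integer(status)
  list(tp = sum(predicted == 1L & status == 1L),
       fp = sum(predicted == 1L & status == 0L),
       tn = sum(predicted == 0L & status == 0L),
       fn = sum(predicted == 0L & status == 1L))
}
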