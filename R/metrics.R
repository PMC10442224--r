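#' Confusion counts at a threshold
#'
#' A sample is predicted positive iff its score is greater than or equal to
#' the threshold (the cut is closed on the positive side).
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels binary vector (0/1) of true labels.
#' @param threshold decision threshold.
#' @return an object of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- check_binary(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pred <- scores >= threshold
  structure(
    list(tp = sum(pred & labels == 1L), fp = sum(pred & labels == 0L),
         tn = sum(!pred & labels == 0L), fn = sum(!pred & labels == 1L)),
    class = "confusion_counts"
  )
}

check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  labels
}

#' Classification metrics with normal-approximation CIs
#'
#' Sensitivity, specificity, PPV, NPV and F1 from confusion counts, each with
#' a 95 percent CI from the normal approximation to a binomial proportion,
#' `p +/- 1.96 * sqrt(p(1-p)/n)` clipped to [0,1]. A metric whose denominator
#' is zero is reported as `NA` (undefined) rather than raising.
#'
#' @param c a `confusion_counts` object.
#' @param level confidence level (default 0.95).
#' @return a list with one `c(value, low, high)` entry per metric plus
#'   scalar `f1`.
#' @export
classification_metrics <- function(c, level = 0.95) {
  stopifnot(inherits(c, "confusion_counts"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  prop <- function(num, den) {
    if (den == 0) return(c(value = NA_real_, low = NA_real_, high = NA_real_))
    p <- num / den
    se <- sqrt(p * (1 - p) / den)
    c(value = p, low = max(0, p - z * se), high = min(1, p + z * se))
  }
  sens <- prop(c$tp, c$tp + c$fn)
  spec <- prop(c$tn, c$tn + c$fp)
  ppv <- prop(c$tp, c$tp + c$fp)
  npv <- prop(c$tn, c$tn + c$fn)
  f1 <- if (is.na(sens["value"]) || is.na(ppv["value"]) ||
            (sens["value"] + ppv["value"]) == 0) {
    NA_real_
  } else {
    unname(2 * sens["value"] * ppv["value"] / (sens["value"] + ppv["value"]))
  }
  list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' positive outscores a uniformly random negative, counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUROC in [0,1].
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC requires both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil confidence interval for an AUROC
#'
#' Standard error
#' `SE = sqrt((A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)) / (n+ n-))`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`; the interval is
#' `A +/- z * SE` clipped to [0,1].
#'
#' @param auc AUROC point estimate in [0,1].
#' @param n_pos,n_neg class sizes (>= 1).
#' @param level confidence level (default 0.95).
#' @return a list with `se`, `low`, `high`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  if (auc < 0 || auc > 1) stop("auc must lie in [0,1]")
  if (n_pos < 1 || n_neg < 1) stop("class sizes must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(se = se, low = max(0, auc - z * se), high = min(1, auc + z * se))
}

#' Equalized-odds dispersion across sensitive groups
#'
#' Computes each group's true positive rate `TP/(TP+FN)` and false positive
#' rate `FP/(FP+TN)` at the given threshold, and summarizes fairness as the
#' population standard deviation (divide by the number of groups — the
#' groups are the complete set, not a sample) of each rate across groups.
#' Zero dispersion means the classifier satisfies equalized odds exactly.
#' A group with no positives (or no negatives) has an undefined rate and is
#' excluded from the corresponding s.d. with a warning.
#'
#' @param scores numeric positive-class scores.
#' @param labels binary 0/1 labels.
#' @param groups group index per sample (0-based integers or a factor).
#' @param threshold decision threshold (predict positive iff score >=
#'   threshold).
#' @param group_levels optional character names for the groups.
#' @return an object of class `fairness_report`: per-group `tpr` and `fpr`,
#'   `sd_tp`, `sd_fp`, and the group labels.
#' @export
equalized_odds_sd <- function(scores, labels, groups, threshold,
                              group_levels = NULL) {
  labels <- check_binary(labels)
  if (is.factor(groups)) {
    if (is.null(group_levels)) group_levels <- levels(groups)
    groups <- as.integer(groups) - 1L
  }
  groups <- as.integer(groups)
  m <- max(groups) + 1L
  if (is.null(group_levels)) group_levels <- as.character(seq_len(m) - 1L)
  m <- max(m, length(group_levels))
  tpr <- fpr <- rep(NA_real_, m)
  for (g in seq_len(m) - 1L) {
    in_g <- groups == g
    pos <- sum(in_g & labels == 1L)
    neg <- sum(in_g & labels == 0L)
    pred <- scores >= threshold
    if (pos > 0) tpr[g + 1L] <- sum(in_g & labels == 1L & pred) / pos
    if (neg > 0) fpr[g + 1L] <- sum(in_g & labels == 0L & pred) / neg
  }
  if (anyNA(tpr)) {
    warning("group(s) with no positives excluded from sd_tp: ",
            paste(group_levels[is.na(tpr)], collapse = ", "))
  }
  if (anyNA(fpr)) {
    warning("group(s) with no negatives excluded from sd_fp: ",
            paste(group_levels[is.na(fpr)], collapse = ", "))
  }
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }
  structure(
    list(tpr = stats::setNames(tpr, group_levels),
         fpr = stats::setNames(fpr, group_levels),
         sd_tp = pop_sd(tpr), sd_fp = pop_sd(fpr),
         threshold = threshold, group_levels = group_levels),
    class = "fairness_report"
  )
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("<fairness_report> sd_TP = %.6f, sd_FP = %.6f at threshold %.4g\n",
              x$sd_tp, x$sd_fp, x$threshold))
  print(data.frame(group = x$group_levels, TPR = x$tpr, FPR = x$fpr,
                   row.names = NULL))
  invisible(x)
}

#' Calibrate a decision threshold to a target sensitivity
#'
#' Scans the sorted unique validation scores and returns the largest
#' threshold whose validation sensitivity is at least the target. Because
#' specificity is non-decreasing in the threshold, this choice also
#' maximizes specificity among all thresholds meeting the target.
#'
#' @param scores_val validation positive-class scores.
#' @param labels_val binary 0/1 validation labels; must contain positives.
#' @param target_sensitivity required sensitivity in [0,1].
#' @return the calibrated threshold.
#' @export
adjust_threshold <- function(scores_val, labels_val, target_sensitivity) {
  labels_val <- check_binary(labels_val)
  n_pos <- sum(labels_val == 1L)
  if (n_pos == 0L) stop("validation set contains no positives")
  cand <- sort(unique(scores_val), decreasing = TRUE)
  for (thr in cand) {
    sens <- sum(scores_val >= thr & labels_val == 1L) / n_pos
    if (sens >= target_sensitivity) return(thr)
  }
  cand[length(cand)]   # lowest score: sensitivity 1 is always reachable
}

#' Paired comparison of two classifiers' accuracy
#'
#' Converts each model's predictions into per-sample correctness indicators
#' and applies the Wilcoxon signed-rank test to the paired differences
#' (zero differences dropped, as is standard). Returns the two-sided p-value;
#' if every difference is zero the models are indistinguishable and p = 1.
#'
#' @param preds_a,preds_b binary 0/1 predictions of the two models.
#' @param labels binary 0/1 true labels.
#' @return two-sided p-value.
#' @export
paired_accuracy_test <- function(preds_a, preds_b, labels) {
  labels <- check_binary(labels)
  if (length(preds_a) != length(labels) || length(preds_b) != length(labels)) {
    stop("prediction vectors must match labels in length")
  }
  d <- as.integer(preds_a == labels) - as.integer(preds_b == labels)
  d <- d[d != 0L]
  if (!length(d)) return(1)
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value
  )
}
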