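# Diagnostic-test statistics for neck circumference as an OSA screening
# score: ROC curve and AUC (tie-aware, identical to the Mann-Whitney U
# statistic scaled by n1*n2), Hanley-McNeil confidence interval, cutoff
# metric tables with likelihood ratios, Youden-optimal cutoff selection,
# and the nonparametric rank tests used alongside (Spearman, Mann-Whitney).

#' ROC curve and AUC
#'
#' Higher scores indicate the positive class. The AUC is computed from mid
#' ranks, so tied scores contribute 1/2 and the identity
#' `AUC = U / (n_pos * n_neg)` with the Mann-Whitney U statistic holds
#' exactly. Curve points are evaluated at every distinct score with the
#' test-positive rule `score > cutoff`.
#'
#' @param scores Numeric scores (e.g. neck circumference in cm).
#' @param labels Logical (or 0/1) vector, TRUE for the positive class.
#' @param level Confidence level for the AUC interval.
#' @return Object of class `roc_result`: `curve` (data frame `cutoff`,
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `auc`, `ci_low`,
#'   `ci_high`, `n_positive`, `n_negative`, `level`.
#' @examples
#' roc_auc(c(3, 4, 5, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  rk <- rank(scores) # mid ranks for ties
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  cuts <- sort(unique(scores))
  tpr <- vapply(cuts, function(ct) mean(scores[labels] > ct), 0)
  fpr <- vapply(cuts, function(ct) mean(scores[!labels] > ct), 0)
  curve <- data.frame(cutoff = c(-Inf, cuts), fpr = c(1, fpr),
                      tpr = c(1, tpr))
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  ci <- auc_confidence_interval(auc, n_pos, n_neg, level)
  structure(list(curve = curve, auc = auc,
                 ci_low = ci[1], ci_high = ci[2],
                 n_positive = n_pos, n_negative = n_neg, level = level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval using the Hanley-McNeil standard error;
#' bounds are clipped to \[0, 1\]. A degenerate AUC of 0 or 1 has zero
#' standard error and is flagged.
#'
#' @param auc AUC estimate.
#' @param n_pos,n_neg Class sizes.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` with attributes `se` and `degenerate`.
#' @export
auc_confidence_interval <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(n_pos > 0, n_neg > 0, auc >= 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(max(0, auc - z * se), min(1, auc + z * se))
  attr(out, "se") <- se
  attr(out, "degenerate") <- se == 0
  out
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `LR+ = sensitivity / (1 - specificity)` (how much the odds of disease
#' rise after a positive test) and `LR- = (1 - sensitivity) / specificity`
#' (how much they fall after a negative one). Undefined ratios (division by
#' zero) are returned as `Inf`.
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @return List with `lr_pos` and `lr_neg`.
#' @examples
#' likelihood_ratios(0.8099, 0.5185) # LR+ 1.68, LR- 0.37
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  list(lr_pos = if (specificity < 1) sensitivity / (1 - specificity) else Inf,
       lr_neg = if (specificity > 0) (1 - sensitivity) / specificity else Inf)
}

#' Diagnostic metrics at a list of cutoffs
#'
#' Test-positive means `score > cutoff`. Reports sensitivity, specificity,
#' PPV, NPV, LR+ and LR- for every cutoff; as the cutoff grows, sensitivity
#' is non-increasing and specificity non-decreasing.
#'
#' @inheritParams roc_auc
#' @param cutoffs Numeric vector of cutoffs (non-empty).
#' @return Data frame with one row per cutoff.
#' @export
cutoff_metrics_table <- function(scores, labels, cutoffs) {
  labels <- as.logical(labels)
  if (length(cutoffs) == 0) stop("cutoff list is empty")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  rows <- lapply(cutoffs, function(ct) {
    pos_test <- scores > ct
    tp <- sum(pos_test & labels); fp <- sum(pos_test & !labels)
    fn <- n_pos - tp; tn <- n_neg - fp
    se <- tp / n_pos; sp <- tn / n_neg
    lr <- likelihood_ratios(se, sp)
    data.frame(cutoff = ct, sensitivity = se, specificity = sp,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               lr_pos = lr$lr_pos, lr_neg = lr$lr_neg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Youden-optimal cutoff
#'
#' Selects the candidate cutoff maximizing the Youden index
#' `J = sensitivity + specificity - 1`; ties go to the smallest cutoff.
#' `youden_from_table()` applies the same rule to an existing table of
#' (cutoff, sensitivity, specificity) rows.
#'
#' @inheritParams cutoff_metrics_table
#' @param candidate_cutoffs Cutoffs to consider; defaults to the integer cm
#'   values spanning the observed score range.
#' @return The selected cutoff, with the Youden index as attribute `J`.
#' @export
youden_optimal_cutoff <- function(scores, labels, candidate_cutoffs = NULL) {
  if (is.null(candidate_cutoffs))
    candidate_cutoffs <- seq(floor(min(scores)), ceiling(max(scores)))
  tab <- cutoff_metrics_table(scores, labels, candidate_cutoffs)
  youden_from_table(tab)
}

#' @rdname youden_optimal_cutoff
#' @param table Data frame with `cutoff`, `sensitivity`, `specificity`.
#' @export
youden_from_table <- function(table) {
  stopifnot(all(c("cutoff", "sensitivity", "specificity") %in% names(table)))
  j <- table$sensitivity + table$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(table$cutoff[best])]
  structure(table$cutoff[pick], J = j[pick])
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation (two-sided).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = rho, p_value = ct$p.value, n = length(x))
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with average ranks for ties (orientation: number of
#' (x, y) pairs with x > y, ties counting 1/2, so
#' `U / (n1 * n2)` equals the ROC AUC of x against y exactly). The p-value
#' uses the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return List with `U`, `p_value`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  list(U = u, p_value = p, n1 = n1, n2 = n2)
}
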