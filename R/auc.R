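# AUC and DeLong variance/covariance machinery.
#
# The AUC is the Mann-Whitney probability that a randomly chosen positive
# outscores a randomly chosen negative (ties counted half). Standard errors,
# confidence intervals and paired/unpaired AUC-difference tests use the
# placement-value (structural components) estimator of DeLong.

#' Area under the ROC curve
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (0/1); both classes must be present.
#' @return The AUC as a single number in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC is undefined when one outcome class is absent", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values via midranks (exact under ties):
#   v10[i] = P-hat(X_i beats a random negative), one per positive
#   v01[j] = P-hat(a random positive beats Y_j), one per negative
placement_values <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

delong_variance <- function(pv) {
  if (pv$n1 < 2L || pv$n0 < 2L)
    stop("DeLong variance needs at least 2 members of each class", call. = FALSE)
  var(pv$v10) / pv$n1 + var(pv$v01) / pv$n0
}

#' DeLong standard error and confidence interval for an AUC
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes; each class needs at least 2 members.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci_low`, `ci_high` (normal-approximation
#'   interval, clipped to \[0, 1\]).
#' @export
delong_se_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)),
            level > 0, level < 1)
  pv <- placement_values(scores, labels)
  se <- sqrt(delong_variance(pv))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = pv$auc, se = se,
       ci_low = max(0, pv$auc - z * se),
       ci_high = min(1, pv$auc + z * se))
}

#' DeLong test for a difference between two AUCs
#'
#' Paired comparison (two score vectors for the identical admissions with the
#' identical outcomes, e.g. a cross-validated model versus a transferred
#' model on the same site) uses the DeLong covariance of the placement
#' values; unpaired comparison (different data sets) adds the two independent
#' variances. Two-sided normal test.
#'
#' @param scores_1,scores_2 Score vectors for the two models.
#' @param labels_1 Binary outcomes for `scores_1`.
#' @param labels_2 Binary outcomes for `scores_2` (must be identical to
#'   `labels_1` when `paired = TRUE`; defaults to it).
#' @param paired Logical; see Details.
#' @param level Confidence level for the difference interval.
#' @param alpha Significance gate (default 0.01).
#' @return An `auc_comparison`: `auc_1`, `auc_2`, `auc_diff`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `paired`, `significant`.
#' @export
delong_compare <- function(scores_1, scores_2, labels_1, labels_2 = labels_1,
                           paired = TRUE, level = 0.95, alpha = 0.01) {
  labels_1 <- as.integer(labels_1); labels_2 <- as.integer(labels_2)
  stopifnot(length(scores_1) == length(labels_1),
            length(scores_2) == length(labels_2))
  if (paired) {
    if (!identical(labels_1, labels_2))
      stop("a paired comparison requires identical outcomes on identical admissions",
           call. = FALSE)
    p1 <- placement_values(scores_1, labels_1)
    p2 <- placement_values(scores_2, labels_2)
    v <- var(p1$v10) / p1$n1 + var(p1$v01) / p1$n0 +
      var(p2$v10) / p2$n1 + var(p2$v01) / p2$n0 -
      2 * (stats::cov(p1$v10, p2$v10) / p1$n1 +
             stats::cov(p1$v01, p2$v01) / p1$n0)
    v <- max(v, 0)
    a1 <- p1$auc; a2 <- p2$auc
  } else {
    d1 <- delong_se_ci(scores_1, labels_1, level)
    d2 <- delong_se_ci(scores_2, labels_2, level)
    v <- d1$se^2 + d2$se^2
    a1 <- d1$auc; a2 <- d2$auc
  }
  diff <- a1 - a2
  se <- sqrt(v)
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    if (diff == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(diff / se))
  }
  structure(list(auc_1 = a1, auc_2 = a2, auc_diff = diff, se = se,
                 ci_low = diff - z_crit * se, ci_high = diff + z_crit * se,
                 p_value = p, paired = paired, significant = p < alpha),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("%s DeLong comparison: AUC %.3f vs %.3f\n",
              if (x$paired) "Paired" else "Unpaired", x$auc_1, x$auc_2))
  cat(sprintf("  difference %.3f (95%% CI %.3f to %.3f), p = %s%s\n",
              x$auc_diff, x$ci_low, x$ci_high, format.pval(x$p_value, digits = 3),
              if (x$significant) " *" else ""))
  invisible(x)
}
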