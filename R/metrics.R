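# Pooled confusion metrics: sensitivity, specificity and the relative risk of
# violent outcome among predicted-high-risk versus predicted-low-risk
# admissions, with approximate confidence intervals (Wilson for proportions,
# Katz log-scale for the relative risk).

wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

katz_rr_ci <- function(tp, fp, fn, tn, level = 0.95) {
  if (tp == 0 || fn == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  log_rr <- log((tp / (tp + fp)) / (fn / (fn + tn)))
  se <- sqrt(1 / tp - 1 / (tp + fp) + 1 / fn - 1 / (fn + tn))
  exp(log_rr + c(-1, 1) * z * se)
}

#' Pooled confusion metrics with relative risk
#'
#' Computes sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, and
#' the relative risk `[TP / (TP + FP)] / [FN / (FN + TN)]` — the risk of a
#' violent outcome among admissions predicted high-risk relative to those
#' predicted low-risk — from confusion counts pooled over cross-validation
#' folds. Metrics with a zero denominator are reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param tn,fn,tp,fp Nonnegative confusion counts. Alternatively pass a
#'   named vector from [confusion_counts()] as `tn`.
#' @param level Confidence level for the intervals.
#' @return A `pooled_metrics` list: the four counts, `n`, `sensitivity`,
#'   `specificity`, `relative_risk`, and their `*_ci` bounds.
#' @export
pooled_metrics <- function(tn, fn = NULL, tp = NULL, fp = NULL, level = 0.95) {
  if (length(tn) == 4L && is.null(fn)) {
    counts <- tn
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
  }
  stopifnot(tn >= 0, fn >= 0, tp >= 0, fp >= 0)

  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  risk_high <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  risk_low <- if (fn + tn > 0) fn / (fn + tn) else NA_real_
  rr <- if (!is.na(risk_high) && !is.na(risk_low) && risk_low > 0)
    risk_high / risk_low else NA_real_

  structure(list(
    tn = tn, fn = fn, tp = tp, fp = fp, n = tn + fn + tp + fp,
    sensitivity = sens, sensitivity_ci = wilson_ci(tp, tp + fn, level),
    specificity = spec, specificity_ci = wilson_ci(tn, tn + fp, level),
    relative_risk = rr, relative_risk_ci = katz_rr_ci(tp, fp, fn, tn, level)
  ), class = "pooled_metrics")
}

#' @export
print.pooled_metrics <- function(x, ...) {
  cat("<pooled_metrics>\n")
  cat(sprintf("  n = %d: TN %d, FN %d, TP %d, FP %d\n", x$n, x$tn, x$fn, x$tp, x$fp))
  fmt <- function(v, ci) {
    if (is.na(v)) return("undefined")
    sprintf("%.3f (%.3f-%.3f)", v, ci[1], ci[2])
  }
  cat("  sensitivity   ", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity   ", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  relative risk ", fmt(x$relative_risk, x$relative_risk_ci), "\n")
  invisible(x)
}
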