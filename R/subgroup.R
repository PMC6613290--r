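#' Subgroup predictive validity from pooled predictions
#'
#' Splits the evaluated admissions into two disjoint subgroups and computes
#' the AUC (with DeLong inference) in each, plus an unpaired DeLong
#' comparison between them — predictive validity for early versus late
#' violence, or for violence during short versus long admissions.
#'
#' For `short_long_admission` the split is by length of stay (default cutoff:
#' the cohort median). For `early_late_violence`, outcome-positive admissions
#' are split by the day of their first qualifying incident (default cutoff 14
#' days); outcome-negative admissions carry no incident day and are allocated
#' to the two subgroups at random (seeded), in proportion to the subgroup
#' positive counts, keeping the subgroups disjoint with a prevalence
#' comparable to the full cohort.
#'
#' @param result A `cv_result` or `transfer_result` (source of pooled
#'   predictions), or a tibble with `admission_id`, `label`, `score`.
#' @param cohort The `labeled_cohort` carrying `length_of_stay` and
#'   `first_incident_day`.
#' @param split `"early_late_violence"` or `"short_long_admission"`.
#' @param cutoff Split point in days; default 14 (early/late) or the cohort
#'   median length of stay (short/long).
#' @param seed Seed for the allocation of negatives (early/late split only).
#' @return A `subgroup_result`: per-subgroup [delong_se_ci()] summaries with
#'   sizes, and `comparison` (unpaired [delong_compare()], or `NULL` with a
#'   warning when a subgroup is empty or single-class).
#' @export
subgroup_auc <- function(result, cohort,
                         split = c("early_late_violence", "short_long_admission"),
                         cutoff = NULL, seed = 1L) {
  split <- match.arg(split)
  preds <- if (is.data.frame(result)) result else result$predictions
  idx <- match(preds$admission_id, cohort$admission_id)
  if (anyNA(idx)) stop("predictions do not match the cohort", call. = FALSE)
  los <- cohort$length_of_stay[idx]
  fid <- cohort$first_incident_day[idx]
  y <- preds$label
  s <- preds$score
  n <- length(y)

  if (split == "short_long_admission") {
    cutoff <- cutoff %||% stats::median(los)
    in_first <- los <= cutoff
    group_names <- c("short_admission", "long_admission")
  } else {
    cutoff <- cutoff %||% 14
    in_first <- rep(NA, n)
    pos <- y == 1L
    in_first[pos] <- fid[pos] <= cutoff
    n_early <- sum(in_first[pos], na.rm = TRUE)
    n_late <- sum(pos) - n_early
    p_early <- if (n_early + n_late > 0) n_early / (n_early + n_late) else 0.5
    neg <- which(!pos)
    alloc <- with_seed(seed, runif(length(neg)) < p_early)
    in_first[neg] <- alloc
    group_names <- c("early_violence", "late_violence")
  }

  eval_group <- function(keep) {
    if (!any(keep)) return(NULL)
    if (length(unique(y[keep])) < 2L) return(list(n = sum(keep), degenerate = TRUE))
    c(delong_se_ci(s[keep], y[keep]), n = sum(keep), n_pos = sum(y[keep]))
  }
  g1 <- eval_group(in_first)
  g2 <- eval_group(!in_first)

  comparison <- NULL
  if (!is.null(g1) && !is.null(g2) && is.null(g1$degenerate) && is.null(g2$degenerate)) {
    comparison <- delong_compare(s[in_first], s[!in_first],
                                 labels_1 = y[in_first], labels_2 = y[!in_first],
                                 paired = FALSE)
  } else {
    warning("a subgroup is empty or single-class; comparison skipped")
  }

  structure(setNames(list(g1, g2, comparison, split, cutoff),
                     c(group_names, "comparison", "split", "cutoff")),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat("<subgroup_result>", x$split, sprintf("(cutoff %.1f d)\n", x$cutoff))
  for (nm in setdiff(names(x), c("comparison", "split", "cutoff"))) {
    g <- x[[nm]]
    if (is.null(g)) {
      cat(sprintf("  %-16s empty\n", nm))
    } else if (!is.null(g$degenerate)) {
      cat(sprintf("  %-16s n = %d, single outcome class\n", nm, g$n))
    } else {
      cat(sprintf("  %-16s n = %d (%d positive): AUC %.3f (95%% CI %.3f-%.3f)\n",
                  nm, g$n, g$n_pos, g$auc, g$ci_low, g$ci_high))
    }
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
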