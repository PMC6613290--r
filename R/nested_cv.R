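#' Hyperparameter grid for the radial-kernel classifier
#'
#' @param costs Candidate margin penalties `C`.
#' @param kernel_widths Candidate kernel scales `gamma`; `NA` stands for the
#'   heuristic `1 / dimension` on standardised features.
#' @return A data frame with columns `cost` and `kernel_width`.
#' @export
default_grid <- function(costs = c(0.1, 1, 10, 100),
                         kernel_widths = c(NA, 0.001, 0.01, 0.1)) {
  expand.grid(cost = costs, kernel_width = kernel_widths,
              KEEP.OUT.ATTRS = FALSE)
}

# fit + score one train/test split for one grid point; NULL when the training
# labels are single-class
fit_score <- function(x_train, y_train, x_test, cost, kernel_width, seed) {
  if (length(unique(y_train)) < 2L) return(NULL)
  cfg <- classifier_config(cost = cost,
                           kernel_width = if (is.na(kernel_width)) NULL else kernel_width,
                           seed = seed)
  clf <- fit_classifier(x_train, y_train, cfg)
  list(classifier = clf, scores = predict_scores(clf, x_test))
}

#' Patient-grouped nested cross-validation of the risk model
#'
#' For each of `k_outer` patient-grouped outer folds, an inner
#' `k_inner`-fold patient-grouped cross-validation on the outer-training set
#' selects the hyperparameter grid point with the best mean inner AUC; the
#' classifier is then refit on the full outer-training set and scored on the
#' held-out outer fold. Admissions used for learning are thus never used to
#' simultaneously estimate predictive validity. The headline AUC is the
#' unweighted mean of the outer-fold AUCs; the pooled AUC over the union of
#' out-of-fold predictions (each admission scored exactly once) is reported
#' alongside, and carries the DeLong standard error and confidence interval.
#' The operating point balancing false positives against false negatives is
#' selected on the pooled scores.
#'
#' @param cohort A `labeled_cohort` (needs `admission_id`, `patient_id`,
#'   `outcome`).
#' @param vectors Document-vector matrix; row names must be admission ids (or
#'   rows aligned with `cohort`).
#' @param grid Hyperparameter grid, see [default_grid()].
#' @param k_outer,k_inner Outer/inner fold counts (both patient-grouped).
#' @param seed Top-level seed; fold assignments derive child seeds from it.
#' @param fold_plan Optional precomputed outer [assign_grouped_folds()] plan.
#' @return A `cv_result`: pooled `predictions` (admission_id, patient_id,
#'   fold, label, score), `fold_aucs`, `auc` (fold mean), `auc_pooled`, `se`,
#'   `ci_low`/`ci_high` (DeLong, pooled), `threshold`, `confusion`, `metrics`
#'   ([pooled_metrics()]), and the per-fold selected hyperparameters.
#' @export
run_nested_cv <- function(cohort, vectors, grid = default_grid(),
                          k_outer = 5, k_inner = 5, seed = 1L,
                          fold_plan = NULL) {
  stopifnot(nrow(grid) >= 1)
  vectors <- align_vectors(vectors, cohort)
  y <- as.integer(cohort$outcome)
  seeds <- derive_seeds(seed, 2L + k_outer)
  if (is.null(fold_plan))
    fold_plan <- assign_grouped_folds(cohort, k = k_outer, seed = seeds[1])
  fold <- fold_plan$fold[match(cohort$admission_id, fold_plan$admission_id)]
  if (anyNA(fold)) stop("fold plan does not cover the cohort", call. = FALSE)

  predictions <- vector("list", k_outer)
  fold_aucs <- rep(NA_real_, k_outer)
  chosen <- vector("list", k_outer)

  for (f in sort(unique(fold))) {
    tr <- fold != f
    inner_cohort <- cohort[tr, , drop = FALSE]
    inner_plan <- assign_grouped_folds(inner_cohort, k = k_inner,
                                       seed = seeds[2L + f])
    inner_fold <- inner_plan$fold

    grid_auc <- rep(NA_real_, nrow(grid))
    for (g in seq_len(nrow(grid))) {
      aucs <- c()
      for (i in seq_len(k_inner)) {
        it <- inner_fold != i
        y_it <- y[tr][it]; y_iv <- y[tr][!it]
        if (length(unique(y_it)) < 2L || length(unique(y_iv)) < 2L) {
          warning(sprintf("inner fold %d of outer fold %d has a single class; grid evaluation skipped",
                          i, f))
          next
        }
        fs <- fit_score(vectors[tr, , drop = FALSE][it, , drop = FALSE], y_it,
                        vectors[tr, , drop = FALSE][!it, , drop = FALSE],
                        grid$cost[g], grid$kernel_width[g], seed)
        aucs <- c(aucs, auc(fs$scores, y_iv))
      }
      if (length(aucs)) grid_auc[g] <- mean(aucs)
    }
    if (all(is.na(grid_auc)))
      stop("all inner-fold grid evaluations were skipped (degenerate folds)",
           call. = FALSE)
    best <- which.max(grid_auc) # ties: first grid row
    chosen[[f]] <- data.frame(fold = f, cost = grid$cost[best],
                              kernel_width = grid$kernel_width[best],
                              inner_auc = grid_auc[best])

    fs <- fit_score(vectors[tr, , drop = FALSE], y[tr],
                    vectors[!tr, , drop = FALSE],
                    grid$cost[best], grid$kernel_width[best], seed)
    y_te <- y[!tr]
    if (length(unique(y_te)) >= 2L) fold_aucs[f] <- auc(fs$scores, y_te)
    predictions[[f]] <- tibble::tibble(
      admission_id = cohort$admission_id[!tr],
      patient_id = cohort$patient_id[!tr],
      fold = f, label = y_te, score = fs$scores
    )
  }

  pooled <- do.call(rbind, predictions)
  pooled <- pooled[match(cohort$admission_id, pooled$admission_id), ]
  d <- delong_se_ci(pooled$score, pooled$label)
  thr <- select_threshold(pooled$score, pooled$label)
  cc <- confusion_counts(pooled$score, pooled$label, thr)

  structure(list(
    predictions = pooled,
    fold_aucs = fold_aucs,
    auc = mean(fold_aucs, na.rm = TRUE),
    auc_pooled = d$auc, se = d$se, ci_low = d$ci_low, ci_high = d$ci_high,
    threshold = as.numeric(thr), confusion = cc,
    metrics = pooled_metrics(cc),
    hyperparameters = do.call(rbind, chosen),
    fold_plan = fold_plan, seed = seed
  ), class = "cv_result")
}

align_vectors <- function(vectors, cohort) {
  vectors <- as.matrix(vectors)
  if (!is.null(rownames(vectors))) {
    idx <- match(cohort$admission_id, rownames(vectors))
    if (anyNA(idx))
      stop("vectors are missing rows for some admissions", call. = FALSE)
    vectors <- vectors[idx, , drop = FALSE]
  } else if (nrow(vectors) != nrow(cohort)) {
    stop("unnamed vector matrix must have one row per admission", call. = FALSE)
  }
  vectors
}

#' ROC curve coordinates
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered from the most to
#'   the least conservative threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, scores[ord][keep]),
    fpr = c(0, fp[keep] / max(sum(labels == 0L), 1)),
    tpr = c(0, tp[keep] / max(sum(labels == 1L), 1))
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> patient-grouped nested cross-validation\n")
  cat(sprintf("  AUC (mean of %d fold AUCs): %.3f\n", length(x$fold_aucs), x$auc))
  cat(sprintf("  AUC (pooled) %.3f (95%% CI %.3f-%.3f) [SE %.3f]\n",
              x$auc_pooled, x$ci_low, x$ci_high, x$se))
  cat(sprintf("  threshold %.4f -> TN %d, FN %d, TP %d, FP %d\n",
              x$threshold, x$confusion[["tn"]], x$confusion[["fn"]],
              x$confusion[["tp"]], x$confusion[["fp"]]))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, relative risk %s\n",
              x$metrics$sensitivity, x$metrics$specificity,
              ifelse(is.na(x$metrics$relative_risk), "undefined",
                     sprintf("%.3f", x$metrics$relative_risk))))
  invisible(x)
}
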