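# Cross-site model transfer: freeze everything learned at one site (the
# embedding space, the feature standardisation, the classifier, the operating
# point) and evaluate it, untouched, on the other site's admissions.

#' Freeze a complete site model for transfer
#'
#' Trains the paragraph-vector embedding on the site's documents (optionally
#' a larger note corpus), selects classifier hyperparameters by
#' patient-grouped cross-validated grid search, fits the classifier on the
#' full site, and fixes the FP/FN-balancing threshold on the out-of-fold
#' scores of the selected configuration. The result contains every learned
#' component, so an external site can be scored without re-estimating
#' anything.
#'
#' @param cohort A `labeled_cohort` for the training site.
#' @param embed_config An [embedding_config()].
#' @param grid Hyperparameter grid ([default_grid()]).
#' @param k Folds for the hyperparameter search.
#' @param seed Top-level seed.
#' @param training_corpus Optional larger unsupervised corpus (list of token
#'   vectors or character texts, e.g. all of the site's notes) for embedding
#'   training; defaults to the cohort documents.
#' @return A `site_model`: `embedding`, `classifier`, `threshold`,
#'   `hyperparameters`, out-of-fold `oof` predictions, and the seed.
#' @export
freeze_site_model <- function(cohort, embed_config = embedding_config(),
                              grid = default_grid(), k = 5, seed = 1L,
                              training_corpus = NULL) {
  seeds <- derive_seeds(seed, 3L)
  corpus <- training_corpus %||% setNames(cohort$document, cohort$admission_id)
  emb_cfg <- embed_config
  emb_cfg$seed <- seeds[1]
  model <- train_embedding(corpus, emb_cfg)
  vectors <- embed_documents(model, cohort$document, ids = cohort$admission_id)

  y <- as.integer(cohort$outcome)
  plan <- assign_grouped_folds(cohort, k = k, seed = seeds[2])
  fold <- plan$fold

  grid_auc <- rep(NA_real_, nrow(grid))
  oof_best <- NULL
  for (g in seq_len(nrow(grid))) {
    scores <- rep(NA_real_, nrow(cohort))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      fs <- fit_score(vectors[tr, , drop = FALSE], y[tr],
                      vectors[!tr, , drop = FALSE],
                      grid$cost[g], grid$kernel_width[g], seed)
      scores[!tr] <- fs$scores
    }
    ok <- !is.na(scores)
    if (any(ok) && length(unique(y[ok])) >= 2L) {
      grid_auc[g] <- auc(scores[ok], y[ok])
      if (g == which.max(replace(grid_auc, is.na(grid_auc), -Inf)))
        oof_best <- scores
    }
  }
  if (all(is.na(grid_auc)))
    stop("hyperparameter search failed: no grid point could be evaluated", call. = FALSE)
  best <- which.max(grid_auc)

  cfg <- classifier_config(
    cost = grid$cost[best],
    kernel_width = if (is.na(grid$kernel_width[best])) NULL else grid$kernel_width[best],
    seed = seeds[3]
  )
  classifier <- fit_classifier(vectors, y, cfg)
  ok <- !is.na(oof_best)
  threshold <- select_threshold(oof_best[ok], y[ok])

  structure(list(
    embedding = model, classifier = classifier,
    threshold = as.numeric(threshold),
    hyperparameters = grid[best, , drop = FALSE],
    oof = tibble::tibble(admission_id = cohort$admission_id[ok],
                         label = y[ok], score = oof_best[ok]),
    site = cohort$site[1], seed = seed
  ), class = "site_model")
}

#' Evaluate a frozen site model on another site
#'
#' Embeds the target site's predictor-window documents with the source
#' site's embedding model, scores them with the source site's frozen
#' classifier, and evaluates at the source site's operating point. When the
#' target site's internal cross-validation result is supplied, a paired
#' DeLong comparison of the internal versus the transferred scores on the
#' identical admissions is included.
#'
#' @param site_model A frozen [freeze_site_model()] bundle.
#' @param cohort The target site's `labeled_cohort`.
#' @param internal_result Optional `cv_result` of the target site's internal
#'   nested cross-validation (for the paired comparison).
#' @return A `transfer_result`: `predictions`, `auc`, `se`, `ci_low`,
#'   `ci_high`, `confusion`, `metrics`, and `comparison` (paired
#'   [delong_compare()] vs the internal result, or `NULL`).
#' @export
transfer_evaluate <- function(site_model, cohort, internal_result = NULL) {
  stopifnot(inherits(site_model, "site_model"))
  vectors <- embed_documents(site_model$embedding, cohort$document,
                             ids = cohort$admission_id)
  scores <- predict_scores(site_model$classifier, vectors)
  y <- as.integer(cohort$outcome)
  d <- delong_se_ci(scores, y)
  cc <- confusion_counts(scores, y, site_model$threshold)

  comparison <- NULL
  if (!is.null(internal_result)) {
    internal <- internal_result$predictions
    idx <- match(cohort$admission_id, internal$admission_id)
    if (anyNA(idx))
      stop("internal result does not cover the same admissions; paired comparison rejected",
           call. = FALSE)
    comparison <- delong_compare(internal$score[idx], scores,
                                 labels_1 = internal$label[idx], labels_2 = y,
                                 paired = TRUE)
  }

  structure(list(
    predictions = tibble::tibble(admission_id = cohort$admission_id,
                                 label = y, score = scores),
    auc = d$auc, se = d$se, ci_low = d$ci_low, ci_high = d$ci_high,
    threshold = site_model$threshold, confusion = cc,
    metrics = pooled_metrics(cc),
    comparison = comparison, trained_on = site_model$site
  ), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result> model trained in", x$trained_on %||% "?", "\n")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f) [SE %.3f]\n",
              x$auc, x$ci_low, x$ci_high, x$se))
  cat(sprintf("  at source threshold: TN %d, FN %d, TP %d, FP %d\n",
              x$confusion[["tn"]], x$confusion[["fn"]],
              x$confusion[["tp"]], x$confusion[["fp"]]))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
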