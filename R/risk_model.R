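#' Configuration for the radial-kernel risk classifier
#'
#' @param cost Margin-violation penalty `C` (> 0).
#' @param kernel_width Radial (Gaussian) kernel scale `gamma` (> 0); `NULL`
#'   defaults to `1 / dimension` at fit time.
#' @param seed Integer seed (recorded for provenance; the underlying
#'   optimisation is deterministic).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(cost = 1, kernel_width = NULL, seed = 1L) {
  stopifnot(cost > 0, is.null(kernel_width) || kernel_width > 0)
  structure(list(cost = cost, kernel_width = kernel_width,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit the radial-kernel maximum-margin classifier
#'
#' Fits a support vector machine with a Gaussian kernel on document vectors.
#' Features are z-scored with statistics computed from the training data only;
#' the same statistics are applied at prediction time (no leakage from test
#' folds). Scores are signed decision values, oriented so that larger scores
#' mean higher violence risk.
#'
#' @param vectors Numeric matrix (admissions x dimension) of document vectors.
#' @param labels Binary outcome vector (0/1), one per row.
#' @param config A [classifier_config()].
#' @return A `risk_classifier` holding the fitted machine, the
#'   standardisation statistics and the configuration.
#' @export
fit_classifier <- function(vectors, labels, config = classifier_config()) {
  vectors <- as.matrix(vectors)
  labels <- as.integer(labels)
  stopifnot(nrow(vectors) == length(labels), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; both outcomes are required to fit",
         call. = FALSE)

  center <- colMeans(vectors)
  scale_ <- apply(vectors, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  x <- sweep(sweep(vectors, 2, center), 2, scale_, "/")
  gamma <- config$kernel_width %||% (1 / ncol(x))

  y <- factor(labels, levels = c(0L, 1L))
  fit <- e1071::svm(x, y, kernel = "radial", cost = config$cost, gamma = gamma,
                    scale = FALSE, fitted = FALSE)

  # libsvm's decision value is signed w.r.t. its internally-first class;
  # record a flip so that higher score always means class 1
  dv_name <- colnames(attr(stats::predict(fit, x[1:2, , drop = FALSE],
                                          decision.values = TRUE),
                           "decision.values"))
  flip <- startsWith(dv_name, "0")

  structure(list(svm = fit, center = center, scale = scale_, flip = flip,
                 dimension = ncol(x), gamma = gamma, config = config),
            class = "risk_classifier")
}

#' Predict continuous risk scores
#'
#' @param classifier A `risk_classifier`.
#' @param vectors Numeric matrix with the training dimensionality.
#' @return Numeric vector of signed decision scores (higher = higher risk),
#'   one per row, in row order.
#' @export
predict_scores <- function(classifier, vectors) {
  stopifnot(inherits(classifier, "risk_classifier"))
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != classifier$dimension)
    stop(sprintf("vector dimension %d does not match training dimension %d",
                 ncol(vectors), classifier$dimension), call. = FALSE)
  x <- sweep(sweep(vectors, 2, classifier$center), 2, classifier$scale, "/")
  pred <- stats::predict(classifier$svm, x, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (classifier$flip) dv <- -dv
  stopifnot(all(is.finite(dv)))
  dv
}

#' Select the FP/FN-balancing operating point
#'
#' Chooses the dichotomising threshold on pooled out-of-fold scores that
#' balances false-positive and false-negative counts: among all cut points
#' (midpoints between adjacent distinct scores, plus the two outer
#' sentinels), the one minimising `|FP - FN|` is returned, with ties broken
#' toward the smaller FP. Predicted class is 1 iff `score >= threshold`.
#'
#' @param scores Numeric vector of continuous risk scores.
#' @param labels Binary outcome vector.
#' @return The selected threshold, with attributes `fp` and `fn` at that
#'   threshold.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("threshold selection requires both outcome classes", call. = FALSE)

  s <- sort(unique(scores))
  cuts <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  best <- NULL
  for (ct in cuts) {
    pred <- as.integer(scores >= ct)
    fp <- sum(pred == 1L & labels == 0L)
    fn <- sum(pred == 0L & labels == 1L)
    if (is.null(best) || abs(fp - fn) < best$gap ||
        (abs(fp - fn) == best$gap && fp < best$fp)) {
      best <- list(threshold = ct, gap = abs(fp - fn), fp = fp, fn = fn)
    }
  }
  structure(best$threshold, fp = best$fp, fn = best$fn)
}

#' Confusion counts at a threshold
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes.
#' @param threshold Operating point; predicted class is 1 iff
#'   `score >= threshold`.
#' @return Named integer vector `c(tn, fn, tp, fp)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  c(tn = sum(pred == 0L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L),
    tp = sum(pred == 1L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L))
}
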