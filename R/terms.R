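# Exploratory term analysis: the most frequent unigrams and bigrams as
# binary presence variables, chi-squared association with the outcome,
# Matthews correlation for direction, bootstrap stability selection as a
# within-data-set generalizability measure, and Holm-Bonferroni familywise
# error control.

#' Extract the most frequent terms (including bigrams) as binary variables
#'
#' Candidate vocabulary is the union of unigrams and adjacent-token bigrams
#' (joined with `_`); the top `k` candidates by document frequency are kept,
#' with ties broken lexicographically. Presence is binary: a term occurring
#' twice in a document still scores 1.
#'
#' @param documents Character vector of document texts (tokenized with the
#'   shared tokenizer) or a list of token vectors; names become row ids.
#' @param k Number of terms to keep (default 1000). If fewer candidates
#'   exist, all are returned with a warning.
#' @param include_bigrams Include adjacent-token bigrams as candidates.
#' @param frequency Ranking frequency: `"document"` (default; number of
#'   documents containing the term) or `"token"` (total occurrences).
#' @return A `term_matrix`: list with `terms` (ordered character vector) and
#'   `matrix` (binary documents x terms matrix).
#' @export
extract_terms <- function(documents, k = 1000, include_bigrams = TRUE,
                          frequency = c("document", "token")) {
  frequency <- match.arg(frequency)
  docs <- as_token_docs(documents)

  doc_terms <- lapply(docs, function(toks) {
    if (include_bigrams && length(toks) >= 2L) {
      n <- length(toks)
      c(toks, paste(toks[-n], toks[-1], sep = "_"))
    } else toks
  })

  counted <- if (frequency == "document") lapply(doc_terms, unique) else doc_terms
  freq <- table(unlist(counted, use.names = FALSE))
  if (length(freq) == 0L) stop("no terms found in the documents", call. = FALSE)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  terms <- names(freq)[ord]
  if (length(terms) < k) {
    warning(sprintf("only %d candidate terms available (k = %d requested)",
                    length(terms), k))
  } else {
    terms <- terms[seq_len(k)]
  }

  m <- matrix(0L, length(docs), length(terms),
              dimnames = list(names(docs), terms))
  for (i in seq_along(doc_terms)) {
    hit <- match(unique(doc_terms[[i]]), terms)
    m[i, hit[!is.na(hit)]] <- 1L
  }
  structure(list(terms = terms, matrix = m), class = "term_matrix")
}

# weighted 2x2 cells for every term column at once; w are row multiplicities
term_cells <- function(X, y, w = rep(1, length(y))) {
  wy <- w * (y == 1L)
  a <- as.vector(crossprod(X, wy))          # present & positive
  pres <- as.vector(crossprod(X, w))        # present
  n1 <- sum(wy); n0 <- sum(w) - n1
  b <- pres - a                             # present & negative
  list(a = a, b = b, c = n1 - a, d = n0 - b, n = n1 + n0)
}

chi2_from_cells <- function(cl) {
  num <- cl$n * (cl$a * cl$d - cl$b * cl$c)^2
  den <- (cl$a + cl$b) * (cl$c + cl$d) * (cl$a + cl$c) * (cl$b + cl$d)
  ifelse(den > 0, num / den, 0)
}

mcc_from_cells <- function(cl) {
  den <- sqrt(cl$a + cl$b) * sqrt(cl$c + cl$d) * sqrt(cl$a + cl$c) * sqrt(cl$b + cl$d)
  ifelse(den > 0, (cl$a * cl$d - cl$b * cl$c) / den, 0)
}

#' Chi-squared association of a binary term with the outcome
#'
#' Pearson chi-squared on the 2x2 contingency table, 1 degree of freedom,
#' without continuity correction (so that the identity
#' `chi2 = n * MCC^2` holds exactly; a corrected version is available via
#' `correct = TRUE`). A term present in all or in no documents (zero
#' marginal) yields statistic 0 and p = 1, flagged via the `degenerate`
#' attribute.
#'
#' @param term_column Binary presence vector.
#' @param outcome Binary outcome vector.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic` and `p_value` (upper chi-squared tail).
#' @export
chi2_association <- function(term_column, outcome, correct = FALSE) {
  x <- as.integer(term_column); y <- as.integer(outcome)
  stopifnot(length(x) == length(y), all(x %in% 0:1), all(y %in% 0:1))
  cl <- term_cells(matrix(x, ncol = 1), y)
  degenerate <- (cl$a + cl$b) == 0 || (cl$c + cl$d) == 0 ||
    (cl$a + cl$c) == 0 || (cl$b + cl$d) == 0
  stat <- if (correct && !degenerate) {
    num <- cl$n * pmax(0, abs(cl$a * cl$d - cl$b * cl$c) - cl$n / 2)^2
    den <- (cl$a + cl$b) * (cl$c + cl$d) * (cl$a + cl$c) * (cl$b + cl$d)
    num / den
  } else {
    chi2_from_cells(cl)
  }
  structure(list(statistic = as.numeric(stat),
                 p_value = if (degenerate) 1 else pchisq(stat, 1, lower.tail = FALSE)),
            degenerate = degenerate)
}

#' Matthews correlation coefficient of a binary term with the outcome
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` on the 2x2 table; the sign gives
#' the direction of the association (positive: the term accompanies violent
#' outcomes). The confidence interval is a nonparametric bootstrap over
#' admissions (percentile method).
#'
#' @param term_column Binary presence vector.
#' @param outcome Binary outcome vector.
#' @param B Bootstrap replicates for the CI (0 to skip).
#' @param level Confidence level.
#' @param seed Bootstrap seed.
#' @return List with `mcc` and (when `B > 0`) `ci_low`, `ci_high`.
#' @export
mcc <- function(term_column, outcome, B = 2000, level = 0.95, seed = 1L) {
  x <- as.integer(term_column); y <- as.integer(outcome)
  stopifnot(length(x) == length(y), all(x %in% 0:1), all(y %in% 0:1))
  point <- mcc_from_cells(term_cells(matrix(x, ncol = 1), y))
  out <- list(mcc = as.numeric(point))
  if (B > 0) {
    n <- length(x)
    reps <- with_seed(seed, {
      W <- stats::rmultinom(B, n, rep(1 / n, n))
      vapply(seq_len(B), function(b) {
        mcc_from_cells(term_cells(matrix(x, ncol = 1), y, W[, b]))
      }, numeric(1))
    })
    qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    out$ci_low <- qs[1]; out$ci_high <- qs[2]
  }
  out
}

#' Bootstrap stability selection of terms
#'
#' In each of `B` resamples of admissions with replacement, all chi-squared
#' scores are recomputed and the top `ceiling(top_fraction * k)` terms are
#' marked (chi-squared ties broken by lexicographic term order). A term's
#' stability ratio is the fraction of resamples in which it was marked — the
#' within-data-set generalizability of the term as a predictor. Resamples
#' containing a single outcome class are redrawn (and counted in the
#' `redraws` attribute).
#'
#' @param term_matrix A `term_matrix` from [extract_terms()] (or a binary
#'   matrix with column names).
#' @param outcome Binary outcome vector, one per document row.
#' @param B Number of bootstrap resamples (default 1000).
#' @param top_fraction Fraction of terms marked per resample (default 0.10).
#' @param seed Integer seed.
#' @param resample Draw bootstrap resamples (default). With `resample =
#'   FALSE` the full sample is used every time, and the result reduces to a
#'   deterministic top-decile indicator (ratios 0 or 1).
#' @return Named numeric vector of stability ratios in \[0, 1\], one per term,
#'   in term order.
#' @export
stability_selection <- function(term_matrix, outcome, B = 1000,
                                top_fraction = 0.10, seed = 1L,
                                resample = TRUE) {
  X <- if (inherits(term_matrix, "term_matrix")) term_matrix$matrix else as.matrix(term_matrix)
  y <- as.integer(outcome)
  stopifnot(nrow(X) == length(y), B >= 1, ncol(X) >= 10)
  k <- ncol(X)
  n <- nrow(X)
  top_m <- ceiling(top_fraction * k)
  terms <- colnames(X)
  lex <- order(terms, method = "radix") # tie-break rank: lexicographic
  lex_rank <- match(seq_len(k), lex)

  inclusions <- integer(k)
  redraws <- 0L
  with_seed(seed, {
    storage.mode(X) <- "double"
    for (b in seq_len(B)) {
      if (resample) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) > 1L) break
          redraws <- redraws + 1L
          message("stability_selection: single-class resample redrawn")
        }
        w <- tabulate(idx, nbins = n)
      } else {
        w <- rep(1L, n)
      }
      chi <- chi2_from_cells(term_cells(X, y, w))
      top <- order(-chi, lex_rank)[seq_len(top_m)]
      inclusions[top] <- inclusions[top] + 1L
    }
  })
  structure(setNames(inclusions / B, terms), redraws = redraws,
            top_m = top_m, B = B)
}

#' Holm-Bonferroni familywise error control
#'
#' Step-down procedure: p-values are sorted ascending and `p_(i)` is compared
#' against `alpha / (m - i + 1)`, rejecting until the first failure.
#' Adjusted p-values come from [stats::p.adjust()] (method `"holm"`);
#' rejections are `adjusted <= alpha`, which is equivalent to the step-down
#' rule. Holm rejections always contain the plain Bonferroni rejections.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param alpha Familywise error rate (default 0.01).
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @export
holm_bonferroni <- function(p_values, alpha = 0.01) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adjusted <- p.adjust(p_values, method = "holm")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Full exploratory term screen
#'
#' Runs [extract_terms()], per-term chi-squared tests with Holm-Bonferroni
#' correction, Matthews correlation coefficients with bootstrap CIs, and
#' [stability_selection()], returning a ranked report (by stability ratio,
#' then chi-squared).
#'
#' @param cohort A `labeled_cohort` (or anything with `document` and
#'   `outcome`).
#' @param k Number of terms.
#' @param B Stability-selection resamples.
#' @param mcc_B Bootstrap replicates for the MCC confidence intervals.
#' @param top_fraction Stability-selection top fraction.
#' @param alpha Familywise error rate.
#' @param seed Integer seed.
#' @return A `term_screen` tibble: `rank`, `term`, `stability_ratio`, `mcc`,
#'   `mcc_ci_low`, `mcc_ci_high`, `chi2`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
term_screen <- function(cohort, k = 1000, B = 1000, mcc_B = 2000,
                        top_fraction = 0.10, alpha = 0.01, seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  docs <- setNames(cohort$document, cohort$admission_id)
  tm <- extract_terms(docs, k = k)
  y <- as.integer(cohort$outcome)
  X <- tm$matrix
  storage.mode(X) <- "double"

  cl <- term_cells(X, y)
  chi <- chi2_from_cells(cl)
  p_raw <- pchisq(chi, 1, lower.tail = FALSE)
  degenerate <- (cl$a + cl$b) == 0 | (cl$c + cl$d) == 0 |
    (cl$a + cl$c) == 0 | (cl$b + cl$d) == 0
  p_raw[degenerate] <- 1
  hb <- holm_bonferroni(p_raw, alpha = alpha)
  mcc_pt <- mcc_from_cells(cl)

  # batched bootstrap for all MCC CIs at once
  n <- nrow(X)
  ci <- with_seed(seeds[1], {
    W <- stats::rmultinom(mcc_B, n, rep(1 / n, n))
    A <- crossprod(X, W * (y == 1L))
    P <- crossprod(X, W)
    n1 <- colSums(W * (y == 1L)); n0 <- n - n1
    Bm <- P - A
    Cm <- matrix(n1, nrow(A), ncol(A), byrow = TRUE) - A
    Dm <- matrix(n0, nrow(A), ncol(A), byrow = TRUE) - Bm
    den <- sqrt(A + Bm) * sqrt(Cm + Dm) * sqrt(A + Cm) * sqrt(Bm + Dm)
    M <- ifelse(den > 0, (A * Dm - Bm * Cm) / den, 0)
    t(apply(M, 1, quantile, probs = c(0.025, 0.975), names = FALSE))
  })

  stab <- stability_selection(tm, y, B = B, top_fraction = top_fraction,
                              seed = seeds[2])

  out <- tibble::tibble(
    term = tm$terms,
    stability_ratio = as.numeric(stab),
    mcc = mcc_pt, mcc_ci_low = ci[, 1], mcc_ci_high = ci[, 2],
    chi2 = chi, p_raw = p_raw, p_adjusted = hb$adjusted,
    significant = hb$reject
  )
  out <- out[order(-out$stability_ratio, -out$chi2, out$term), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  class(out) <- c("term_screen", class(out))
  out
}
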