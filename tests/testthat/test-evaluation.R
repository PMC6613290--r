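# Evaluation machinery: grouped folds, AUC against exhaustive pair counting,
# DeLong inference against bootstrap and an independent implementation,
# pooled metrics against published confusion counts, and the leakage the
# patient grouping prevents.

with_seed <- getFromNamespace("with_seed", "noterisk")

brute_auc <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  s <- 0
  for (i in seq_along(x)) for (j in seq_along(y))
    s <- s + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
  s / (length(x) * length(y))
}

test_that("grouped folds partition admissions and never split a patient", {
  co <- fx_strong_cohort()
  plan <- assign_grouped_folds(co, k = 5, seed = 2)
  expect_setequal(plan$admission_id, co$admission_id)
  expect_false(any(duplicated(plan$admission_id)))
  per_patient <- tapply(plan$fold, plan$patient_id, function(f) length(unique(f)))
  expect_true(all(per_patient == 1))
  # multi-admission patients exist in the fixture, so the check has teeth
  expect_gt(sum(table(co$patient_id) >= 3), 0)
})

test_that("singleton patients and divisible n give exactly equal folds", {
  n <- 40
  lab <- data.frame(admission_id = sprintf("a%02d", 1:n),
                    patient_id = sprintf("p%02d", 1:n))
  plan <- assign_grouped_folds(lab, k = 5, seed = 1)
  expect_equal(as.integer(table(plan$fold)), rep(8L, 5))
  expect_error(assign_grouped_folds(lab[1:3, ], k = 5), "patient-grouped folds")
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  expect_equal(auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "class")
  for (s in 1:10) {
    d <- with_seed(s, list(x = sample(seq(0, 1, 0.05), 20, replace = TRUE),
                           y = rbinom(20, 1, 0.4)))
    if (length(unique(d$y)) < 2) next
    expect_equal(auc(d$x, d$y), brute_auc(d$x, d$y))
  }
})

test_that("DeLong SE/CI is sane, matches pROC, and tracks the bootstrap", {
  # perfect separation: all placement values 1, SE exactly 0
  d0 <- delong_se_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(d0$se, 0)
  expect_equal(d0$auc, 1)

  d <- with_seed(42, list(x = rnorm(50) + rep(c(0, 0.8), c(30, 20)),
                          y = rep(c(0L, 1L), c(30, 20))))
  r <- delong_se_ci(d$x, d$y)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  # independent implementation
  pr <- pROC::roc(d$y, d$x, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-8)

  # 10,000-replicate bootstrap of the AUC
  boot <- with_seed(7, vapply(1:10000, function(b) {
    i <- sample.int(50, replace = TRUE)
    if (length(unique(d$y[i])) < 2) return(NA_real_)
    auc(d$x[i], d$y[i])
  }, numeric(1)))
  expect_lt(abs(r$se / sd(boot, na.rm = TRUE) - 1), 0.15)

  expect_error(delong_se_ci(c(1, 2, 3), c(0, 1, 1)), "at least 2")
})

test_that("paired DeLong comparison respects covariance and degeneracy", {
  d <- with_seed(3, {
    base <- rnorm(80)
    y <- rbinom(80, 1, 0.4)
    list(s1 = base + y * 0.8 + rnorm(80, sd = 0.3),
         s2 = base + y * 0.8 + rnorm(80, sd = 0.3), y = y)
  })
  # self-comparison: zero difference, zero variance, p = 1
  self <- delong_compare(d$s1, d$s1, d$y, paired = TRUE)
  expect_equal(self$auc_diff, 0)
  expect_equal(self$se, 0)
  expect_equal(self$p_value, 1)

  # positively correlated scores: paired variance below sum of marginals
  cmp <- delong_compare(d$s1, d$s2, d$y, paired = TRUE)
  v1 <- delong_se_ci(d$s1, d$y)$se^2
  v2 <- delong_se_ci(d$s2, d$y)$se^2
  expect_lt(cmp$se^2, v1 + v2)

  # agreement with pROC's paired DeLong test
  pr <- pROC::roc.test(pROC::roc(d$y, d$s1, quiet = TRUE, direction = "<"),
                       pROC::roc(d$y, d$s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, pr$p.value, tolerance = 1e-8)

  # unpaired: identical variance estimate (pROC refers the same statistic to
  # a t distribution with Welch df; we use the z reference, so p-values agree
  # only approximately)
  d2 <- with_seed(4, list(x = rnorm(60) + rep(c(0, 0.5), c(40, 20)),
                          y = rep(c(0L, 1L), c(40, 20))))
  un <- delong_compare(d$s1, d2$x, d$y, d2$y, paired = FALSE)
  pru <- pROC::roc.test(pROC::roc(d$y, d$s1, quiet = TRUE, direction = "<"),
                        pROC::roc(d2$y, d2$x, quiet = TRUE, direction = "<"),
                        method = "delong", paired = FALSE)
  expect_equal(un$auc_diff / un$se, unname(pru$statistic), tolerance = 1e-8)
  expect_equal(un$p_value, pru$p.value, tolerance = 0.1)

  expect_error(delong_compare(d$s1, d$s2, d$y, rev(d$y), paired = TRUE),
               "identical")
})

test_that("pooled metrics reproduce published-style confusion counts", {
  m <- pooled_metrics(tn = 2711, fn = 193, tp = 97, fp = 188)
  expect_equal(round(m$sensitivity, 3), 0.334)
  expect_equal(round(m$specificity, 3), 0.935)
  expect_equal(round(m$relative_risk, 3), 5.121)
  # identity: sensitivity * (TP + FN) = TP
  expect_equal(m$sensitivity * (m$tp + m$fn), m$tp)

  # degenerate perfect prediction: relative risk undefined, not 0
  d <- pooled_metrics(tn = 50, fn = 0, tp = 50, fp = 0)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_true(is.na(d$relative_risk))
})

test_that("nested CV covers each admission exactly once and balances FP/FN", {
  cv <- fx_cv()
  co <- fx_strong_cohort()
  expect_setequal(cv$predictions$admission_id, co$admission_id)
  expect_false(any(duplicated(cv$predictions$admission_id)))
  expect_equal(sum(cv$confusion), nrow(co))
  expect_length(cv$fold_aucs, 5)

  # selected threshold achieves the minimal |FP - FN| (brute force)
  gaps <- vapply(c(-Inf, sort(unique(cv$predictions$score)), Inf), function(ct) {
    cc <- confusion_counts(cv$predictions$score, cv$predictions$label, ct)
    abs(cc[["fp"]] - cc[["fn"]])
  }, numeric(1))
  expect_equal(abs(cv$confusion[["fp"]] - cv$confusion[["fn"]]), min(gaps))

  # strong planted signal is recovered
  expect_gt(cv$auc, 0.85)
})

test_that("subgroup analysis partitions the evaluated admissions", {
  cv <- fx_cv()
  co <- fx_strong_cohort()
  sg <- subgroup_auc(cv, co, split = "short_long_admission")
  expect_equal(sg$short_admission$n + sg$long_admission$n, nrow(co))
  expect_false(sg$comparison$paired)

  sg2 <- subgroup_auc(cv, co, split = "early_late_violence", seed = 3)
  expect_equal(sg2$early_violence$n + sg2$late_violence$n, nrow(co))

  # degenerate split: everything in one subgroup, comparison skipped
  expect_warning(sg3 <- subgroup_auc(cv, co, split = "short_long_admission",
                                     cutoff = max(co$length_of_stay) + 1),
                 "skipped")
  expect_null(sg3$comparison)
})

test_that("patient grouping removes the leakage that ungrouped CV enjoys", {
  # same-patient admissions share near-identical feature vectors; labels are
  # patient-level, so ungrouped CV can recognise the patient and cheat
  leak <- function(seed) {
    with_seed(seed, {
      n_pat <- 60
      base <- matrix(rnorm(n_pat * 10), n_pat)
      y_pat <- rbinom(n_pat, 1, 0.5)
      idx <- rep(seq_len(n_pat), each = 2)
      x <- base[idx, ] + matrix(rnorm(2 * n_pat * 10, sd = 0.05), 2 * n_pat)
      rownames(x) <- sprintf("a%03d", seq_len(2 * n_pat))
      co <- tibble::tibble(admission_id = rownames(x),
                           patient_id = sprintf("p%03d", idx),
                           outcome = y_pat[idx])
      grid <- data.frame(cost = 1, kernel_width = NA)
      grouped <- run_nested_cv(co, x, grid = grid, seed = seed)$auc_pooled
      co_ungrouped <- co
      co_ungrouped$patient_id <- co_ungrouped$admission_id
      ungrouped <- run_nested_cv(co_ungrouped, x, grid = grid, seed = seed)$auc_pooled
      c(grouped = grouped, ungrouped = ungrouped)
    })
  }
  r <- vapply(1:3, leak, c(grouped = 0, ungrouped = 0))
  expect_lt(mean(r["grouped", ]), mean(r["ungrouped", ]))
  expect_gt(mean(r["ungrouped", ]), 0.8)   # the cheat is real
  expect_lt(mean(r["grouped", ]), 0.65)    # grouping removes it
})
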