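# Exploratory term analysis: extraction and binarization, chi-squared and
# MCC closed forms with their algebraic identity, bootstrap stability
# selection against an independently coded loop, and Holm-Bonferroni.

with_seed <- getFromNamespace("with_seed", "noterisk")

rand_table <- function(seed) {
  with_seed(seed, {
    n <- 120
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    list(x = x, y = y)
  })
}

test_that("term extraction follows adjacency, binarization and tie-breaks", {
  tm <- extract_terms(c(d1 = "patient was aggressive"), k = 5)
  expect_true(all(c("patient_was", "was_aggressive") %in% tm$terms))

  # a term present twice still scores 1
  tm2 <- extract_terms(c(d1 = "calm calm calm", d2 = "agitated"), k = 3)
  expect_equal(max(tm2$matrix), 1L)

  # 3-document corpus: hand-enumerated document frequencies, lexicographic ties
  docs <- c(d1 = "a b", d2 = "a c", d3 = "a b")
  tm3 <- extract_terms(docs, k = 4)
  # df: a=3, b=2, a_b=2, c=1, a_c=1 -> top 4 = a, a_b, b (tie a_b < b), c|a_c (tie -> a_c)
  expect_identical(tm3$terms, c("a", "a_b", "b", "a_c"))
  expect_identical(unname(tm3$matrix[, "a"]), c(1L, 1L, 1L))

  expect_warning(extract_terms(c(d1 = "x y"), k = 10), "candidate terms")
})

test_that("chi-squared matches the closed form and chisq.test", {
  # perfect independence
  ind <- chi2_association(rep(c(1, 1, 0, 0), 10), rep(c(1, 0, 1, 0), 10))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)

  # (a,b,c,d) = (30,70,10,90): N(ad-bc)^2 / margins = 12.5
  x <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  r <- chi2_association(x, y)
  expect_equal(r$statistic, 12.5)

  # symmetric under simultaneous swap of both labels
  r_swap <- chi2_association(1 - x, 1 - y)
  expect_equal(r_swap$statistic, r$statistic)

  # degenerate marginal: statistic 0, p 1, flagged
  deg <- chi2_association(rep(1, 20), rbinom(20, 1, 0.5))
  expect_equal(deg$statistic, 0)
  expect_true(attr(deg, "degenerate"))

  # independent implementation on random tables
  for (s in 1:8) {
    d <- rand_table(s)
    if (length(unique(d$x)) < 2 || length(unique(d$y)) < 2) next
    ours <- chi2_association(d$x, d$y)
    ref <- suppressWarnings(chisq.test(table(d$x, d$y), correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
  }
})

test_that("MCC matches the closed form, with chi2 = n * MCC^2", {
  n <- 15
  expect_equal(mcc(rep(c(1, 0), c(n, n)), rep(c(1, 0), c(n, n)), B = 0)$mcc, 1)
  expect_equal(mcc(rep(c(1, 0), c(n, n)), rep(c(0, 1), c(n, n)), B = 0)$mcc, -1)

  x <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  expect_equal(mcc(x, y, B = 0)$mcc, 0.25)  # denominator sqrt(64e6) = 8000

  m <- mcc(x, y, B = 500, seed = 3)
  expect_true(m$ci_low <= m$mcc && m$mcc <= m$ci_high)

  # algebraic identity on random tables
  for (s in 1:8) {
    d <- rand_table(100 + s)
    chi <- chi2_association(d$x, d$y)$statistic
    mc <- mcc(d$x, d$y, B = 0)$mcc
    expect_equal(chi, length(d$x) * mc^2)
  }
})

test_that("stability selection matches an independently coded loop", {
  d <- with_seed(11, {
    n <- 60; k <- 20
    X <- matrix(rbinom(n * k, 1, 0.4), n, k,
                dimnames = list(NULL, sprintf("term%02d", 1:k)))
    y <- rbinom(n, 1, 0.3)
    list(X = X, y = y)
  })
  B <- 200; seed <- 77
  ours <- stability_selection(d$X, d$y, B = B, top_fraction = 0.10, seed = seed)

  # duplicate implementation: same RNG stream, independent statistics code
  chi2_one <- function(x, y, w) {
    a <- sum(w * x * y); b <- sum(w * x * (1 - y))
    cc <- sum(w * (1 - x) * y); dd <- sum(w * (1 - x) * (1 - y))
    den <- (a + b) * (cc + dd) * (a + cc) * (b + dd)
    if (den == 0) 0 else sum(w) * (a * dd - b * cc)^2 / den
  }
  top_m <- ceiling(0.10 * ncol(d$X))
  lex <- order(colnames(d$X))
  lex_rank <- match(seq_len(ncol(d$X)), lex)
  counts <- integer(ncol(d$X))
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(nrow(d$X), nrow(d$X), replace = TRUE)
        if (length(unique(d$y[idx])) > 1) break
      }
      w <- tabulate(idx, nbins = nrow(d$X))
      chi <- vapply(seq_len(ncol(d$X)), function(j) chi2_one(d$X[, j], d$y, w),
                    numeric(1))
      top <- order(-chi, lex_rank)[seq_len(top_m)]
      counts[top] <- counts[top] + 1L
    }
  })
  expect_equal(unname(as.numeric(ours)), counts / B)

  # conservation: inclusions per resample sum to ceil(0.10 k)
  expect_equal(sum(ours) * B, top_m * B)
  expect_true(all(ours >= 0 & ours <= 1))
})

test_that("a dominant term is always selected; no-resample mode is deterministic", {
  d <- with_seed(5, {
    n <- 80; k <- 15
    y <- rbinom(n, 1, 0.4)
    X <- cbind(dominant = y, matrix(rbinom(n * (k - 1), 1, 0.5), n, k - 1))
    colnames(X) <- c("dominant", sprintf("noise%02d", 1:(k - 1)))
    list(X = X, y = y)
  })
  r <- stability_selection(d$X, d$y, B = 100, top_fraction = 0.10, seed = 1)
  expect_equal(unname(r["dominant"]), 1.00)

  flat <- stability_selection(d$X, d$y, B = 3, top_fraction = 0.2, seed = 1,
                              resample = FALSE)
  expect_true(all(flat %in% c(0, 1)))
  expect_equal(sum(flat), ceiling(0.2 * ncol(d$X)))
})

test_that("Holm-Bonferroni follows the step-down rule and dominates Bonferroni", {
  expect_length(holm_bonferroni(numeric(0))$reject, 0)
  expect_false(any(holm_bonferroni(rep(1, 10))$reject))

  # thresholds 0.05/3, 0.05/2, 0.05: all three rejected
  r <- holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_true(all(r$reject))

  step_down <- function(p, alpha) {
    o <- order(p); m <- length(p)
    rej <- logical(m)
    for (i in seq_len(m)) {
      if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
    }
    rej
  }
  for (s in 1:10) {
    p <- with_seed(s, runif(25)^3)
    ours <- holm_bonferroni(p, alpha = 0.05)
    expect_identical(ours$reject, step_down(p, 0.05))
    # step-down dominance over plain Bonferroni
    expect_true(all(ours$reject[p.adjust(p, "bonferroni") <= 0.05]))
    # adjusted p-values monotone in the sorted order
    expect_true(all(diff(ours$adjusted[order(p)]) >= 0))
  }
})

test_that("familywise error is controlled under a global null", {
  reps <- 300
  fwer <- mean(vapply(seq_len(reps), function(s) {
    d <- with_seed(9000 + s, {
      X <- matrix(rbinom(150 * 60, 1, 0.3), 150, 60)
      y <- rbinom(150, 1, 0.3)
      list(X = X, y = y)
    })
    cells <- getFromNamespace("term_cells", "noterisk")(d$X + 0, d$y)
    chi <- getFromNamespace("chi2_from_cells", "noterisk")(cells)
    p <- pchisq(chi, 1, lower.tail = FALSE)
    any(holm_bonferroni(p, alpha = 0.01)$reject)
  }, logical(1)))
  expect_lte(fwer, 0.01 + 3 * sqrt(0.01 * 0.99 / reps))
})

test_that("planted signal terms dominate the screen with correct signs", {
  scr <- fx_term_screen()
  planted <- names(strong_signal_terms())
  planted_tok <- gsub(" ", "_", planted)
  top <- scr$term[scr$rank <= 15]
  expect_gte(sum(planted_tok %in% top), 8)

  # risk terms positive, protective terms negative
  risk <- scr[scr$term %in% c("aggressive", "angry", "threatening"), ]
  expect_true(all(risk$mcc > 0))
  prot <- scr[scr$term %in% c("status_voluntary", "dejected"), ]
  expect_gt(nrow(prot), 0)
  expect_true(all(prot$mcc < 0))
  expect_true(all(scr$p_adjusted >= scr$p_raw))
})
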