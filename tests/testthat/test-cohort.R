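# Cohort rules: episode merging with the 2-week absence allowance, the
# predictor note window, the outcome window with category exclusions, and
# the post-24-hour word-count exclusion.

test_that("tokenizer lowercases, strips punctuation, and keeps numerals", {
  expect_identical(tokenize("Patient was very agitated; BP 120/80.")[[1]],
                   c("patient", "was", "very", "agitated", "bp", "120", "80"))
  expect_identical(tokenize("")[[1]], character(0))
  expect_identical(count_words(c("one two", "", "a b c")), c(2L, 0L, 3L))
})

test_that("episode merging follows the gap rule with an inclusive boundary", {
  # zero gap: one admission
  m <- merge_episodes(make_episodes(c(0, 10), c(10, 20)))
  expect_equal(nrow(m), 1)
  expect_equal(m$end, 20)

  # gap exactly 14 days merges; 15 days splits
  m14 <- merge_episodes(make_episodes(c(0, 24), c(10, 30)))
  expect_equal(nrow(m14), 1)
  m15 <- merge_episodes(make_episodes(c(0, 25), c(10, 30)))
  expect_equal(nrow(m15), 2)

  # chain with gaps 5 and 30 days: two admissions
  m2 <- merge_episodes(make_episodes(c(0, 15, 75), c(10, 45, 85)))
  expect_equal(nrow(m2), 2)
  expect_equal(m2$end[1], 45)

  # overlap warns and merges
  expect_warning(mo <- merge_episodes(make_episodes(c(0, 5), c(10, 20))),
                 "overlap")
  expect_equal(nrow(mo), 1)
  expect_equal(mo$end, 20)
})

test_that("merging is idempotent and keeps the episode map consistent", {
  ep <- rbind(make_episodes(c(0, 12, 60, 100), c(10, 40, 80, 120), "p1"),
              make_episodes(c(5, 50), c(30, 70), "p2"))
  m1 <- merge_episodes(ep)
  m2 <- merge_episodes(m1)
  expect_equal(m2[names(m2)], m1[names(m1)], ignore_attr = TRUE)
  emap <- attr(m1, "episode_map")
  expect_setequal(emap$episode_id, ep$admission_id)
  expect_true(all(emap$admission_id %in% m1$admission_id))
})

test_that("the predictor window is [start - 28 d, start + 1 d], closed", {
  adm <- list(start = 100)
  notes <- data.frame(
    timestamp = c(100 - 27, 100 - 29, 100 + 23 / 24, 100 + 25 / 24),
    text = c("in early", "out early", "in late", "out late"))
  doc <- select_note_window(adm, notes)
  expect_identical(doc, c("in", "early", "in", "late"))

  # concatenation conserves word counts
  notes3 <- data.frame(timestamp = c(95, 99, 100.5),
                       text = c("a b c", "d e", "f g h i"))
  expect_length(select_note_window(adm, notes3), 3 + 2 + 4)

  expect_warning(empty <- select_note_window(adm,
                                             data.frame(timestamp = 10, text = "x")),
                 "no notes")
  expect_length(empty, 0)
})

test_that("outcome labeling applies the window and category rules", {
  adm <- list(start = 0)
  inc <- function(day, cat) data.frame(timestamp = day, category = cat)
  expect_equal(label_outcome(adm, inc(10, "violence_physical")), 1L)
  expect_equal(label_outcome(adm, inc(0.5, "violence_physical")), 0L)  # hour 12
  expect_equal(label_outcome(adm, inc(35, "violence_physical")), 0L)
  expect_equal(label_outcome(adm, inc(10, "self_harm")), 0L)
  expect_equal(label_outcome(adm, inc(10, "substance_use")), 0L)
  expect_equal(label_outcome(adm, data.frame(timestamp = numeric(0),
                                             category = character(0))), 0L)

  # invariant to incident order and to out-of-window incidents
  many <- data.frame(timestamp = c(35, 10, 0.5), category =
                       c("vandalism", "violence_verbal", "violence_physical"))
  expect_equal(label_outcome(adm, many), 1L)
  expect_equal(label_outcome(adm, many[sample(3), , drop = FALSE]), 1L)
})

test_that("word-count exclusion is a closed threshold at 100", {
  lab <- data.frame(admission_id = c("a", "b", "c"),
                    word_count_post24h = c(99L, 100L, 250L))
  out <- suppressMessages(apply_exclusions(lab))
  expect_identical(out$admission_id, c("b", "c"))
  expect_equal(attr(out, "n_excluded"), 1)
  expect_identical(attr(out, "excluded_ids"), "a")

  all_ok <- suppressMessages(apply_exclusions(lab[lab$word_count_post24h >= 100, ]))
  expect_equal(nrow(all_ok), 2)
  expect_equal(attr(all_ok, "n_excluded"), 0)
})

test_that("planted under-documented admissions are excluded exactly", {
  p <- demo_profile("ud", n_patients = 80, n_underdocumented = 12)
  cs <- generate_site(p, 31)
  co <- suppressMessages(build_cohort(cs))
  expect_equal(attr(co, "n_excluded"), 12)
  # conservation: input = retained + excluded
  expect_equal(nrow(co) + attr(co, "n_excluded"), nrow(cs$admissions))
})

test_that("the built cohort reproduces the generator's ground truth", {
  cs <- fx_strong_corpus()
  co <- fx_strong_cohort()
  truth <- cs$truth$labels
  expect_identical(co$outcome,
                   truth$outcome[match(co$admission_id, truth$admission_id)])
  expect_true(all(co$word_count_post24h >= 100))
  expect_true(all(co$word_count > 0))
  expect_true(all(!is.na(co$first_incident_day[co$outcome == 1])))
  expect_true(all(is.na(co$first_incident_day[co$outcome == 0])))
  expect_true(all(co$first_incident_day > 1 & co$first_incident_day <= 28,
                  na.rm = TRUE))
})

test_that("unknown author roles are rejected", {
  cs <- generate_site(demo_profile("ar", n_patients = 20), 3)
  cs$notes$author_role[1] <- "social_worker"
  expect_error(build_cohort(cs), "psychiatrists or nurses")
})
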