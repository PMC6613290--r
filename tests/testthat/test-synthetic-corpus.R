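# The generator must be deterministic, respect its configured rates within
# sampling error, and reject invalid profiles with a message naming the
# violated invariant.

test_that("identical profile and seed give byte-identical corpora", {
  p <- demo_profile("det", n_patients = 60)
  a <- generate_site(p, 123)
  b <- generate_site(p, 123)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$notes, b$notes)
  expect_identical(a$incidents, b$incidents)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(a, d1); write_corpus(b, d2)
  for (f in c("admissions.csv", "notes.csv", "incidents.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  c3 <- generate_site(p, 124)
  expect_false(identical(a$notes, c3$notes))
})

test_that("invalid profiles are rejected with the violated invariant named", {
  expect_error(demo_profile("x", prevalence = 0), "prevalence")
  expect_error(demo_profile("x", prevalence = 1.2), "prevalence")
  expect_error(demo_profile("x", diagnosis_mixture = c(a = 0.5, b = 0.4)),
               "diagnosis_mixture")
  expect_error(demo_profile("x", frac_incidents_first4w = 0.2,
                            frac_incidents_first24h = 0.3),
               "frac_incidents_first24h")
  expect_error(demo_profile("x", site_shift = 1.5), "site_shift")
  expect_error(demo_profile("x", admission_rate = 0.5), "admission_rate")
})

test_that("rates and distributions converge to configured values at scale", {
  p <- demo_profile("big", n_patients = 3500, prevalence = 0.09)
  cs <- memo("big_corpus", function() generate_site(p, 2024))
  n <- nrow(cs$admissions)
  expect_gt(n, 4500)

  # outcome fraction within the exact binomial 99% interval around 0.09
  k <- sum(cs$truth$labels$outcome)
  expect_gte(k, qbinom(0.005, n, 0.09))
  expect_lte(k, qbinom(0.995, n, 0.09))

  # configured medians recovered within 10%
  los <- cs$admissions$end - cs$admissions$start
  expect_lt(abs(median(los) / exp(p$los_log_mean) - 1), 0.10)
  note_len <- count_words(cs$notes$text)
  expect_lt(abs(median(note_len) / exp(p$notelen_log_mean) - 1), 0.10)

  # incident timing fractions within binomial error (3 SE)
  adm_start <- cs$admissions$start[match(cs$incidents$admission_id,
                                         cs$admissions$admission_id)]
  d <- cs$incidents$timestamp - adm_start
  m <- nrow(cs$incidents)
  expect_lt(abs(mean(d < 1) - p$frac_incidents_first24h),
            3 * sqrt(p$frac_incidents_first24h * (1 - p$frac_incidents_first24h) / m))
  expect_lt(abs(mean(d <= 28) - p$frac_incidents_first4w),
            3 * sqrt(p$frac_incidents_first4w * (1 - p$frac_incidents_first4w) / m))

  # admissions-to-patients ratio tracks the readmission knob
  ratio <- n / length(unique(cs$admissions$patient_id))
  expect_lt(abs(ratio - p$admission_rate), 0.1)
})

test_that("every admission has exactly one truth record and valid incidents", {
  cs <- fx_strong_corpus()
  expect_setequal(cs$truth$labels$admission_id, cs$admissions$admission_id)
  expect_false(any(duplicated(cs$truth$labels$admission_id)))

  expect_true(all(cs$incidents$soas_r >= 1 & cs$incidents$soas_r <= 22))
  idx <- match(cs$incidents$admission_id, cs$admissions$admission_id)
  expect_true(all(cs$incidents$timestamp >= cs$admissions$start[idx]))
  expect_true(all(cs$incidents$timestamp <= cs$admissions$end[idx]))
  expect_true(all(cs$incidents$category %in%
                    c("violence_verbal", "violence_physical", "self_harm",
                      "substance_use", "sexual_intimidation", "vandalism")))
})

test_that("labels match the qualifying-incident definition in the raw stream", {
  cs <- fx_strong_corpus()
  idx <- match(cs$incidents$admission_id, cs$admissions$admission_id)
  d <- cs$incidents$timestamp - cs$admissions$start[idx]
  qual <- cs$incidents$category %in% c("violence_verbal", "violence_physical") &
    d > 1 & d <= 28
  derived <- as.integer(cs$admissions$admission_id %in%
                          unique(cs$incidents$admission_id[qual]))
  expect_identical(derived, cs$truth$labels$outcome)
})

test_that("site pair shares or splits the signal inventory per site_shift", {
  base <- strong_signal_terms()
  p0a <- demo_profile("a", n_patients = 40, signal_terms = base, site_shift = 0)
  p0b <- demo_profile("b", n_patients = 40, signal_terms = base, site_shift = 0)
  pair0 <- generate_pair(p0a, p0b, 9)
  expect_identical(names(pair0$a$truth$signal_terms),
                   names(pair0$b$truth$signal_terms))
  expect_length(pair0$shared_signal_terms, length(base))

  p1a <- demo_profile("a", n_patients = 40, signal_terms = base, site_shift = 1)
  p1b <- demo_profile("b", n_patients = 40, signal_terms = base, site_shift = 1)
  pair1 <- generate_pair(p1a, p1b, 9)
  expect_length(pair1$shared_signal_terms, 0)

  expect_error(generate_pair(p1a, p1a, 9), "distinct site_id")
})

test_that("corpora survive a write/read round trip", {
  cs <- generate_site(demo_profile("rt", n_patients = 30), 77)
  d <- withr::local_tempdir()
  write_corpus(cs, d)
  back <- read_corpus(d)
  expect_equal(back$admissions, cs$admissions)
  expect_equal(back$truth$labels, cs$truth$labels)
  expect_equal(back$seed, cs$seed)
})
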