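# Shared fixtures, built once per test run and memoized. All corpora are
# generated in code at desk scale: small patient counts, short notes, small
# embedding dimensions, so the full suite stays fast while exercising every
# stage on realistic structure.

.fx <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# ten strongly predictive terms plus two protective ones (one a bigram)
strong_signal_terms <- function(shift = 2.5) {
  c(setNames(rep(shift, 10),
             c("aggressive", "angry", "threatening", "agitated", "irritated",
               "shouting", "seclusion", "reacts", "door", "restraint")),
    "status voluntary" = -shift, dejected = -2)
}

fx_strong_corpus <- function() memo("strong_corpus", function() {
  generate_site(demo_profile("s1", n_patients = 300,
                             signal_terms = strong_signal_terms()),
                seed = 424242)
})

fx_strong_cohort <- function() memo("strong_cohort", function() {
  suppressMessages(build_cohort(fx_strong_corpus()))
})

fx_embedding <- function() memo("embedding", function() {
  co <- fx_strong_cohort()
  cfg <- embedding_config(dimension = 32, epochs = 8, min_term_count = 3,
                          seed = 99)
  train_embedding(setNames(co$document, co$admission_id), cfg)
})

fx_vectors <- function() memo("vectors", function() {
  co <- fx_strong_cohort()
  embed_documents(fx_embedding(), co$document, ids = co$admission_id)
})

fx_cv <- function() memo("cv", function() {
  suppressWarnings(run_nested_cv(fx_strong_cohort(), fx_vectors(), seed = 7))
})

fx_term_screen <- function() memo("term_screen", function() {
  term_screen(fx_strong_cohort(), k = 400, B = 200, mcc_B = 300, seed = 5)
})

# a tiny raw-episode table for cohort-rule unit tests
make_episodes <- function(starts, ends, patient = "p1") {
  data.frame(admission_id = sprintf("e%d", seq_along(starts)),
             patient_id = rep(patient, length.out = length(starts)),
             start = starts, end = ends, stringsAsFactors = FALSE)
}
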