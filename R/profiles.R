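#' Site profile for the synthetic EHR corpus generator
#'
#' A `site_profile` captures everything the generator needs to emulate one
#' psychiatric treatment centre: cohort size and readmission rate, outcome
#' prevalence, length-of-stay and note-length distributions, incident-timing
#' fractions, a diagnosis mixture, a background vocabulary, and a set of
#' planted signal terms whose per-note occurrence odds shift with the true
#' outcome. Two ready-made profiles, [site1_profile()] and [site2_profile()],
#' mirror the descriptive statistics of the two Dutch centres the pipeline
#' was designed around; [demo_profile()] is a desk-scale profile for fast
#' experimentation and testing.
#'
#' @param site_id Character site label (e.g. `"site1"`).
#' @param n_patients Number of unique patients.
#' @param admission_rate Mean admissions per patient (>= 1); the number of
#'   admissions per patient is `1 + Poisson(admission_rate - 1)`.
#' @param prevalence Probability of a violent outcome per admission, in (0,1).
#' @param los_log_mean,los_log_sd Lognormal length-of-stay parameters (days);
#'   the median stay is `exp(los_log_mean)`.
#' @param notelen_log_mean,notelen_log_sd Lognormal per-note length parameters
#'   (words); the median note has `exp(notelen_log_mean)` words.
#' @param frac_incidents_first4w,frac_incidents_first24h Fractions of all
#'   incidents falling in the first 4 weeks / first 24 hours of admission
#'   (the 24-hour window is a subset of the 4-week window).
#' @param diagnosis_mixture Named numeric vector of diagnosis probabilities
#'   summing to 1.
#' @param vocab_size Background vocabulary size.
#' @param signal_terms Named numeric vector: names are planted terms (a name
#'   containing a space plants a multi-token phrase, i.e. a bigram), values
#'   are log-odds shifts of the per-note occurrence probability when the
#'   admission's true outcome is positive. Negative values plant protective
#'   terms.
#' @param site_shift Per-term probability, in \[0,1\], that [generate_pair()]
#'   substitutes a signal term by a site-local synonym.
#' @param signal_base_rate Baseline per-note occurrence probability of each
#'   signal term (outcome-negative admissions).
#' @param notes_per_admission Mean number of notes in the predictor window
#'   (4 weeks before admission through the first 24 hours).
#' @param extra_incident_rate Poisson mean of additional incidents per
#'   outcome-positive admission beyond the one guaranteed qualifying incident.
#' @param neg_incident_rate Probability that an outcome-negative admission
#'   carries (non-qualifying) incidents.
#' @param n_underdocumented Number of admissions planted with fewer than 100
#'   words of post-24-hour documentation (these are the admissions the cohort
#'   stage must exclude).
#' @param min_post24_words Minimum post-24-hour word count guaranteed for all
#'   other admissions.
#' @param study_days Length of the enrolment window (days) over which first
#'   admissions start.
#'
#' @return An object of class `site_profile` (a validated list).
#' @export
site_profile <- function(site_id,
                         n_patients,
                         admission_rate = 1.44,
                         prevalence = 0.091,
                         los_log_mean = log(16), los_log_sd = 1.42,
                         notelen_log_mean = log(200), notelen_log_sd = 1.0,
                         frac_incidents_first4w = 0.684,
                         frac_incidents_first24h = 0.094,
                         diagnosis_mixture = c(psychotic = 0.40, mood = 0.30,
                                               personality = 0.15, other = 0.15),
                         vocab_size = 2000,
                         signal_terms = default_signal_terms(),
                         site_shift = 0,
                         signal_base_rate = 0.08,
                         notes_per_admission = 6,
                         extra_incident_rate = 2.3,
                         neg_incident_rate = 0.05,
                         n_underdocumented = 0,
                         min_post24_words = 110,
                         study_days = 1500) {
  p <- list(site_id = as.character(site_id), n_patients = as.integer(n_patients),
            admission_rate = admission_rate, prevalence = prevalence,
            los_log_mean = los_log_mean, los_log_sd = los_log_sd,
            notelen_log_mean = notelen_log_mean, notelen_log_sd = notelen_log_sd,
            frac_incidents_first4w = frac_incidents_first4w,
            frac_incidents_first24h = frac_incidents_first24h,
            diagnosis_mixture = diagnosis_mixture, vocab_size = as.integer(vocab_size),
            signal_terms = signal_terms, site_shift = site_shift,
            signal_base_rate = signal_base_rate,
            notes_per_admission = notes_per_admission,
            extra_incident_rate = extra_incident_rate,
            neg_incident_rate = neg_incident_rate,
            n_underdocumented = as.integer(n_underdocumented),
            min_post24_words = min_post24_words,
            study_days = study_days)
  validate_site_profile(p)
  structure(p, class = "site_profile")
}

validate_site_profile <- function(p) {
  fail <- function(msg) stop("invalid site profile: ", msg, call. = FALSE)
  if (!nzchar(p$site_id)) fail("site_id must be a nonempty label")
  if (is.na(p$n_patients) || p$n_patients < 1) fail("n_patients must be >= 1")
  if (p$admission_rate < 1) fail("admission_rate must be >= 1")
  if (!(p$prevalence > 0 && p$prevalence < 1)) fail("prevalence must lie in (0, 1)")
  if (p$los_log_sd <= 0 || p$notelen_log_sd <= 0) fail("lognormal sd parameters must be positive")
  for (f in c("frac_incidents_first4w", "frac_incidents_first24h", "site_shift",
              "signal_base_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) fail(paste(f, "must lie in [0, 1]"))
  }
  if (p$frac_incidents_first24h > p$frac_incidents_first4w)
    fail("frac_incidents_first24h must not exceed frac_incidents_first4w")
  dm <- p$diagnosis_mixture
  if (is.null(names(dm)) || any(!nzchar(names(dm)))) fail("diagnosis_mixture must be named")
  if (any(dm < 0)) fail("diagnosis_mixture probabilities must be nonnegative")
  if (abs(sum(dm) - 1) > 1e-9) fail("diagnosis_mixture must sum to 1")
  st <- p$signal_terms
  if (length(st) && (is.null(names(st)) || any(!nzchar(names(st)))))
    fail("signal_terms must be a named numeric vector of log-odds shifts")
  if (p$vocab_size < 10) fail("vocab_size must be at least 10")
  invisible(p)
}

#' @rdname site_profile
#' @export
default_signal_terms <- function() {
  c(aggressive = 1.2, angry = 1.1, threatening = 1.0, agitated = 1.0,
    irritated = 0.9, shouting = 0.9, seclusion = 0.8, "emergency medication" = 0.8,
    reacts = 0.7, door = 0.7, "status voluntary" = -0.9, dejected = -0.8)
}

#' @rdname site_profile
#' @export
site1_profile <- function() {
  site_profile(
    site_id = "site1", n_patients = 2209, admission_rate = 3189 / 2209,
    prevalence = 0.091,
    los_log_mean = log(16), los_log_sd = 1.42,
    notelen_log_mean = log(200), notelen_log_sd = 1.0,
    frac_incidents_first4w = 0.684, frac_incidents_first24h = 0.094,
    diagnosis_mixture = site1_diagnoses(),
    vocab_size = 5000, notes_per_admission = 7,
    extra_incident_rate = 962 / 290 - 1,
    n_underdocumented = 12
  )
}

#' @rdname site_profile
#' @export
site2_profile <- function() {
  site_profile(
    site_id = "site2", n_patients = 1919, admission_rate = 3253 / 1919,
    prevalence = 0.077,
    los_log_mean = log(15), los_log_sd = 1.48,
    notelen_log_mean = log(190), notelen_log_sd = 1.1,
    frac_incidents_first4w = 0.488, frac_incidents_first24h = 0.064,
    diagnosis_mixture = site2_diagnoses(),
    vocab_size = 5000, notes_per_admission = 7,
    extra_incident_rate = 652 / 247 - 1,
    n_underdocumented = 24
  )
}

site1_diagnoses <- function() {
  d <- c(anxiety = 92, bipolar = 65, cognitive = 20, depressive = 106,
         developmental = 180, eating = 57, mood = 580, personality = 214,
         substance = 99, psychotic = 860, none = 795, other = 121)
  d / sum(d)
}

site2_diagnoses <- function() {
  d <- c(anxiety = 63, bipolar = 170, cognitive = 109, depressive = 150,
         developmental = 29, eating = 10, mood = 10, personality = 116,
         substance = 373, psychotic = 685, none = 1392, other = 146)
  d / sum(d)
}

#' @rdname site_profile
#' @param ... Overrides passed on to [site_profile()].
#' @export
demo_profile <- function(site_id = "demo", n_patients = 450, ...) {
  args <- modifyList(
    list(site_id = site_id, n_patients = n_patients,
         admission_rate = 1.44, prevalence = 0.091,
         los_log_mean = log(16), los_log_sd = 1.42,
         notelen_log_mean = log(40), notelen_log_sd = 0.6,
         vocab_size = 800, notes_per_admission = 4,
         min_post24_words = 110),
    list(...))
  do.call(site_profile, args)
}

#' @export
print.site_profile <- function(x, ...) {
  cat("<site_profile> ", x$site_id, "\n", sep = "")
  cat(sprintf("  patients: %d, admissions/patient: %.2f, prevalence: %.3f\n",
              x$n_patients, x$admission_rate, x$prevalence))
  cat(sprintf("  LOS median %.1f d; note length median %.0f words; vocab %d\n",
              exp(x$los_log_mean), exp(x$notelen_log_mean), x$vocab_size))
  cat(sprintf("  incident fractions: %.3f first 4 wk, %.3f first 24 h\n",
              x$frac_incidents_first4w, x$frac_incidents_first24h))
  cat(sprintf("  signal terms: %d (site_shift %.2f)\n",
              length(x$signal_terms), x$site_shift))
  invisible(x)
}
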