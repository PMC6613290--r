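# Synthetic two-site EHR corpus generator.
#
# Notes are synthetic token streams, not natural language: a Zipf-distributed
# background vocabulary plus planted signal terms whose per-note occurrence
# log-odds shift with the admission's true outcome. Only this distributional
# structure matters to the downstream pipeline.

with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

incident_categories <- function() {
  c("violence_verbal", "violence_physical", "self_harm", "substance_use",
    "sexual_intimidation", "vandalism")
}

violent_categories <- function() c("violence_verbal", "violence_physical")

# discrete triangular severity on [1, 22] with mode `mode`
rsoas <- function(n, mode = 12) {
  k <- 1:22
  w <- ifelse(k <= mode, (k - 0) / mode, (23 - k) / (23 - mode))
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

zipf_probs <- function(v, shift = 2.7) {
  p <- 1 / (seq_len(v) + shift)
  p / sum(p)
}

# site-local synonym for a (possibly multi-token) signal term
synonym_term <- function(term, site_id) {
  tag <- gsub("[^a-z0-9]", "", tolower(site_id))
  toks <- strsplit(term, " ", fixed = TRUE)[[1]]
  paste(paste0(toks, "syn", tag), collapse = " ")
}

#' Generate one synthetic site corpus
#'
#' Draws a full single-site EHR extract — admissions, clinical notes and
#' incident reports — with known ground truth. Patients may be readmitted
#' (`1 + Poisson(admission_rate - 1)` admissions each, consecutive admissions
#' separated by more than the 2-week merge gap). Outcomes are Bernoulli with
#' the configured prevalence; each outcome-positive admission is guaranteed
#' one qualifying violent incident between 24 hours and 4 weeks after
#' admission start, and the remaining incidents are placed so that the
#' site-level fractions falling in the first 24 hours / first 4 weeks match
#' the configured values as closely as length-of-stay truncation permits.
#' Signal terms occur per note with probability
#' `plogis(qlogis(signal_base_rate) + log_odds * outcome)` and are inserted at
#' random positions into the Zipf-distributed background token stream of notes
#' in the predictor window.
#'
#' @param profile A [site_profile()].
#' @param seed Integer seed; identical profile and seed give byte-identical
#'   corpora.
#' @return An object of class `site_corpus`: a list with data frames
#'   `admissions` (admission_id, patient_id, site, ward, diagnosis, start,
#'   end; times in fractional days), `notes` (note_id, admission_id,
#'   author_role, timestamp, text), `incidents` (incident_id, admission_id,
#'   timestamp, category, soas_r), and `truth` (a list with per-admission
#'   `labels` — outcome and latent risk — and the planted `signal_terms`).
#' @export
generate_site <- function(profile, seed) {
  validate_site_profile(profile)
  stopifnot(length(seed) == 1L, is.finite(seed))
  with_seed(seed, generate_site_impl(profile, seed))
}

generate_site_impl <- function(p, seed) {
  site <- p$site_id

  ## ---- patients and admissions -------------------------------------------
  n_adm_per_pat <- 1L + rpois(p$n_patients, p$admission_rate - 1)
  n_adm <- sum(n_adm_per_pat)
  patient_id <- rep(sprintf("%s-P%05d", site, seq_len(p$n_patients)), n_adm_per_pat)
  adm_index <- sequence(n_adm_per_pat)

  outcome <- rbinom(n_adm, 1L, p$prevalence)

  los <- rlnorm(n_adm, p$los_log_mean, p$los_log_sd)
  # the outcome window (24 h - 28 d) must intersect a positive admission
  short_pos <- which(outcome == 1L & los <= 1.5)
  while (length(short_pos)) {
    los[short_pos] <- rlnorm(length(short_pos), p$los_log_mean, p$los_log_sd)
    short_pos <- short_pos[los[short_pos] <= 1.5]
  }

  # consecutive admissions of a patient separated by > 14 d (already merged)
  first_start <- runif(p$n_patients, 0, p$study_days)
  gap <- 15 + stats::rexp(n_adm, 1 / 60)
  start <- numeric(n_adm)
  pos <- 1L
  for (i in seq_len(p$n_patients)) {
    k <- n_adm_per_pat[i]
    idx <- pos:(pos + k - 1L)
    t0 <- first_start[i]
    for (j in seq_len(k)) {
      start[idx[j]] <- t0
      t0 <- t0 + los[idx[j]] + gap[idx[j]]
    }
    pos <- pos + k
  }

  admissions <- data.frame(
    admission_id = sprintf("%s-A%05d", site, seq_len(n_adm)),
    patient_id = patient_id,
    site = site,
    ward = sample(sprintf("%s-W%d", site, 1:4), n_adm, replace = TRUE),
    diagnosis = sample(names(p$diagnosis_mixture), n_adm, replace = TRUE,
                       prob = p$diagnosis_mixture),
    start = start,
    end = start + los,
    stringsAsFactors = FALSE
  )

  under_doc <- sort(sample(n_adm, min(p$n_underdocumented, n_adm)))

  ## ---- notes --------------------------------------------------------------
  vocab <- sprintf("w%04d", seq_len(p$vocab_size))
  vp <- zipf_probs(p$vocab_size)
  sig_terms <- p$signal_terms
  sig_names <- names(sig_terms)

  n_in <- 1L + rpois(n_adm, p$notes_per_admission - 1)

  note_adm <- integer(0); note_time <- numeric(0); note_len <- integer(0)
  note_window <- logical(0)
  for (i in seq_len(n_adm)) {
    # predictor-window notes: 4 weeks before admission up to first 24 hours
    t_in <- sort(runif(n_in[i], start[i] - 28, start[i] + 1))
    # post-24h documentation: enough words to pass the 100-word rule unless
    # the admission is planted as under-documented
    if (i %in% under_doc) {
      len_post <- sample(20:80, 1L)
      t_post <- runif(1L, start[i] + 1, start[i] + 1 + max(los[i] - 1, 0.5))
    } else {
      len_post <- integer(0); tot <- 0
      while (tot < p$min_post24_words) {
        l <- pmax(5L, as.integer(round(rlnorm(1, p$notelen_log_mean, p$notelen_log_sd))))
        len_post <- c(len_post, l); tot <- tot + l
      }
      t_post <- sort(runif(length(len_post), start[i] + 1,
                           start[i] + 1 + max(los[i] - 1, 0.5)))
    }
    len_in <- pmax(5L, as.integer(round(rlnorm(n_in[i], p$notelen_log_mean,
                                               p$notelen_log_sd))))
    note_adm <- c(note_adm, rep(i, n_in[i] + length(len_post)))
    note_time <- c(note_time, t_in, t_post)
    note_len <- c(note_len, len_in, as.integer(len_post))
    note_window <- c(note_window, rep(TRUE, n_in[i]), rep(FALSE, length(len_post)))
  }
  n_notes <- length(note_adm)

  # background tokens drawn in one pass, then split per note
  all_tokens <- sample(vocab, sum(note_len), replace = TRUE, prob = vp)
  tok_split <- split(all_tokens, rep.int(seq_len(n_notes), note_len))

  # plant signal terms in predictor-window notes
  if (length(sig_terms)) {
    base_logit <- qlogis(p$signal_base_rate)
    for (j in seq_along(sig_terms)) {
      pr <- plogis(base_logit + sig_terms[j] * outcome[note_adm])
      occurs <- which(note_window & runif(n_notes) < pr)
      toks <- strsplit(sig_names[j], " ", fixed = TRUE)[[1]]
      for (k in occurs) {
        v <- tok_split[[k]]
        at <- sample.int(length(v) + 1L, 1L) - 1L
        tok_split[[k]] <- append(v, toks, after = at)
      }
    }
  }

  notes <- data.frame(
    note_id = sprintf("%s-N%06d", site, seq_len(n_notes)),
    admission_id = admissions$admission_id[note_adm],
    author_role = sample(c("psychiatrist", "nurse"), n_notes, replace = TRUE,
                         prob = c(0.25, 0.75)),
    timestamp = note_time,
    text = vapply(tok_split, paste, character(1), collapse = " "),
    stringsAsFactors = FALSE
  )
  rownames(notes) <- NULL

  ## ---- incidents ----------------------------------------------------------
  pos_idx <- which(outcome == 1L)
  n_pos <- length(pos_idx)

  # guaranteed qualifying incident per positive admission, in (24 h, 4 wk]
  g_adm <- pos_idx
  g_time <- start[g_adm] + runif(n_pos, 1, pmin(28, los[g_adm]))
  g_cat <- sample(violent_categories(), n_pos, replace = TRUE)

  # extra incidents: positives carry additional incidents of any category,
  # attached proportionally to (capped) length of stay — longer admissions
  # accumulate more incidents; negatives occasionally carry non-qualifying
  # (non-violent) incidents
  m_pos <- rpois(1L, n_pos * p$extra_incident_rate)
  e_adm <- if (m_pos > 0L && n_pos > 0L)
    pos_idx[sample.int(n_pos, m_pos, replace = TRUE,
                       prob = pmin(los[pos_idx], 90))]
  else integer(0)
  neg_idx <- which(outcome == 0L & runif(n_adm) < p$neg_incident_rate)
  e_adm <- c(e_adm, rep(neg_idx, 1L + rpois(length(neg_idx), 0.3)))
  e_is_pos <- outcome[e_adm] == 1L
  m <- length(e_adm)

  e_cat <- character(m)
  e_cat[e_is_pos] <- sample(incident_categories(), sum(e_is_pos), replace = TRUE,
                            prob = c(0.35, 0.35, 0.10, 0.10, 0.05, 0.05))
  e_cat[!e_is_pos] <- sample(setdiff(incident_categories(), violent_categories()),
                             sum(!e_is_pos), replace = TRUE,
                             prob = c(0.40, 0.30, 0.15, 0.15))

  e_time <- allocate_incident_times(
    los = los[e_adm], n_guaranteed = n_pos,
    frac24 = p$frac_incidents_first24h, frac4w = p$frac_incidents_first4w
  ) + start[e_adm]

  incidents <- data.frame(
    admission_id = admissions$admission_id[c(g_adm, e_adm)],
    timestamp = c(g_time, e_time),
    category = c(g_cat, e_cat),
    soas_r = rsoas(n_pos + m),
    stringsAsFactors = FALSE
  )
  incidents <- incidents[order(incidents$admission_id, incidents$timestamp), ]
  incidents$incident_id <- sprintf("%s-I%06d", site, seq_len(nrow(incidents)))
  incidents <- incidents[, c("incident_id", "admission_id", "timestamp",
                             "category", "soas_r")]
  rownames(incidents) <- NULL

  truth <- list(
    labels = data.frame(admission_id = admissions$admission_id,
                        outcome = outcome,
                        latent_risk = rep(p$prevalence, n_adm),
                        stringsAsFactors = FALSE),
    signal_terms = sig_terms
  )

  structure(list(admissions = admissions, notes = notes, incidents = incidents,
                 truth = truth, profile = p, seed = seed),
            class = "site_corpus")
}

# Place extra incidents into timing strata (first 24 h / 24 h-4 wk / after
# 4 wk) so that, together with the guaranteed 4-week incidents, the overall
# fractions match the configured ones. Deterministic count allocation with
# availability constraints: the after-4-wk stratum needs length of stay
# > 28 d; unplaceable allocations spill into the adjacent earlier stratum.
allocate_incident_times <- function(los, n_guaranteed, frac24, frac4w) {
  m <- length(los)
  if (m == 0L) return(numeric(0))
  n_total <- m + n_guaranteed
  n1 <- round(frac24 * n_total)                       # target: first 24 h
  n2 <- round(frac4w * n_total) - n1 - n_guaranteed   # target: 24 h - 4 wk
  n3 <- m - n1 - max(n2, 0)                           # target: after 4 wk
  if (n2 < 0) { n3 <- n3 + n2; n2 <- 0 }
  if (n3 < 0) { n2 <- max(0, n2 + n3); n3 <- 0 }
  if (n1 + n2 + n3 > m) n1 <- m - n2 - n3

  pick <- function(avail, n_take) {
    if (length(avail) == 0L || n_take <= 0L) return(integer(0))
    avail[sample.int(length(avail), min(n_take, length(avail)))]
  }
  stratum <- rep(1L, m)
  avail3 <- which(los > 28)
  take3 <- pick(avail3, n3)
  stratum[take3] <- 3L
  n2 <- n2 + (n3 - length(take3))                     # spill unplaceable late
  take2 <- pick(setdiff(which(los > 1), take3), n2)
  stratum[take2] <- 2L

  t <- numeric(m)
  s1 <- stratum == 1L
  t[s1] <- runif(sum(s1), 0, pmin(1, los[s1]))
  t[take2] <- runif(length(take2), 1, pmin(28, los[take2]))
  t[take3] <- runif(length(take3), 28, los[take3])
  t
}

#' Generate a pair of synthetic site corpora with shifted signal inventories
#'
#' Generates two sites sharing the background vocabulary. Each site's
#' `site_shift` is the per-term probability that a signal term is replaced by
#' a site-local synonym carrying the same log-odds shift — emulating the
#' observation that predictive terms at one centre often have a counterpart
#' with similar meaning, rather than the identical token, at another. With
#' `site_shift = 0` in both profiles the two sites draw signal terms from the
#' identical inventory; with `site_shift = 1` they share none.
#'
#' @param profile_a,profile_b [site_profile()]s; `site_id`s must differ.
#' @param seed Integer seed.
#' @return A list with elements `a` and `b` (each a `site_corpus`) and
#'   `shared_signal_terms`, the terms left unshifted in both sites.
#' @export
generate_pair <- function(profile_a, profile_b, seed) {
  validate_site_profile(profile_a)
  validate_site_profile(profile_b)
  if (identical(profile_a$site_id, profile_b$site_id))
    stop("the two site profiles must have distinct site_id labels", call. = FALSE)
  seeds <- derive_seeds(seed, 4L)

  shift_inventory <- function(profile, s) {
    terms <- profile$signal_terms
    if (!length(terms) || profile$site_shift == 0) return(terms)
    shifted <- with_seed(s, runif(length(terms)) < profile$site_shift)
    nm <- names(terms)
    nm[shifted] <- vapply(nm[shifted], synonym_term, character(1),
                          site_id = profile$site_id)
    names(terms) <- nm
    terms
  }

  pa <- profile_a; pa$signal_terms <- shift_inventory(profile_a, seeds[1])
  pb <- profile_b; pb$signal_terms <- shift_inventory(profile_b, seeds[2])

  a <- generate_site(pa, seeds[3])
  b <- generate_site(pb, seeds[4])
  shared <- intersect(names(pa$signal_terms), names(pb$signal_terms))
  list(a = a, b = b, shared_signal_terms = shared)
}

#' @export
print.site_corpus <- function(x, ...) {
  cat("<site_corpus> ", x$profile$site_id, "\n", sep = "")
  cat(sprintf("  %d admissions of %d patients; %d notes; %d incidents\n",
              nrow(x$admissions), length(unique(x$admissions$patient_id)),
              nrow(x$notes), nrow(x$incidents)))
  cat(sprintf("  outcome prevalence %.3f (configured %.3f); seed %s\n",
              mean(x$truth$labels$outcome), x$profile$prevalence,
              format(x$seed)))
  invisible(x)
}

#' Write or read a site corpus as delimited text files
#'
#' Writes `admissions.csv`, `notes.csv`, `incidents.csv` and `truth.csv`
#' plus a `profile.json` sidecar recording the full generator profile and
#' seed for provenance.
#'
#' @param corpus A `site_corpus`.
#' @param dir Directory to write to (created if needed).
#' @return `write_corpus()` returns `dir` invisibly; `read_corpus()` returns
#'   a `site_corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "site_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(corpus$admissions, file.path(dir, "admissions.csv"), row.names = FALSE)
  write.csv(corpus$notes, file.path(dir, "notes.csv"), row.names = FALSE)
  write.csv(corpus$incidents, file.path(dir, "incidents.csv"), row.names = FALSE)
  tr <- corpus$truth$labels
  write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  prof <- unclass(corpus$profile)
  prof$signal_terms <- as.list(prof$signal_terms)
  prof$diagnosis_mixture <- as.list(prof$diagnosis_mixture)
  jsonlite::write_json(list(profile = prof, seed = corpus$seed,
                            signal_terms = as.list(corpus$truth$signal_terms)),
                       file.path(dir, "profile.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  adm <- read.csv(file.path(dir, "admissions.csv"), stringsAsFactors = FALSE)
  notes <- read.csv(file.path(dir, "notes.csv"), stringsAsFactors = FALSE)
  inc <- read.csv(file.path(dir, "incidents.csv"), stringsAsFactors = FALSE)
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  sidecar <- file.path(dir, "profile.json")
  profile <- NULL; seed <- NA_integer_; sig <- numeric(0)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed <- meta$seed
    sig <- unlist(meta$signal_terms) %||% numeric(0)
    profile <- meta$profile
  }
  if (file.exists(tp)) {
    truth <- list(labels = read.csv(tp, stringsAsFactors = FALSE),
                  signal_terms = sig)
  }
  structure(list(admissions = adm, notes = notes, incidents = inc,
                 truth = truth, profile = profile, seed = seed),
            class = "site_corpus")
}
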