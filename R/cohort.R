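# Cohort construction: episode merging, note-window selection, outcome
# labelling, and documentation-based exclusions.
#
# Conventions (durations, not boundary rules, are given by the source data
# model): "4 weeks" = 28 days, "24 hours" = 1 day; the predictor window is
# [start - 28 d, start + 1 d] (closed), the outcome window is
# (start + 1 d, start + 28 d] (open on the left so first-day incidents never
# label the admission).

#' Merge admission episodes separated by short absences
#'
#' Consecutive episodes of the same patient separated by at most
#' `max_gap_days` (gap measured as next start minus previous end) are merged
#' into a single admission spanning both — e.g. discharge and prompt
#' readmission, or a temporary transfer to a non-psychiatric department.
#' Longer absences remain separate admissions. Overlapping episodes of one
#' patient are merged with a warning (treated as gap 0). The operation is
#' idempotent.
#'
#' @param episodes Data frame with columns `admission_id`, `patient_id`,
#'   `start`, `end` (fractional days, or `POSIXct`/`Date`), and any others
#'   (kept from the first episode of a merged run).
#' @param max_gap_days Maximum bridged absence in days (the gap is merged when
#'   `gap <= max_gap_days`).
#' @return A data frame of merged admissions, with an `episode_map` attribute
#'   (data frame `episode_id` -> `admission_id`) recording which input
#'   episodes compose each merged admission.
#' @export
merge_episodes <- function(episodes, max_gap_days = 14) {
  stopifnot(all(c("admission_id", "patient_id", "start", "end") %in% names(episodes)))
  episodes$start <- as_days(episodes$start)
  episodes$end <- as_days(episodes$end)
  if (any(episodes$start >= episodes$end))
    stop("episode start must precede end", call. = FALSE)
  if (any(!nzchar(episodes$patient_id) | is.na(episodes$patient_id)))
    stop("patient_id must be nonempty", call. = FALSE)

  ord <- order(episodes$patient_id, episodes$start)
  ep <- episodes[ord, , drop = FALSE]
  n <- nrow(ep)
  group <- integer(n)
  g <- 0L
  overlap_seen <- FALSE
  for (i in seq_len(n)) {
    if (i == 1L || ep$patient_id[i] != ep$patient_id[i - 1L]) {
      g <- g + 1L
    } else {
      gap <- ep$start[i] - max(ep$end[group == g])
      if (gap < 0) overlap_seen <- TRUE
      if (gap <= max_gap_days) {
        # same admission: bridged absence
      } else {
        g <- g + 1L
      }
    }
    group[i] <- g
  }
  if (overlap_seen)
    warning("overlapping episodes of the same patient merged (treated as gap 0)")

  first_of_group <- !duplicated(group)
  merged <- ep[first_of_group, , drop = FALSE]
  merged$end <- as.numeric(tapply(ep$end, group, max))
  rownames(merged) <- NULL
  attr(merged, "episode_map") <- data.frame(
    episode_id = ep$admission_id,
    admission_id = merged$admission_id[group],
    stringsAsFactors = FALSE
  )
  merged
}

#' Select the predictor-window document for one admission
#'
#' Concatenates, in chronological order, all notes with a timestamp in the
#' predictor window `[start - 28 d, start + 1 d]` into one token sequence.
#'
#' @param admission A one-row data frame (or list) with a `start` field.
#' @param notes Data frame of this admission's notes with `timestamp` and
#'   `text` columns.
#' @return Character vector of tokens (empty, with a warning, when no note
#'   falls in the window; such admissions are flagged for exclusion
#'   downstream).
#' @export
select_note_window <- function(admission, notes) {
  start <- as_days(admission$start)[1]
  ts <- as_days(notes$timestamp)
  keep <- ts >= start - 28 & ts <= start + 1
  if (!any(keep)) {
    warning("no notes in the predictor window; empty document")
    return(character(0))
  }
  sel <- notes[keep, , drop = FALSE]
  sel <- sel[order(as_days(sel$timestamp)), , drop = FALSE]
  unlist(tokenize(sel$text), use.names = FALSE)
}

#' Label the violent outcome of one admission
#'
#' The outcome is positive iff at least one incident of a violent category
#' (`violence_verbal`, `violence_physical`) falls in the outcome window
#' `(start + 1 d, start + 28 d]`. Self-harm, substance use, sexual
#' intimidation and vandalism never qualify, nor do incidents in the first
#' 24 hours or after 4 weeks.
#'
#' @param admission A one-row data frame (or list) with a `start` field.
#' @param incidents Data frame of this admission's incidents with `timestamp`
#'   and `category` columns.
#' @return Integer 0 or 1.
#' @export
label_outcome <- function(admission, incidents) {
  if (NROW(incidents) == 0L) return(0L)
  start <- as_days(admission$start)[1]
  ts <- as_days(incidents$timestamp)
  qualifying <- incidents$category %in% violent_categories() &
    ts > start + 1 & ts <= start + 28
  as.integer(any(qualifying))
}

#' Exclude under-documented admissions
#'
#' Admissions with fewer than `min_words` words registered after the first 24
#' hours of admission are removed: without follow-up documentation the outcome
#' cannot be assessed. The word count uses the shared tokenizer.
#'
#' @param labeled Data frame of labeled admissions containing a
#'   `word_count_post24h` column (as produced by [build_cohort()]).
#' @param min_words Exclusion threshold; admissions with
#'   `word_count_post24h < min_words` are removed (a count of exactly
#'   `min_words` is retained).
#' @return The retained rows, with attribute `n_excluded` and an
#'   `excluded_ids` attribute naming the removed admissions.
#' @export
apply_exclusions <- function(labeled, min_words = 100) {
  stopifnot("word_count_post24h" %in% names(labeled))
  drop <- labeled$word_count_post24h < min_words
  out <- labeled[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "excluded_ids") <- labeled$admission_id[drop]
  message(sprintf("excluded %d of %d admissions with < %d words after 24 h",
                  sum(drop), nrow(labeled), min_words))
  out
}

#' Build the labeled analysis cohort from raw tables
#'
#' Runs the full cohort pipeline: episode merging, predictor-window document
#' assembly, outcome labelling, and the post-24-hour word-count exclusion.
#'
#' @param admissions,notes,incidents Raw tables in the generator's schema (or
#'   a real extract mapped onto it). A `site_corpus` can be passed as the
#'   first argument instead.
#' @param max_gap_days Episode-merge gap, days.
#' @param min_words Post-24-hour word-count exclusion threshold.
#' @param count_window Which word count the exclusion applies to:
#'   `"post24h"` (default; words registered after the first 24 hours) or
#'   `"predictor"` (words in the predictor-window document).
#' @return A tibble of class `labeled_cohort` with one row per retained
#'   admission: `admission_id`, `patient_id`, `site`, `outcome`,
#'   `length_of_stay` (days), `first_incident_day` (days from admission start
#'   to the first qualifying incident; `NA` for outcome-negative admissions),
#'   `word_count` (predictor window), `word_count_post24h`, and `document`
#'   (the predictor-window token sequence, space-joined). Attributes
#'   `n_excluded` / `excluded_ids` report the word-count exclusion.
#' @export
build_cohort <- function(admissions, notes = NULL, incidents = NULL,
                         max_gap_days = 14, min_words = 100,
                         count_window = c("post24h", "predictor")) {
  count_window <- match.arg(count_window)
  if (inherits(admissions, "site_corpus")) {
    corpus <- admissions
    admissions <- corpus$admissions
    notes <- corpus$notes
    incidents <- corpus$incidents
  }
  stopifnot(is.data.frame(admissions), is.data.frame(notes), is.data.frame(incidents))
  if (!all(notes$author_role %in% c("psychiatrist", "nurse")))
    stop("notes must be authored by psychiatrists or nurses", call. = FALSE)

  merged <- merge_episodes(admissions, max_gap_days = max_gap_days)
  emap <- attr(merged, "episode_map")
  remap <- setNames(emap$admission_id, emap$episode_id)
  notes$admission_id <- unname(remap[notes$admission_id])
  incidents$admission_id <- unname(remap[incidents$admission_id])
  if (anyNA(notes$admission_id) || anyNA(incidents$admission_id))
    stop("notes/incidents reference unknown admission ids", call. = FALSE)

  n <- nrow(merged)
  start <- as_days(merged$start)
  note_ts <- as_days(notes$timestamp)
  note_adm <- match(notes$admission_id, merged$admission_id)
  in_window <- note_ts >= (start[note_adm] - 28) & note_ts <= (start[note_adm] + 1)
  post24 <- note_ts > (start[note_adm] + 1)
  wc <- count_words(notes$text)

  agg <- function(v, flag) {
    out <- numeric(n)
    s <- tapply(v[flag], note_adm[flag], sum)
    out[as.integer(names(s))] <- s
    out
  }
  word_count <- as.integer(agg(wc, in_window))
  word_count_post24h <- as.integer(agg(wc, post24))

  # chronological predictor-window documents
  ord <- order(note_adm, note_ts)
  sel <- ord[in_window[ord]]
  docs <- character(n)
  doc_parts <- split(tolower(notes$text[sel]), note_adm[sel])
  docs[as.integer(names(doc_parts))] <- vapply(doc_parts, paste, character(1),
                                               collapse = " ")

  inc_adm <- match(incidents$admission_id, merged$admission_id)
  inc_day <- as_days(incidents$timestamp) - start[inc_adm]
  qualifying <- incidents$category %in% violent_categories() &
    inc_day > 1 & inc_day <= 28
  outcome <- integer(n)
  first_day <- rep(NA_real_, n)
  if (any(qualifying)) {
    q_adm <- inc_adm[qualifying]
    q_day <- inc_day[qualifying]
    outcome[unique(q_adm)] <- 1L
    fd <- tapply(q_day, q_adm, min)
    first_day[as.integer(names(fd))] <- fd
  }

  labeled <- tibble::tibble(
    admission_id = merged$admission_id,
    patient_id = merged$patient_id,
    site = if ("site" %in% names(merged)) merged$site else NA_character_,
    outcome = outcome,
    length_of_stay = as_days(merged$end) - start,
    first_incident_day = first_day,
    word_count = word_count,
    word_count_post24h = word_count_post24h,
    document = docs
  )

  count_col <- if (count_window == "post24h") "word_count_post24h" else "word_count"
  drop <- labeled[[count_col]] < min_words
  out <- labeled[!drop, , drop = FALSE]
  message(sprintf("cohort: %d admissions retained, %d excluded (< %d words, %s window)",
                  nrow(out), sum(drop), min_words, count_window))
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "excluded_ids") <- labeled$admission_id[drop]
  class(out) <- c("labeled_cohort", class(out))
  out
}
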