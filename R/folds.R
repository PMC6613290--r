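#' Assign patient-grouped cross-validation folds
#'
#' Partitions admissions into `k` folds such that all admissions of one
#' patient share a fold — predictions for an admission are then never
#' informed by other (e.g. future) admissions of the same patient. Patients
#' are shuffled (seeded), ordered by their admission count (largest first),
#' and greedily assigned to the currently smallest fold, which balances fold
#' sizes as far as grouping permits; with one admission per patient and `n`
#' divisible by `k`, fold sizes are exactly `n / k`.
#'
#' @param labeled A `labeled_cohort` (or any data frame with `admission_id`
#'   and `patient_id`).
#' @param k Number of folds (>= 2, at most the number of patients).
#' @param seed Integer seed for the patient shuffle.
#' @return A `fold_plan`: tibble with `admission_id`, `patient_id`, `fold`,
#'   plus attributes `k` and `seed`.
#' @export
assign_grouped_folds <- function(labeled, k = 5, seed = 1L) {
  stopifnot(all(c("admission_id", "patient_id") %in% names(labeled)), k >= 2)
  patients <- unique(labeled$patient_id)
  if (k > length(patients))
    stop(sprintf("cannot form %d patient-grouped folds from %d patients",
                 k, length(patients)), call. = FALSE)

  n_adm <- table(labeled$patient_id)
  shuffled <- with_seed(seed, sample(patients))
  shuffled <- shuffled[order(-as.integer(n_adm[shuffled]))] # stable: keeps shuffle within ties

  fold_size <- integer(k)
  patient_fold <- integer(length(shuffled))
  for (i in seq_along(shuffled)) {
    f <- which.min(fold_size)
    patient_fold[i] <- f
    fold_size[f] <- fold_size[f] + as.integer(n_adm[shuffled[i]])
  }
  names(patient_fold) <- shuffled

  plan <- tibble::tibble(
    admission_id = labeled$admission_id,
    patient_id = labeled$patient_id,
    fold = unname(patient_fold[labeled$patient_id])
  )
  structure(plan, k = as.integer(k), seed = as.integer(seed),
            class = c("fold_plan", class(plan)))
}
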