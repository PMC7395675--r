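# Cohort curation: SAP-OCT pairing within a day window, reliability and
# quality exclusions, and patient-level train/validation/test splitting.

#' Pair perimetry and OCT tests within a day window
#'
#' Within each eye, every SAP test is paired with the nearest-in-time OCT test
#' whose date lies within `max_days` (inclusive) of the SAP date; ties are
#' broken toward the earlier OCT. One OCT may serve several SAP tests.
#' Unpairable SAP tests are dropped and counted.
#'
#' @param sap Data frame with columns `sap_id`, `eye_id`, `date`.
#' @param oct Data frame with columns `oct_id`, `eye_id`, `date`.
#' @param max_days Pairing window in days (inclusive boundary).
#' @return List with `pairs` (data frame `sap_id`, `oct_id`, `delta_days` =
#'   OCT date − SAP date) and `dropped` (data frame `sap_id`, `reason`).
#' @export
pair_exams <- function(sap, oct, max_days = 180) {
  stop_if_not(all(c("sap_id", "eye_id", "date") %in% names(sap)),
              "sap needs columns sap_id, eye_id, date")
  stop_if_not(all(c("oct_id", "eye_id", "date") %in% names(oct)),
              "oct needs columns oct_id, eye_id, date")
  pairs <- list(); dropped <- list()
  oct_by_eye <- split(oct, oct$eye_id)
  for (i in seq_len(nrow(sap))) {
    cand <- oct_by_eye[[as.character(sap$eye_id[i])]]
    if (is.null(cand) || nrow(cand) == 0) {
      dropped[[length(dropped) + 1]] <-
        data.frame(sap_id = sap$sap_id[i], reason = "no_oct_for_eye")
      next
    }
    delta <- as.numeric(cand$date - sap$date[i])
    ok <- abs(delta) <= max_days
    if (!any(ok)) {
      dropped[[length(dropped) + 1]] <-
        data.frame(sap_id = sap$sap_id[i], reason = "outside_window")
      next
    }
    cand <- cand[ok, , drop = FALSE]; delta <- delta[ok]
    # nearest in time; tie toward the earlier OCT date
    ord <- order(abs(delta), cand$date)
    pairs[[length(pairs) + 1]] <- data.frame(
      sap_id = sap$sap_id[i], oct_id = cand$oct_id[ord[1]],
      delta_days = delta[ord[1]])
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, pairs)
            else data.frame(sap_id = character(), oct_id = character(),
                            delta_days = numeric()),
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(sap_id = character(), reason = character())
  )
}

#' Apply reliability and quality filters
#'
#' Keeps an exam iff fixation losses are at most 33%, false positives at most
#' 15%, and the OCT quality score is at least 15 — the literal reading of the
#' exclusion wording (">33%" excludes, "lower than 15" excludes). Exams with
#' missing metadata are excluded with reason `missing_metadata`. Filtering is
#' idempotent.
#'
#' @param cohort A `paired_cohort`.
#' @param max_fixation_loss,max_false_positive,min_quality Filter boundaries.
#' @return List with `cohort` (the retained exams) and `log` (data frame
#'   `exam_id`, `reason`; one row per excluded exam and reason).
#' @export
apply_reliability_filters <- function(cohort,
                                      max_fixation_loss = 0.33,
                                      max_false_positive = 0.15,
                                      min_quality = 15) {
  ex <- cohort$exams
  need <- c("fixation_loss_frac", "false_positive_frac", "oct_quality_score")
  stop_if_not(all(need %in% names(ex)), "cohort lacks reliability metadata")
  miss <- Reduce(`|`, lapply(ex[need], is.na))
  fl <- !miss & ex$fixation_loss_frac > max_fixation_loss
  fp <- !miss & ex$false_positive_frac > max_false_positive
  ql <- !miss & ex$oct_quality_score < min_quality
  log <- rbind(
    if (any(miss)) data.frame(exam_id = ex$exam_id[miss], reason = "missing_metadata"),
    if (any(fl)) data.frame(exam_id = ex$exam_id[fl], reason = "fixation_loss"),
    if (any(fp)) data.frame(exam_id = ex$exam_id[fp], reason = "false_positive"),
    if (any(ql)) data.frame(exam_id = ex$exam_id[ql], reason = "low_quality")
  )
  if (is.null(log)) log <- data.frame(exam_id = integer(), reason = character())
  keep <- !(miss | fl | fp | ql)
  list(cohort = cohort[keep], log = log)
}

#' Patient-level train/validation/test split
#'
#' Patients (not eyes or exams) are shuffled with a seeded RNG and allocated
#' first to the test set, then to validation, then to training, so that no
#' patient contributes exams to more than one set. `val_frac` is taken from
#' the patients remaining after the test reservation. All of a patient's exams
#' follow the patient; the union of the three sets is exactly the input.
#'
#' @param cohort A `paired_cohort`.
#' @param test_frac,val_frac Fractions in (0, 1) of patients (test) and of
#'   remaining patients (validation).
#' @param seed Integer seed.
#' @return Object of class `split_result`: list of `paired_cohort`s `train`,
#'   `validation`, `test`, plus `patient_ids` (list of id vectors) and `seed`.
#' @export
split_by_patient <- function(cohort, test_frac = 0.15, val_frac = 0.15,
                             seed = 1L) {
  stop_if_not(test_frac > 0 && test_frac < 1 && val_frac > 0 && val_frac < 1,
              "fractions must lie in (0, 1)")
  ids <- unique(cohort$exams$patient_id)
  stop_if_not(length(ids) >= 3, "need at least 3 patients to form 3 sets")
  set.seed(seed)
  ids <- sample(ids)
  n_test <- max(1, round(test_frac * length(ids)))
  n_val <- max(1, round(val_frac * (length(ids) - n_test)))
  stop_if_not(n_test + n_val < length(ids), "fractions leave no training patients")
  test_ids <- ids[seq_len(n_test)]
  val_ids <- ids[n_test + seq_len(n_val)]
  train_ids <- ids[-seq_len(n_test + n_val)]
  pick <- function(set) cohort[cohort$exams$patient_id %in% set]
  structure(
    list(train = pick(train_ids), validation = pick(val_ids),
         test = pick(test_ids),
         patient_ids = list(train = sort(train_ids), validation = sort(val_ids),
                            test = sort(test_ids)),
         seed = seed),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("patient-level split: train %d / validation %d / test %d exams (%d/%d/%d patients)\n",
              n_exams(x$train), n_exams(x$validation), n_exams(x$test),
              length(x$patient_ids$train), length(x$patient_ids$validation),
              length(x$patient_ids$test)))
  invisible(x)
}
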