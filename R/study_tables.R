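#' Printed per-iteration validation counts
#'
#' The 2x2 cross-classification (screener vs clinician referral decision)
#' printed for each of the seven development iterations, together with the
#' setting and the change each iteration introduced. These published
#' counts are inputs: [accuracy_summary()] recomputes the accuracy metrics
#' from them.
#'
#' @return A tibble with columns `iteration`, `setting`, `change`, `tp`,
#'   `fn`, `fp`, `tn`.
#' @examples
#' iteration_counts()
#' @export
iteration_counts <- function() {
  cat <- algorithm_catalog()
  tibble::tibble(
    iteration = 1:7,
    setting = cat$setting,
    change = cat$change,
    tp = c(117L, 250L, 110L, 182L, 144L, 342L, 344L),
    fn = c(1L, 3L, 3L, 50L, 28L, 36L, 34L),
    fp = c(10L, 18L, 74L, 32L, 54L, 102L, 43L),
    tn = c(11L, 35L, 16L, 99L, 85L, 176L, 153L)
  )
}

#' Accuracy metrics recomputed for every iteration
#'
#' Applies [accuracy_summary()] to each iteration's printed 2x2 counts.
#'
#' @param counts A tibble as from [iteration_counts()].
#' @param level Confidence level; default 0.95.
#' @return A tibble with one row per iteration x metric: the
#'   [iteration_counts()] columns plus `metric`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @examples
#' iteration_accuracy()
#' @export
iteration_accuracy <- function(counts = iteration_counts(), level = 0.95) {
  counts |>
    dplyr::rowwise() |>
    dplyr::reframe(
      iteration = .data$iteration, setting = .data$setting,
      accuracy_summary(confusion_table(.data$tp, .data$fn, .data$fp, .data$tn),
        level = level)
    )
}

#' Printed clinician diagnoses of reference-referred participants
#'
#' For the final-iteration validation cohort, the clinical diagnosis of
#' every participant the reference clinician referred, split by whether
#' the screener also referred them (`cv_referred`) or missed them
#' (`cv_not_referred`, the false negatives). The `group` column collapses
#' allergic and other conjunctivitis into a single conjunctivitis group.
#'
#' @return A tibble with columns `diagnosis`, `group`, `cv_referred`,
#'   `cv_not_referred`.
#' @examples
#' diagnosis_referrals()
#' @export
diagnosis_referrals <- function() {
  tibble::tibble(
    diagnosis = c(
      "cataract", "presbyopia", "glaucoma", "refractive_error",
      "allergic_conjunctivitis", "other_conjunctivitis", "corneal_disease",
      "retinal_disease", "eye_injury_foreign_body", "uveitis",
      "pterygium_conjunctival_swelling", "chalazion_lid_swelling", "other"
    ),
    group = c(
      "cataract", "presbyopia", "glaucoma", "refractive_error",
      "conjunctivitis", "conjunctivitis", "corneal_disease",
      "retinal_disease", "eye_injury_foreign_body", "uveitis",
      "pterygium_conjunctival_swelling", "chalazion_lid_swelling", "other"
    ),
    cv_referred = c(29L, 56L, 1L, 64L, 117L, 44L, 2L, 5L, 1L, 1L, 10L, 2L, 12L),
    cv_not_referred = c(0L, 2L, 1L, 2L, 16L, 9L, 0L, 0L, 0L, 0L, 0L, 0L, 4L)
  )
}

#' Composition of the false negatives by diagnosis group
#'
#' Groups the screener-missed (false-negative) column of
#' [diagnosis_referrals()] and reports each group's share.
#'
#' @param referrals A tibble as from [diagnosis_referrals()].
#' @return A tibble with columns `group`, `n_false_negative`, `share`,
#'   sorted by descending count.
#' @examples
#' false_negative_composition()
#' @export
false_negative_composition <- function(referrals = diagnosis_referrals()) {
  referrals |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_false_negative = sum(.data$cv_not_referred)) |>
    dplyr::mutate(share = .data$n_false_negative / sum(.data$n_false_negative)) |>
    dplyr::arrange(dplyr::desc(.data$n_false_negative))
}
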