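#' Catalog of the seven referral-algorithm iterations
#'
#' The referral rule set was developed iteratively: one hospital-setting
#' iteration followed by six community-setting iterations, each changing
#' the questions asked or the mandatory examinations until the target
#' sensitivity (>= 90%) and specificity (>= 75%) were met at iteration 7.
#'
#' @return A tibble with one row per iteration and columns:
#' \describe{
#'   \item{iteration}{1 to 7.}
#'   \item{setting}{`"hospital"` (iteration 1) or `"community"`.}
#'   \item{problem_question_scope}{`"any_duration"` or `"today_only"` for
#'     the generic eye-problem question (iterations 1-4).}
#'   \item{symptom_questions}{List-column of the symptom questions asked:
#'     a subset of `any_eye_problem`, `eye_pain`,
#'     `eye_pain_or_discomfort`, `vision_difficulty`.}
#'   \item{distance_va_mandatory}{Is distance acuity testing mandatory for
#'     participants aged 6+? (From iteration 3 on.)}
#'   \item{near_vision_required_40plus}{Is the N8 near-vision check at
#'     33 cm required for participants aged 40+? (Iteration 7 only.)}
#'   \item{change}{Short label for what the iteration introduced.}
#' }
#' @examples
#' algorithm_catalog()
#' @export
algorithm_catalog <- function() {
  tibble::tibble(
    iteration = 1:7,
    setting = c("hospital", rep("community", 6)),
    problem_question_scope = c(
      "any_duration", "any_duration", "any_duration", "today_only",
      NA_character_, NA_character_, NA_character_
    ),
    symptom_questions = list(
      "any_eye_problem", "any_eye_problem", "any_eye_problem",
      "any_eye_problem",
      c("eye_pain", "vision_difficulty"),
      c("eye_pain_or_discomfort", "vision_difficulty"),
      c("eye_pain_or_discomfort", "vision_difficulty")
    ),
    distance_va_mandatory = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    near_vision_required_40plus = c(rep(FALSE, 6), TRUE),
    change = c(
      "any eye problem (no time limit); distance VA optional; enriched hospital sample",
      "same rule in outreach setting with self-selected patients",
      "introduced mandatory distance VA testing",
      "limited the eye-problem question to today",
      "replaced the problem question with eye pain + difficulty seeing far/near",
      "expanded eye pain to pain or discomfort",
      "added mandatory near vision (N8 at 33 cm) for ages 40+"
    )
  )
}

# canonical emission order for reason codes
referral_reason_codes <- c(
  "child_problem", "low_distance_va", "pain_or_discomfort",
  "vision_difficulty", "near_vision_fail", "any_eye_problem"
)

yes_flag <- function(x) !is.na(x) & x == "yes"
fail_flag <- function(x) !is.na(x) & x == "fail"

stop_missing <- function(field, iteration, ids) {
  stop(sprintf(
    "iteration %d requires `%s`, which is missing for participant(s): %s",
    iteration, field, paste(utils::head(ids, 5), collapse = ", ")
  ), call. = FALSE)
}

require_answered <- function(data, field, iteration, who) {
  if (!field %in% names(data)) {
    stop(sprintf(
      "iteration %d requires column `%s`, which is absent from the data",
      iteration, field
    ), call. = FALSE)
  }
  miss <- who & is.na(data[[field]])
  if (any(miss)) stop_missing(field, iteration, data$id[miss])
}

#' Apply a referral-algorithm iteration to participant records
#'
#' Computes the automated refer / do-not-refer decision for each record
#' under one of the seven rule sets (see [algorithm_catalog()]). Under the
#' final rule (iteration 7) a participant aged 6+ is referred if distance
#' acuity is worse than the threshold in either eye, or they report eye
#' pain or discomfort, or difficulty seeing far or near, or (aged 40+)
#' they fail the N8 near-vision check; a child under 6 is referred if the
#' parent or guardian reports any eye problem. Earlier iterations apply
#' their own question subsets, and iterations 1-2 consult distance acuity
#' only when it was measured.
#'
#' A field that the selected iteration makes mandatory (both acuities for
#' ages 6+ from iteration 3, `near_n8` for ages 40+ at iteration 7, the
#' symptom answers it asks) must be present and answered; a missing value
#' raises an error naming the field and iteration rather than defaulting.
#'
#' @param data A participant tibble as returned by [read_participants()]
#'   or [simulate_participants()]; see [participant_schema()].
#' @param iteration Integer 1-7; defaults to the final algorithm, 7.
#' @param threshold Snellen referral threshold for distance acuity
#'   (strictly worse triggers); default `"6/12"`.
#' @return The input tibble with two added columns: `refer` (logical) and
#'   `reasons` (list-column of reason codes, in the fixed order
#'   `child_problem`, `low_distance_va`, `pain_or_discomfort`,
#'   `vision_difficulty`, `near_vision_fail`, `any_eye_problem`). `refer`
#'   is `TRUE` exactly when `reasons` is non-empty.
#' @examples
#' recs <- simulate_participants(n = 20, seed = 1)
#' decide_referrals(recs, iteration = 7)
#' @export
decide_referrals <- function(data, iteration = 7, threshold = "6/12") {
  stopifnot(is.data.frame(data))
  if (!(is.numeric(iteration) && length(iteration) == 1 &&
    iteration %in% 1:7)) {
    stop("`iteration` must be a single integer between 1 and 7", call. = FALSE)
  }
  iteration <- as.integer(iteration)
  validate_participants(data)
  n <- nrow(data)
  spec <- algorithm_catalog()[iteration, ]
  questions <- spec$symptom_questions[[1]]

  child <- data$age_years < 6
  adult <- !child
  adult40 <- data$age_years >= 40

  trig <- matrix(FALSE, nrow = n, ncol = length(referral_reason_codes),
    dimnames = list(NULL, referral_reason_codes))

  # child rule, uniform across iterations: any reported problem refers
  if (any(child)) {
    miss <- child & is.na(data$child_problem)
    if (any(miss)) stop_missing("child_problem", iteration, data$id[miss])
    trig[, "child_problem"] <- child & yes_flag(data$child_problem)
  }

  # distance acuity: mandatory from iteration 3; consulted when present before
  worse_r <- va_worse_than(data$va_right, threshold)
  worse_l <- va_worse_than(data$va_left, threshold)
  if (spec$distance_va_mandatory) {
    for (f in c("va_right", "va_left")) {
      miss <- adult & is.na(data[[f]])
      if (any(miss)) stop_missing(f, iteration, data$id[miss])
    }
  }
  trig[, "low_distance_va"] <- adult &
    ((!is.na(worse_r) & worse_r) | (!is.na(worse_l) & worse_l))

  if ("any_eye_problem" %in% questions) {
    field <- if (identical(spec$problem_question_scope, "today_only")) {
      "problem_today"
    } else {
      "problem_any"
    }
    require_answered(data, field, iteration, adult)
    trig[, "any_eye_problem"] <- adult & yes_flag(data[[field]])
  }
  if ("eye_pain" %in% questions) {
    require_answered(data, "eye_pain", iteration, adult)
    trig[, "pain_or_discomfort"] <- adult & yes_flag(data$eye_pain)
  }
  if ("eye_pain_or_discomfort" %in% questions) {
    require_answered(data, "pain_discomfort", iteration, adult)
    trig[, "pain_or_discomfort"] <- adult & yes_flag(data$pain_discomfort)
  }
  if ("vision_difficulty" %in% questions) {
    require_answered(data, "vision_difficulty", iteration, adult)
    trig[, "vision_difficulty"] <- adult & yes_flag(data$vision_difficulty)
  }
  if (spec$near_vision_required_40plus) {
    miss <- adult40 & is.na(data$near_n8)
    if (any(miss)) stop_missing("near_n8", iteration, data$id[miss])
    trig[, "near_vision_fail"] <- adult40 & fail_flag(data$near_n8)
  }

  reasons <- apply(trig, 1, function(r) referral_reason_codes[r],
    simplify = FALSE)
  out <- dplyr::as_tibble(data)
  out$refer <- rowSums(trig) > 0
  out$reasons <- reasons
  out
}
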