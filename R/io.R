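#' Participant file schema
#'
#' Participant files are comma-separated UTF-8 text with a mandatory
#' header and the token `"NA"` for a not-applicable or unanswered field.
#' Tri-state answers are `yes`/`no`/`NA`; near vision is `pass`/`fail`/`NA`;
#' acuities are Snellen strings; the reference referral is
#' `refer`/`no_refer`/`NA`.
#'
#' @return A tibble with columns `column`, `required`, `values` (a short
#'   description of the admissible values).
#' @export
participant_schema <- function() {
  tibble::tibble(
    column = c(
      "id", "age_years", "sex", "child_problem", "pain_discomfort",
      "vision_difficulty", "va_right", "va_left", "near_n8", "diagnosis",
      "reference_referral", "problem_any", "problem_today", "eye_pain"
    ),
    required = c(rep(TRUE, 11), rep(FALSE, 3)),
    values = c(
      "opaque identifier", "integer >= 0 (rounded up to whole years)",
      "male|female", "yes|no|NA (guardian answer, only for age < 6)",
      "yes|no|NA", "yes|no|NA", "Snellen e.g. 6/12, NA if unassessed",
      "Snellen e.g. 6/12, NA if unassessed",
      "pass|fail|NA (N8 at 33 cm, only for age >= 40)",
      "diagnosis label or NA", "refer|no_refer|NA",
      "yes|no|NA (any eye problem, no time limit)",
      "yes|no|NA (any eye problem today)", "yes|no|NA (eye pain only)"
    )
  )
}

tri_state_cols <- c(
  "child_problem", "pain_discomfort", "vision_difficulty",
  "problem_any", "problem_today", "eye_pain"
)

row_err <- function(rows, msg) {
  stop(sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
    paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
}

#' Validate participant records against the record invariants
#'
#' Enforced invariants: ages are non-negative integers; sex is
#' male/female; the guardian problem question applies only to children
#' under 6 (and is required for them at decision time); distance acuity
#' is never assessed for children under 6; near vision applies only from
#' age 40; every flag takes its admissible values; acuities parse as
#' Snellen. Violations are reported with row numbers. An unassessed adult
#' acuity is accepted here and rejected only when a rule that needs it is
#' applied ([decide_referrals()]).
#'
#' @param data A participant data frame (see [participant_schema()]).
#' @return The data, invisibly.
#' @export
validate_participants <- function(data) {
  stopifnot(is.data.frame(data))
  sch <- participant_schema()
  need <- setdiff(sch$column[sch$required], c("diagnosis", "reference_referral"))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("participant data lacks required column(s): %s",
      paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(data) == 0) {
    return(invisible(data))
  }
  age <- data$age_years
  bad <- which(is.na(age) | age < 0 | age != round(age))
  if (length(bad)) row_err(bad, "age_years must be a non-negative integer")
  bad <- which(!data$sex %in% c("male", "female"))
  if (length(bad)) row_err(bad, "sex must be \"male\" or \"female\"")
  for (col in intersect(tri_state_cols, names(data))) {
    v <- data[[col]]
    bad <- which(!is.na(v) & !v %in% c("yes", "no"))
    if (length(bad)) {
      row_err(bad, sprintf("`%s` must be yes, no or NA", col))
    }
  }
  bad <- which(!is.na(data$near_n8) & !data$near_n8 %in% c("pass", "fail"))
  if (length(bad)) row_err(bad, "`near_n8` must be pass, fail or NA")

  child <- age < 6
  bad <- which(!child & !is.na(data$child_problem))
  if (length(bad)) {
    row_err(bad, "`child_problem` is applicable only to children aged < 6")
  }
  for (col in c("va_right", "va_left")) {
    parse_snellen(data[[col]]) # errors on malformed strings
    bad <- which(child & !is.na(data[[col]]))
    if (length(bad)) {
      row_err(bad, sprintf(
        "`%s` must be NA for children aged < 6 (vision not assessed)", col))
    }
  }
  bad <- which(age < 40 & !is.na(data$near_n8))
  if (length(bad)) {
    row_err(bad, "`near_n8` is applicable only from age 40")
  }
  if ("reference_referral" %in% names(data) &&
    !is.logical(data$reference_referral)) {
    bad <- which(!is.na(data$reference_referral) &
      !data$reference_referral %in% c("refer", "no_refer"))
    if (length(bad)) {
      row_err(bad, "`reference_referral` must be refer, no_refer or NA")
    }
  }
  invisible(data)
}

#' Read a participant file
#'
#' Reads the comma-separated participant format (see
#' [participant_schema()]), validates every row against the record
#' invariants, and returns a tibble with `reference_referral` converted
#' to logical. Schema or invariant violations are reported with row
#' context.
#'
#' @param path Path to a participant CSV file.
#' @return A validated participant tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_participants(simulate_participants(n = 10, seed = 1), f)
#' read_participants(f)
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("participant file not found: %s", path), call. = FALSE)
  }
  data <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "NA", progress = FALSE)
  sch <- participant_schema()
  missing_cols <- setdiff(sch$column[sch$required], names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "header of %s lacks required column(s): %s", path,
      paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  suppressWarnings(age <- as.numeric(data$age_years))
  bad <- which(!is.na(data$age_years) & is.na(age))
  if (length(bad)) row_err(bad, "age_years is not numeric")
  data$age_years <- as.integer(age)
  flags <- intersect(c(tri_state_cols, "near_n8", "sex"), names(data))
  data[flags] <- lapply(data[flags], tolower)
  if ("reference_referral" %in% names(data)) {
    data$reference_referral <- as_decision(data$reference_referral,
      "reference")
  }
  validate_participants(data)
  data
}

#' Write participant records to a file
#'
#' Writes the [participant_schema()] columns (core columns always,
#' optional ones when present) as comma-separated UTF-8 text with `"NA"`
#' for missing values; the output round-trips through
#' [read_participants()] with full equality. Latent simulator columns are
#' not written.
#'
#' @param data A participant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(data, path) {
  validate_participants(data)
  sch <- participant_schema()
  keep <- intersect(sch$column, names(data))
  out <- data[keep]
  if ("reference_referral" %in% keep && is.logical(out$reference_referral)) {
    out$reference_referral <- dplyr::if_else(out$reference_referral,
      "refer", "no_refer")
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
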