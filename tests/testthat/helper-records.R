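# a small, fully explicit participant table covering the rule branches
manual_records <- function() {
  tibble::tibble(
    id = sprintf("M%02d", 1:8),
    age_years = c(4L, 4L, 30L, 45L, 25L, 70L, 50L, 10L),
    sex = c("male", "female", "male", "female", "male", "female",
      "male", "female"),
    child_problem = c("yes", "no", NA, NA, NA, NA, NA, NA),
    problem_any = c(NA, NA, "no", "no", "no", "yes", "no", "no"),
    problem_today = c(NA, NA, "no", "no", "no", "yes", "no", "no"),
    eye_pain = c(NA, NA, "no", "no", "no", "no", "no", "no"),
    pain_discomfort = c(NA, NA, "no", "no", "no", "yes", "no", "no"),
    vision_difficulty = c(NA, NA, "no", "no", "no", "no", "no", "yes"),
    va_right = c(NA, NA, "6/6", "6/6", "6/18", "6/60", "6/6", "6/6"),
    va_left = c(NA, NA, "6/6", "6/6", "6/6", "6/36", "6/12", "6/6"),
    near_n8 = c(NA, NA, NA, "fail", NA, "pass", "pass", NA),
    diagnosis = c("other", "normal", "normal", "presbyopia", "refractive_error",
      "allergic_conjunctivitis", "normal", "refractive_error"),
    reference_referral = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
}

random_acuities <- function(n) {
  chart <- snellen_chart()
  chart$snellen[sample.int(nrow(chart), n, replace = TRUE)]
}
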