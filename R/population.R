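#' Generative model for a synthetic community screening population
#'
#' The default model reproduces the statistical structure of the
#' final-iteration validation cohort: the printed age-group and sex
#' margins (n = 574), the diagnosis mix of the reference-referred
#' participants plus a `normal` group sized so that the expected
#' referable prevalence is 378/574 = 65.9%, and symptom/acuity/near-vision
#' generation consistent with those margins. Screener-observed answers are
#' derived from the latent reference answers through a measurement-error
#' model (`cv_noise`): each elicited answer flips independently with a
#' small probability and the measured acuity is jittered on the logMAR
#' scale and snapped back to the nearest chart line.
#'
#' The per-diagnosis symptom and acuity probabilities are calibration
#' targets chosen for plausibility (conjunctivitis is symptom-driven with
#' normal acuity, cataract and refractive error are acuity-driven,
#' presbyopia fails near vision), not estimates of any real population's
#' epidemiology: the joint distribution of symptoms and diagnoses is not
#' published. Age, sex and diagnosis are drawn independently from their
#' margins for the same reason.
#'
#' @param referable_prevalence Expected proportion of reference-referable
#'   participants; the `normal` share of the diagnosis mix is set to
#'   `1 - referable_prevalence`. Default 378/574.
#' @param symptom_flip Probability a screener-elicited tri-state answer
#'   differs from the latent reference answer; default 0.03.
#' @param acuity_sd Test-retest noise of the measured acuity on the logMAR
#'   scale; default 0.05 (about half a chart line).
#' @param reference_from_rule If `TRUE`, the reference referral decision
#'   is not drawn from `referable_given_diagnosis` but computed by
#'   applying the final (iteration-7) rule to the latent noise-free
#'   fields, making reference and index definitions decision-consistent
#'   (with zero noise, sensitivity = specificity = 1 by construction).
#' @return An object of class `"population_model"`: a list with elements
#'   `age_groups` (tibble: `group`, `lo`, `hi`, `weight`), `sex_split_female`,
#'   `diagnosis` (tibble: `diagnosis`, `weight`, `referable`,
#'   `p_pain_discomfort`, `p_vision_difficulty`, `p_band_normal`,
#'   `p_band_impaired`, `p_band_severe`, `p_near_fail`),
#'   `p_pain_is_painful`, `p_problem_history`, `p_child_problem`,
#'   `cv_noise` and `reference_from_rule`.
#' @examples
#' m <- default_population_model()
#' m$age_groups
#' @export
default_population_model <- function(referable_prevalence = 378 / 574,
                                     symptom_flip = 0.03,
                                     acuity_sd = 0.05,
                                     reference_from_rule = FALSE) {
  stopifnot(referable_prevalence > 0, referable_prevalence < 1)
  age_groups <- tibble::tibble(
    group = c("<15", "15-29", "30-44", "45-59", "60-74", "75+"),
    lo = c(0L, 15L, 30L, 45L, 60L, 75L),
    hi = c(14L, 29L, 44L, 59L, 74L, 90L),
    weight = c(252, 100, 80, 76, 52, 14) / 574
  )
  # reference-referred diagnosis counts, scaled to the referable share
  ref_counts <- c(
    cataract = 29, presbyopia = 58, glaucoma = 2, refractive_error = 66,
    allergic_conjunctivitis = 133, other_conjunctivitis = 53,
    corneal_disease = 2, retinal_disease = 5, eye_injury_foreign_body = 1,
    uveitis = 1, pterygium_conjunctival_swelling = 10,
    chalazion_lid_swelling = 2, other = 16
  )
  diagnosis <- tibble::tibble(
    diagnosis = c(names(ref_counts), "normal"),
    weight = c(
      referable_prevalence * ref_counts / sum(ref_counts),
      1 - referable_prevalence
    ),
    referable = c(rep(1, length(ref_counts)), 0),
    p_pain_discomfort = c(
      0.10, 0.10, 0.20, 0.05, 0.85, 0.80, 0.70, 0.10, 0.90, 0.90,
      0.60, 0.70, 0.50, 0.06
    ),
    p_vision_difficulty = c(
      0.90, 0.80, 0.70, 0.85, 0.20, 0.20, 0.60, 0.90, 0.30, 0.60,
      0.30, 0.10, 0.50, 0.06
    ),
    p_band_normal = c(
      0.20, 0.90, 0.30, 0.35, 0.95, 0.95, 0.30, 0.20, 0.60, 0.40,
      0.90, 1.00, 0.70, 0.98
    ),
    p_band_impaired = c(
      0.50, 0.10, 0.40, 0.60, 0.05, 0.05, 0.50, 0.50, 0.30, 0.40,
      0.10, 0.00, 0.25, 0.02
    ),
    p_near_fail = c(
      0.30, 0.95, 0.20, 0.30, 0.15, 0.15, 0.20, 0.30, 0.15, 0.20,
      0.15, 0.10, 0.20, 0.02
    )
  )
  diagnosis$p_band_severe <-
    1 - diagnosis$p_band_normal - diagnosis$p_band_impaired
  model <- structure(list(
    age_groups = age_groups,
    sex_split_female = 361 / 574,
    diagnosis = diagnosis,
    p_pain_is_painful = 0.5,
    p_problem_history = c(referable = 0.30, normal = 0.08),
    p_child_problem = c(referable = 0.90, normal = 0.05),
    cv_noise = list(symptom_flip = symptom_flip, acuity_sd = acuity_sd),
    reference_from_rule = reference_from_rule
  ), class = "population_model")
  validate_population_model(model)
  model
}

#' Validate a population model
#'
#' Checks that every weight vector sums to 1 (within 1e-9) and that every
#' probability lies in \[0, 1\]; called before any sampling.
#'
#' @param model A `"population_model"` object.
#' @return The model, invisibly; errors describe the violated invariant.
#' @export
validate_population_model <- function(model) {
  if (!inherits(model, "population_model")) {
    stop("expected a `population_model` object", call. = FALSE)
  }
  check_sum1 <- function(w, what) {
    if (abs(sum(w) - 1) > 1e-9) {
      stop(sprintf("%s weights sum to %.12f, not 1", what, sum(w)),
        call. = FALSE)
    }
  }
  check_sum1(model$age_groups$weight, "age group")
  check_sum1(model$diagnosis$weight, "diagnosis mix")
  d <- model$diagnosis
  probs <- c(
    model$sex_split_female, d$referable, d$p_pain_discomfort,
    d$p_vision_difficulty, d$p_band_normal, d$p_band_impaired,
    d$p_band_severe, d$p_near_fail, model$p_pain_is_painful,
    model$p_problem_history, model$p_child_problem,
    model$cv_noise$symptom_flip
  )
  if (any(probs < -1e-12 | probs > 1 + 1e-12)) {
    stop("population model contains a probability outside [0, 1]",
      call. = FALSE)
  }
  band_sum <- d$p_band_normal + d$p_band_impaired + d$p_band_severe
  if (any(abs(band_sum - 1) > 1e-9)) {
    stop("per-diagnosis acuity band probabilities must sum to 1",
      call. = FALSE)
  }
  if (model$cv_noise$acuity_sd < 0) {
    stop("acuity noise standard deviation must be non-negative",
      call. = FALSE)
  }
  invisible(model)
}

#' Expected referable prevalence of a population model
#'
#' @param model A `"population_model"` object.
#' @return `sum(diagnosis weight * referable probability)`.
#' @export
expected_prevalence <- function(model = default_population_model()) {
  validate_population_model(model)
  sum(model$diagnosis$weight * model$diagnosis$referable)
}

flip_yes_no <- function(x, p) {
  flip <- !is.na(x) & stats::runif(length(x)) < p
  dplyr::if_else(flip, dplyr::if_else(x == "yes", "no", "yes"), x)
}

yn <- function(bool) dplyr::if_else(bool, "yes", "no")

#' Simulate a synthetic screening population
#'
#' Draws `n` participant records from a [default_population_model()] (or
#' any valid population model), retaining the latent truth alongside the
#' screener-observed fields. A single seed governs a single random stream:
#' identical seeds give identical output.
#'
#' The generative process per record: age group, sex and diagnosis are
#' drawn from the model margins (ages uniform integers within group);
#' the latent referable flag, symptom answers, per-eye acuity band and
#' chart line, and near-vision result (ages 40+) are drawn conditionally
#' on diagnosis; children under 6 get no acuity, near-vision, or adult
#' symptom answers, only the guardian-reported problem flag; the reference
#' referral comes from the latent referable flag (or from the iteration-7
#' rule on latent fields when `reference_from_rule` is set); finally the
#' screener-observed columns are the latent answers passed through the
#' `cv_noise` measurement-error model.
#'
#' @param n Number of records (`n >= 0`).
#' @param seed Integer seed; required, part of the reproducibility
#'   contract.
#' @param model A `"population_model"`; default [default_population_model()].
#' @return A tibble with the [participant_schema()] columns (including the
#'   optional `problem_any`, `problem_today`, `eye_pain`), plus
#'   `latent_referable` and `latent_`-prefixed copies of every elicited
#'   field before measurement error.
#' @examples
#' simulate_participants(n = 5, seed = 42)
#' @export
simulate_participants <- function(n, seed, model = default_population_model()) {
  stopifnot(length(n) == 1, n >= 0, n == round(n))
  validate_population_model(model)
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    ag <- model$age_groups
    gi <- sample.int(nrow(ag), n, replace = TRUE, prob = ag$weight)
    age <- ag$lo[gi] +
      floor(stats::runif(n) * (ag$hi[gi] - ag$lo[gi] + 1L))
    sex <- dplyr::if_else(stats::runif(n) < model$sex_split_female,
      "female", "male")
    dg <- model$diagnosis
    di <- sample.int(nrow(dg), n, replace = TRUE, prob = dg$weight)
    diagnosis <- dg$diagnosis[di]
    referable <- stats::runif(n) < dg$referable[di]

    child <- age < 6
    adult <- !child

    pain_disc <- adult & stats::runif(n) < dg$p_pain_discomfort[di]
    pain <- pain_disc & stats::runif(n) < model$p_pain_is_painful
    visdiff <- adult & stats::runif(n) < dg$p_vision_difficulty[di]
    p_hist <- unname(model$p_problem_history[
      dplyr::if_else(referable, "referable", "normal")])
    prob_today <- pain_disc | visdiff
    prob_any <- prob_today | (adult & stats::runif(n) < p_hist)

    chart <- snellen_chart()
    draw_eye <- function() {
      u <- stats::runif(n)
      band <- dplyr::case_when(
        u < dg$p_band_normal[di] ~ "normal_6_6_to_6_12",
        u < dg$p_band_normal[di] + dg$p_band_impaired[di] ~
          "impaired_6_18_to_6_60",
        TRUE ~ "severe_below_6_60"
      )
      vapply(band, function(b) {
        lines <- chart$snellen[chart$band == b]
        lines[sample.int(length(lines), 1)]
      }, character(1), USE.NAMES = FALSE)
    }
    va_r <- dplyr::if_else(adult, draw_eye(), NA_character_)
    va_l <- dplyr::if_else(adult, draw_eye(), NA_character_)

    near_applicable <- age >= 40
    near <- dplyr::if_else(
      near_applicable,
      dplyr::if_else(stats::runif(n) < dg$p_near_fail[di], "fail", "pass"),
      NA_character_
    )
    p_cp <- unname(model$p_child_problem[
      dplyr::if_else(referable, "referable", "normal")])
    child_prob <- dplyr::if_else(child,
      yn(stats::runif(n) < p_cp), NA_character_)

    latent <- tibble::tibble(
      id = sprintf("P%05d", seq_len(n)),
      age_years = as.integer(age),
      sex = sex,
      child_problem = child_prob,
      problem_any = dplyr::if_else(adult, yn(prob_any), NA_character_),
      problem_today = dplyr::if_else(adult, yn(prob_today), NA_character_),
      eye_pain = dplyr::if_else(adult, yn(pain), NA_character_),
      pain_discomfort = dplyr::if_else(adult, yn(pain_disc), NA_character_),
      vision_difficulty = dplyr::if_else(adult, yn(visdiff), NA_character_),
      va_right = va_r,
      va_left = va_l,
      near_n8 = near,
      diagnosis = diagnosis
    )

    if (model$reference_from_rule) {
      ref <- if (n > 0) {
        decide_referrals(latent, iteration = 7)$refer
      } else {
        logical(0)
      }
    } else {
      ref <- referable
    }

    noise <- model$cv_noise
    flip <- noise$symptom_flip
    jitter_va <- function(v) {
      p <- parse_snellen(v)
      noisy <- p$logmar + stats::rnorm(n, 0, noise$acuity_sd)
      snapped <- vapply(noisy, function(lm) {
        if (is.na(lm)) NA_character_ else {
          chart$snellen[which.min(abs(chart$logmar - lm))]
        }
      }, character(1))
      snapped
    }
    observed <- latent |>
      dplyr::mutate(
        child_problem = flip_yes_no(.data$child_problem, flip),
        problem_any = flip_yes_no(.data$problem_any, flip),
        problem_today = flip_yes_no(.data$problem_today, flip),
        eye_pain = flip_yes_no(.data$eye_pain, flip),
        pain_discomfort = flip_yes_no(.data$pain_discomfort, flip),
        vision_difficulty = flip_yes_no(.data$vision_difficulty, flip),
        near_n8 = {
          f <- !is.na(.data$near_n8) & stats::runif(n) < flip
          dplyr::if_else(f,
            dplyr::if_else(.data$near_n8 == "fail", "pass", "fail"),
            .data$near_n8)
        },
        va_right = jitter_va(.data$va_right),
        va_left = jitter_va(.data$va_left)
      )

    out <- observed |>
      dplyr::mutate(
        reference_referral = ref,
        latent_referable = referable,
        latent_child_problem = latent$child_problem,
        latent_problem_any = latent$problem_any,
        latent_problem_today = latent$problem_today,
        latent_eye_pain = latent$eye_pain,
        latent_pain_discomfort = latent$pain_discomfort,
        latent_vision_difficulty = latent$vision_difficulty,
        latent_va_right = latent$va_right,
        latent_va_left = latent$va_left,
        latent_near_n8 = latent$near_n8
      )
    validate_participants(out)
    out
  })
}
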