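#' Validate one algorithm iteration against the reference standard
#'
#' Computes index decisions from the screener-observed fields with
#' [decide_referrals()], cross-tabulates them against the reference
#' referral, and summarises accuracy with exact intervals. Records with a
#' missing reference decision are excluded and accounted for in the flow
#' (never silently dropped); a record missing a field the iteration makes
#' mandatory is an error.
#'
#' @param records Participant tibble including `reference_referral`.
#' @param iteration Integer 1-7; default 7.
#' @param level Confidence level; default 0.95.
#' @param threshold Snellen referral threshold; default `"6/12"`.
#' @return An object of class `"iteration_eval"`: a list with `iteration`,
#'   `confusion` ([confusion_table()]), `metrics` (the
#'   [accuracy_summary()] tibble), `flow` (a [screening_flow()] tibble)
#'   and `level`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' recs <- simulate_participants(n = 300, seed = 11)
#' evaluate_iteration(recs, iteration = 7)
#' @export
evaluate_iteration <- function(records, iteration = 7, level = 0.95,
                               threshold = "6/12") {
  stopifnot(is.data.frame(records))
  if (!"reference_referral" %in% names(records)) {
    stop("records lack a `reference_referral` column", call. = FALSE)
  }
  fl <- screening_flow(records, iteration = iteration)
  keep <- !is.na(records$reference_referral) &
    !index_incomplete(records, iteration)
  analyzed <- records[keep, , drop = FALSE]
  decided <- decide_referrals(analyzed, iteration = iteration,
    threshold = threshold)
  conf <- build_confusion(decided$refer, decided$reference_referral)
  structure(list(
    iteration = as.integer(iteration),
    confusion = conf,
    metrics = accuracy_summary(conf, level = level),
    flow = fl,
    level = level
  ), class = "iteration_eval")
}

#' @export
print.iteration_eval <- function(x, ...) {
  cat(sprintf("Iteration %d validation (n = %d analyzed of %d eligible)\n",
    x$iteration, x$flow$analyzed, x$flow$eligible))
  cat(sprintf("  2x2: tp=%d fn=%d fp=%d tn=%d\n",
    x$confusion$tp, x$confusion$fn, x$confusion$fp, x$confusion$tn))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$defined[i]) {
      cat(sprintf("  %-11s %5.1f%% (%.1f-%.1f)\n", m$metric[i],
        100 * m$estimate[i], 100 * m$ci_low[i], 100 * m$ci_high[i]))
    } else {
      cat(sprintf("  %-11s undefined (denominator 0)\n", m$metric[i]))
    }
  }
  invisible(x)
}

#' @rdname evaluate_iteration
#' @param x An `"iteration_eval"` object.
#' @param ... Unused.
#' @method tidy iteration_eval
#' @export
tidy.iteration_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, iteration = x$iteration, .before = 1)
}

#' @rdname evaluate_iteration
#' @method glance iteration_eval
#' @export
glance.iteration_eval <- function(x, ...) {
  m <- x$metrics
  est <- stats::setNames(m$estimate, m$metric)
  tibble::tibble(
    iteration = x$iteration,
    n = x$confusion$tp + x$confusion$fn + x$confusion$fp + x$confusion$tn,
    prevalence = (x$confusion$tp + x$confusion$fn) /
      (x$confusion$tp + x$confusion$fn + x$confusion$fp + x$confusion$tn),
    sensitivity = est[["sensitivity"]],
    specificity = est[["specificity"]],
    ppv = est[["ppv"]],
    npv = est[["npv"]]
  )
}

#' @rdname evaluate_iteration
#' @param object An `"iteration_eval"` object.
#' @method autoplot iteration_eval
#' @export
autoplot.iteration_eval <- function(object, ...) {
  m <- dplyr::filter(object$metrics, .data$defined)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
      limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Iteration %d accuracy", object$iteration),
      x = NULL,
      y = sprintf("estimate (%d%% exact CI)", round(100 * object$level))
    ) +
    ggplot2::theme_minimal()
}

strategy_names <- c(
  "full_algorithm", "va_only", "symptoms_only", "age40_or_symptoms"
)

strategy_decision <- function(records, strategy, iteration = 7,
                              threshold = "6/12") {
  child <- records$age_years < 6
  child_yes <- child & yes_flag(records$child_problem)
  adult <- !child
  if (strategy == "full_algorithm") {
    return(decide_referrals(records, iteration = iteration,
      threshold = threshold)$refer)
  }
  worse <- function() {
    wr <- va_worse_than(records$va_right, threshold)
    wl <- va_worse_than(records$va_left, threshold)
    adult & ((!is.na(wr) & wr) | (!is.na(wl) & wl))
  }
  res <- switch(strategy,
    va_only = worse() |
      (records$age_years >= 40 & fail_flag(records$near_n8)),
    symptoms_only = adult & (yes_flag(records$pain_discomfort) |
      yes_flag(records$vision_difficulty)),
    age40_or_symptoms = (adult & records$age_years >= 40) |
      (adult & (yes_flag(records$pain_discomfort) |
        yes_flag(records$vision_difficulty))),
    stop(sprintf("unknown strategy %s; available: %s", sQuote(strategy),
      paste(strategy_names, collapse = ", ")), call. = FALSE)
  )
  # children are not addressed by the counterfactual strategies; the
  # guardian-report rule applies throughout
  res | child_yes
}

#' Compare counterfactual referral strategies
#'
#' Recomputes accuracy under alternative referral strategies on the same
#' records: `full_algorithm` (the selected iteration's rule), `va_only`
#' (refer only on distance acuity or, for 40+, near-vision failure, with
#' no questions), `symptoms_only` (refer only on reported pain/discomfort
#' or vision difficulty, with no examinations), and `age40_or_symptoms`
#' (refer everyone aged 40+ irrespective of acuity or symptoms, plus
#' under-40s reporting either symptom). Children under 6 are decided by
#' the guardian-reported problem flag under every strategy.
#'
#' @param records Participant tibble including `reference_referral`.
#' @param strategies Character vector of strategy names; default all four.
#' @param iteration Iteration used by `full_algorithm`; default 7.
#' @param level Confidence level; default 0.95.
#' @param threshold Snellen referral threshold; default `"6/12"`.
#' @return A tibble of class `"strategy_comparison"`: one row per strategy
#'   with the 2x2 counts and `sensitivity`, `specificity`, `ppv`, `npv`
#'   with `_low`/`_high` exact bounds.
#' @examples
#' recs <- simulate_participants(n = 500, seed = 3)
#' compare_strategies(recs)
#' @export
compare_strategies <- function(records, strategies = strategy_names,
                               iteration = 7, level = 0.95,
                               threshold = "6/12") {
  stopifnot(is.data.frame(records))
  validate_participants(records)
  analyzed <- records[!is.na(records$reference_referral), , drop = FALSE]
  rows <- purrr::map(strategies, function(s) {
    dec <- strategy_decision(analyzed, s, iteration = iteration,
      threshold = threshold)
    conf <- build_confusion(dec, analyzed$reference_referral)
    m <- accuracy_summary(conf, level = level)
    wide <- stats::setNames(
      as.list(c(m$estimate, m$ci_low, m$ci_high)),
      c(m$metric, paste0(m$metric, "_low"), paste0(m$metric, "_high"))
    )
    dplyr::bind_cols(tibble::tibble(strategy = s), conf, wide)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("strategy_comparison", class(out))
  out
}

#' @rdname compare_strategies
#' @param object A `"strategy_comparison"` tibble.
#' @param ... Unused.
#' @method autoplot strategy_comparison
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      cols = c("sensitivity", "specificity"),
      names_to = "metric", values_to = "estimate"
    ) |>
    dplyr::mutate(
      low = dplyr::if_else(.data$metric == "sensitivity",
        .data$sensitivity_low, .data$specificity_low),
      high = dplyr::if_else(.data$metric == "sensitivity",
        .data$sensitivity_high, .data$specificity_high)
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$strategy, y = .data$estimate, colour = .data$metric)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$low, ymax = .data$high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
      limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "estimate (exact CI)",
      title = "Referral strategies compared") +
    ggplot2::theme_minimal()
}

#' Participant-flow accounting
#'
#' Diagnostic-accuracy reporting (STARD) requires stating how many
#' eligible participants were excluded before analysis. A record is
#' incomplete if it lacks the reference referral or any field the
#' selected iteration makes mandatory (both acuities for ages 6+ when
#' acuity testing is mandatory, the iteration's symptom answers, near
#' vision for 40+ at iteration 7, the guardian answer for children).
#'
#' @param records Participant tibble (raw, possibly incomplete).
#' @param iteration Iteration whose completeness requirements apply;
#'   default 7.
#' @return One-row tibble: `eligible`, `excluded_incomplete`, `analyzed`
#'   (`analyzed = eligible - excluded_incomplete`).
#' @examples
#' recs <- simulate_participants(n = 50, seed = 2)
#' screening_flow(recs)
#' @export
screening_flow <- function(records, iteration = 7) {
  stopifnot(is.data.frame(records))
  validate_participants(records)
  n <- nrow(records)
  if (n == 0) {
    return(tibble::tibble(eligible = 0L, excluded_incomplete = 0L,
      analyzed = 0L))
  }
  ref_missing <- if ("reference_referral" %in% names(records)) {
    is.na(records$reference_referral)
  } else {
    rep(TRUE, n)
  }
  excluded <- sum(ref_missing | index_incomplete(records, iteration))
  tibble::tibble(
    eligible = n,
    excluded_incomplete = as.integer(excluded),
    analyzed = as.integer(n - excluded)
  )
}

# vectorized completeness check mirroring decide_referrals' mandatory-field
# requirements; an absent optional column counts as missing for all adults
index_incomplete <- function(records, iteration) {
  spec <- algorithm_catalog()[iteration, ]
  questions <- spec$symptom_questions[[1]]
  n <- nrow(records)
  child <- records$age_years < 6
  adult <- !child
  miss_col <- function(col) {
    if (col %in% names(records)) is.na(records[[col]]) else rep(TRUE, n)
  }
  inc <- child & is.na(records$child_problem)
  if (spec$distance_va_mandatory) {
    inc <- inc | (adult & (is.na(records$va_right) | is.na(records$va_left)))
  }
  if ("any_eye_problem" %in% questions) {
    field <- if (identical(spec$problem_question_scope, "today_only")) {
      "problem_today"
    } else {
      "problem_any"
    }
    inc <- inc | (adult & miss_col(field))
  }
  if ("eye_pain" %in% questions) inc <- inc | (adult & miss_col("eye_pain"))
  if ("eye_pain_or_discomfort" %in% questions) {
    inc <- inc | (adult & miss_col("pain_discomfort"))
  }
  if ("vision_difficulty" %in% questions) {
    inc <- inc | (adult & miss_col("vision_difficulty"))
  }
  if (spec$near_vision_required_40plus) {
    inc <- inc | (records$age_years >= 40 & is.na(records$near_n8))
  }
  inc
}

#' Flow accounting from printed totals
#'
#' @param eligible Number of eligible participants.
#' @param excluded_incomplete Number excluded for incomplete index or
#'   reference data.
#' @return One-row tibble: `eligible`, `excluded_incomplete`, `analyzed`.
#' @examples
#' flow_from_totals(607, 33)
#' @export
flow_from_totals <- function(eligible, excluded_incomplete) {
  stopifnot(eligible >= 0, excluded_incomplete >= 0,
    excluded_incomplete <= eligible)
  tibble::tibble(
    eligible = as.integer(eligible),
    excluded_incomplete = as.integer(excluded_incomplete),
    analyzed = as.integer(eligible - excluded_incomplete)
  )
}
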