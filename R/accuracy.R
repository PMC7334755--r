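#' Construct a 2x2 referral confusion table
#'
#' Cross-classifies index (screener) against reference (clinician)
#' referral decisions. Orientation is fixed: `tp` = both refer, `fn` =
#' reference refers but index does not, `fp` = index refers but reference
#' does not, `tn` = neither refers.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A one-row tibble of class `"confusion"` with columns `tp`,
#'   `fn`, `fp`, `tn`.
#' @examples
#' confusion_table(344, 34, 43, 153)
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  out <- tibble::tibble(
    tp = as.integer(tp), fn = as.integer(fn),
    fp = as.integer(fp), tn = as.integer(tn)
  )
  class(out) <- c("confusion", class(out))
  out
}

#' Cross-tabulate index vs reference decisions
#'
#' @param index,reference Logical vectors (or `"refer"`/`"no_refer"`
#'   character) of equal length, with no missing values.
#' @return A [confusion_table()].
#' @examples
#' build_confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
build_confusion <- function(index, reference) {
  index <- as_decision(index, "index")
  reference <- as_decision(reference, "reference")
  if (length(index) != length(reference)) {
    stop(sprintf(
      "index (%d) and reference (%d) decision vectors differ in length",
      length(index), length(reference)
    ), call. = FALSE)
  }
  na_at <- which(is.na(index) | is.na(reference))
  if (length(na_at) > 0) {
    stop(sprintf(
      "missing decision at record position(s): %s",
      paste(utils::head(na_at, 5), collapse = ", ")
    ), call. = FALSE)
  }
  confusion_table(
    tp = sum(index & reference),
    fn = sum(!index & reference),
    fp = sum(index & !reference),
    tn = sum(!index & !reference)
  )
}

as_decision <- function(x, what) {
  if (is.logical(x)) {
    return(x)
  }
  if (is.character(x) || is.factor(x)) {
    x <- tolower(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("refer", "yes", "true", "1")] <- TRUE
    out[x %in% c("no_refer", "do_not_refer", "no", "false", "0")] <- FALSE
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop(sprintf(
        "unrecognized %s decision value(s): %s", what,
        paste(unique(sQuote(x[bad])), collapse = ", ")
      ), call. = FALSE)
    }
    return(out)
  }
  stop(sprintf("%s decisions must be logical or refer/no_refer labels", what),
    call. = FALSE)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities via the beta-quantile identity:
#' `low = qbeta(alpha/2, k, n - k + 1)` and
#' `high = qbeta(1 - alpha/2, k + 1, n - k)`, with the degenerate
#' endpoints `low = 0` at `k = 0` and `high = 1` at `k = n`. This is the
#' interval that reproduces the study's printed bounds (e.g. 87.7-93.7%
#' for 344/378), where a large-sample Wilson interval would not.
#'
#' @param k Number of successes, `0 <= k <= n` (vectorized).
#' @param n Number of trials, `n >= 1` (vectorized).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `low`, `high`, one row per `k`.
#' @examples
#' exact_binomial_ci(344, 378)
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly between 0 and 1",
      call. = FALSE)
  }
  if (any(is.na(k)) || any(is.na(n)) || any(n < 1) || any(k < 0) ||
    any(k > n) || any(k != round(k)) || any(n != round(n))) {
    stop("`k` and `n` must be integers with 0 <= k <= n and n >= 1",
      call. = FALSE)
  }
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(low = low, high = high)
}

#' Proportion with exact confidence interval
#'
#' @inheritParams exact_binomial_ci
#' @return One-row tibble: `numerator`, `denominator`, `point`, `ci_low`,
#'   `ci_high`, `level`.
#' @export
proportion_estimate <- function(k, n, level = 0.95) {
  ci <- exact_binomial_ci(k, n, level)
  tibble::tibble(
    numerator = as.integer(k), denominator = as.integer(n),
    point = k / n, ci_low = ci$low, ci_high = ci$high, level = level
  )
}

#' Sensitivity, specificity and predictive values of a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(fn+tn)`, each
#' with a Clopper-Pearson interval. A metric whose denominator is zero is
#' flagged undefined (`defined = FALSE`, `NA` estimates) rather than
#' fabricated.
#'
#' @param x A [confusion_table()] (or any one-row data frame with columns
#'   `tp`, `fn`, `fp`, `tn`).
#' @param level Confidence level; default 0.95.
#' @return A tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `ci_low`, `ci_high`, `defined`.
#' @examples
#' accuracy_summary(confusion_table(344, 34, 43, 153))
#' @export
accuracy_summary <- function(x, level = 0.95) {
  x <- check_confusion(x)
  num <- c(
    sensitivity = x$tp, specificity = x$tn,
    ppv = x$tp, npv = x$tn
  )
  den <- c(
    sensitivity = x$tp + x$fn, specificity = x$fp + x$tn,
    ppv = x$tp + x$fp, npv = x$fn + x$tn
  )
  out <- tibble::tibble(
    metric = names(num),
    numerator = as.integer(num),
    denominator = as.integer(den),
    estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    defined = den > 0
  )
  ok <- out$defined
  if (any(ok)) {
    ci <- exact_binomial_ci(num[ok], den[ok], level)
    out$estimate[ok] <- num[ok] / den[ok]
    out$ci_low[ok] <- ci$low
    out$ci_high[ok] <- ci$high
  }
  out
}

check_confusion <- function(x) {
  if (!is.data.frame(x) || nrow(x) != 1 ||
    !all(c("tp", "fn", "fp", "tn") %in% names(x))) {
    stop("expected a one-row confusion table with columns tp, fn, fp, tn",
      call. = FALSE)
  }
  x
}

#' Observed percent agreement of a 2x2 table
#'
#' @inheritParams accuracy_summary
#' @return Proportion `(tp + tn) / N`.
#' @export
percent_agreement <- function(x) {
  x <- check_confusion(x)
  n <- x$tp + x$fn + x$fp + x$tn
  if (n == 0) stop("empty table: agreement undefined", call. = FALSE)
  (x$tp + x$tn) / n
}

#' Cohen's kappa for interrater agreement on referral decisions
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` where `po`
#' is the observed agreement and `pe` the marginal-product chance
#' agreement. Bands follow the study's reporting scheme: 0.41-0.60
#' moderate, 0.61-0.80 fair, 0.81 or more good (values below 0.41 are
#' labelled poor). Degenerate marginals with `pe = 1` leave kappa
#' undefined and flagged.
#'
#' @inheritParams accuracy_summary
#' @return One-row tibble: `observed_agreement`, `expected_agreement`,
#'   `kappa`, `band`, `defined`.
#' @examples
#' cohen_kappa(confusion_table(42, 2, 7, 8))
#' @export
cohen_kappa <- function(x) {
  x <- check_confusion(x)
  n <- x$tp + x$fn + x$fp + x$tn
  if (n == 0) stop("empty table: kappa undefined", call. = FALSE)
  po <- (x$tp + x$tn) / n
  pe <- ((x$tp + x$fn) * (x$tp + x$fp) + (x$fp + x$tn) * (x$fn + x$tn)) / n^2
  if (pe >= 1) {
    return(tibble::tibble(
      observed_agreement = po, expected_agreement = pe,
      kappa = NA_real_, band = NA_character_, defined = FALSE
    ))
  }
  kappa <- (po - pe) / (1 - pe)
  tibble::tibble(
    observed_agreement = po, expected_agreement = pe,
    kappa = kappa, band = kappa_band(kappa), defined = TRUE
  )
}

kappa_band <- function(kappa) {
  dplyr::case_when(
    kappa >= 0.81 ~ "good",
    kappa >= 0.61 ~ "fair",
    kappa >= 0.41 ~ "moderate",
    TRUE ~ "poor"
  )
}

#' Reconstruct a 2x2 table from published marginals and agreement
#'
#' Agreement studies often print only the two raters' positive counts and
#' the percent agreement. Those three numbers and the total determine the
#' full 2x2 uniquely: with concordant count `c = round(agreement * n)`,
#' the both-positive cell is `a = (a_pos + b_pos - (n - c)) / 2`, and the
#' remaining cells follow from the marginals. Inconsistent inputs (a
#' non-integer or negative cell) raise an error naming the violated
#' constraint.
#'
#' @param n Total number of rated subjects.
#' @param rater_a_pos,rater_b_pos Positive counts for raters A and B.
#' @param agreement Observed proportion of concordant decisions in (0, 1].
#' @return A [confusion_table()] with `tp` = both positive and rater A on
#'   the reference margin.
#' @examples
#' reconstruct_2x2(59, 44, 49, 0.848)
#' @export
reconstruct_2x2 <- function(n, rater_a_pos, rater_b_pos, agreement) {
  stopifnot(n >= 1, rater_a_pos >= 0, rater_b_pos >= 0)
  if (rater_a_pos > n || rater_b_pos > n) {
    stop("rater positive counts cannot exceed the total n", call. = FALSE)
  }
  if (agreement < 0 || agreement > 1) {
    stop("`agreement` must be a proportion in [0, 1]", call. = FALSE)
  }
  concordant <- round(agreement * n)
  a2 <- rater_a_pos + rater_b_pos - (n - concordant)
  if (a2 %% 2 != 0) {
    stop(sprintf(
      paste0(
        "inconsistent marginals: a_pos + b_pos - discordant = %d ",
        "is odd, so no integer both-positive cell exists"
      ), a2
    ), call. = FALSE)
  }
  tp <- a2 / 2
  fn <- rater_a_pos - tp
  fp <- rater_b_pos - tp
  tn <- n - tp - fn - fp
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) {
    bad <- names(cells)[cells < 0][1]
    stop(sprintf(
      "inconsistent marginals/agreement: reconstructed cell `%s` = %d is negative",
      bad, cells[[bad]]
    ), call. = FALSE)
  }
  confusion_table(tp, fn, fp, tn)
}

#' Sample size for estimating sensitivity to a given precision
#'
#' Buderer's method: the required number of reference-positive cases is
#' `ceil(z^2 * s * (1 - s) / d^2)` for anticipated sensitivity `s` and
#' half-width `d`, and the total sample is `ceil(cases / prevalence)`.
#' The achieved half-width for a given case count is also reported, so a
#' published design can be checked against its stated precision.
#'
#' @param target_sens Anticipated sensitivity, in (0, 1).
#' @param half_width Desired confidence-interval half-width, in (0, 1).
#' @param prevalence Anticipated proportion of reference-positive
#'   participants, in (0, 1).
#' @param level Confidence level; default 0.95.
#' @return One-row tibble: `cases`, `n`, `achieved_half_width` (the
#'   half-width the returned case count actually delivers).
#' @examples
#' sample_size_sensitivity(0.90, 0.05, 0.30)
#' @export
sample_size_sensitivity <- function(target_sens, half_width, prevalence,
                                    level = 0.95) {
  args <- c(target_sens = target_sens, half_width = half_width,
    prevalence = prevalence, level = level)
  if (any(!is.finite(args)) || any(args <= 0) || any(args >= 1)) {
    stop("all arguments must lie strictly between 0 and 1", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cases <- ceiling(z^2 * target_sens * (1 - target_sens) / half_width^2)
  tibble::tibble(
    cases = as.integer(cases),
    n = as.integer(ceiling(cases / prevalence)),
    achieved_half_width = achieved_half_width(cases, target_sens, level)
  )
}

#' Confidence half-width achieved by a given number of cases
#'
#' @param cases Number of reference-positive cases contributing to the
#'   sensitivity estimate.
#' @param sens Anticipated sensitivity.
#' @param level Confidence level; default 0.95.
#' @return The normal-approximation half-width
#'   `z * sqrt(sens * (1 - sens) / cases)`.
#' @examples
#' achieved_half_width(155, 0.90) # the precision 155 cases deliver
#' @export
achieved_half_width <- function(cases, sens, level = 0.95) {
  stopifnot(cases >= 1, sens > 0, sens < 1)
  stats::qnorm(1 - (1 - level) / 2) * sqrt(sens * (1 - sens) / cases)
}
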