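#' Logistic-regression association check
#'
#' Fits a binomial-family logistic regression by maximum likelihood
#' (iteratively reweighted least squares, via [stats::glm()]) and reports
#' odds ratios with Wald intervals. Used in validation to ask whether
#' correct screener decisions are associated with participant age or sex.
#' Non-convergence and (quasi-)complete separation are raised as errors:
#' a silently divergent fit is never returned.
#'
#' @param data A data frame.
#' @param formula Model formula with a binary (logical, 0/1, or two-level
#'   factor) outcome on the left.
#' @param level Confidence level for the Wald intervals; default 0.95.
#' @return An object of class `"screen_logit"`; see [tidy.screen_logit()]
#'   and [glance.screen_logit()].
#' @examples
#' d <- simulate_participants(n = 200, seed = 7)
#' d$dec <- decide_referrals(d, 7)$refer
#' fit_logistic(d, dec ~ age_years)
#' @export
fit_logistic <- function(data, formula, level = 0.95) {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    # separation is detected and raised as an error below
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
        conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    stop("logistic regression did not converge within 50 IRLS iterations",
      call. = FALSE)
  }
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
    stop(paste0(
      "fitted probabilities numerically 0 or 1: the data show complete ",
      "or quasi-complete separation, so Wald odds ratios are meaningless"
    ), call. = FALSE)
  }
  structure(list(fit = fit, level = level, formula = formula),
    class = "screen_logit")
}

#' @export
print.screen_logit <- function(x, ...) {
  cat("Logistic referral-association model\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic association fit
#'
#' @param x A [fit_logistic()] object.
#' @param ... Unused.
#' @return A tibble with one row per term: log-odds `estimate` and
#'   `std_error`, `odds_ratio` with Wald bounds `or_low`/`or_high`, and
#'   the Wald `p_value`.
#' @method tidy screen_logit
#' @export
tidy.screen_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  z <- stats::qnorm(1 - (1 - x$level) / 2)
  est <- unname(s[, "Estimate"])
  se <- unname(s[, "Std. Error"])
  tibble::tibble(
    term = rownames(s),
    estimate = est,
    std_error = se,
    odds_ratio = exp(est),
    or_low = exp(est - z * se),
    or_high = exp(est + z * se),
    p_value = unname(s[, "Pr(>|z|)"])
  )
}

#' One-row summary of a logistic association fit
#'
#' @inheritParams tidy.screen_logit
#' @return One-row tibble: `n`, `deviance`, `null_deviance`, `aic`,
#'   `converged`.
#' @method glance screen_logit
#' @export
glance.screen_logit <- function(x, ...) {
  tibble::tibble(
    n = stats::nobs(x$fit),
    deviance = stats::deviance(x$fit),
    null_deviance = x$fit$null.deviance,
    aic = stats::AIC(x$fit),
    converged = x$fit$converged
  )
}

#' Odds ratio of a 2x2 table with Wald interval
#'
#' The cross-product ratio `(a * d) / (b * c)` for the table
#' `rbind(c(a, b), c(c, d))` (exposed/unexposed by outcome yes/no), with
#' a log-scale Wald interval. When any cell is zero, 0.5 is added to
#' every cell (Haldane-Anscombe correction) and the result flagged.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param level Confidence level; default 0.95.
#' @return One-row tibble: `odds_ratio`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio_2x2(20, 10, 5, 10)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    corrected = corrected
  )
}
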