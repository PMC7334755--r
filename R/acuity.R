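#' Parse Snellen acuity notation
#'
#' Distance visual acuity is recorded in metric Snellen notation
#' (`"6/12"`: the subject resolves at 6 m what a standard eye resolves at
#' 12 m). The canonical internal scale is logMAR,
#' `log10(denominator / numerator)`: 6/6 is 0.0, 6/60 is 1.0, and larger
#' values mean worse vision. The token `"NA"` (or a missing value) denotes
#' an acuity that was not assessed, as for children under 6 years.
#'
#' @param x Character vector of Snellen strings such as `"6/12"`, or `NA`
#'   for not-assessed.
#' @return A tibble with one row per element and columns `snellen`,
#'   `numerator`, `denominator` and `logmar`. Not-assessed entries carry
#'   `NA` in every numeric column.
#' @examples
#' parse_snellen(c("6/6", "6/12", "6/60", NA))
#' @export
parse_snellen <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & toupper(trimws(x)) == "NA"] <- NA_character_
  out <- tibble::tibble(
    snellen = x,
    numerator = NA_real_,
    denominator = NA_real_,
    logmar = NA_real_
  )
  ok <- !is.na(x)
  if (!any(ok)) {
    return(out)
  }
  parts <- stringr::str_match(trimws(x[ok]), "^([0-9]*\\.?[0-9]+)\\s*/\\s*([0-9]*\\.?[0-9]+)$")
  bad <- is.na(parts[, 1])
  if (any(bad)) {
    stop(sprintf(
      "malformed Snellen acuity %s: expected \"<number>/<number>\", e.g. \"6/12\"",
      paste(sQuote(x[ok][bad]), collapse = ", ")
    ), call. = FALSE)
  }
  num <- as.numeric(parts[, 2])
  den <- as.numeric(parts[, 3])
  nonpos <- num <= 0 | den <= 0
  if (any(nonpos)) {
    stop(sprintf(
      "invalid Snellen acuity %s: numerator and denominator must be positive",
      paste(sQuote(x[ok][nonpos]), collapse = ", ")
    ), call. = FALSE)
  }
  out$numerator[ok] <- num
  out$denominator[ok] <- den
  out$logmar[ok] <- log10(den / num)
  out$snellen[ok] <- format_snellen(num, den)
  out
}

#' Format a Snellen string from its parts
#'
#' @param numerator,denominator Positive numbers; the test distance and the
#'   Snellen denominator, both in meters.
#' @return Character vector `"numerator/denominator"`.
#' @examples
#' format_snellen(6, 12)
#' @export
format_snellen <- function(numerator, denominator) {
  fmt <- function(v) {
    ifelse(is.na(v), NA_character_,
      ifelse(v == round(v), format(as.integer(round(v))), format(v))
    )
  }
  ifelse(is.na(numerator) | is.na(denominator), NA_character_,
    paste0(fmt(numerator), "/", fmt(denominator))
  )
}

#' Convert Snellen acuity to logMAR
#'
#' @inheritParams parse_snellen
#' @return Numeric vector of logMAR values (`NA` where not assessed).
#' @examples
#' snellen_logmar(c("6/6", "6/60"))
#' @export
snellen_logmar <- function(x) {
  parse_snellen(x)$logmar
}

#' Does an acuity fall below a referral threshold?
#'
#' The referral trigger is vision *worse than* the threshold (by default
#' 6/12): the comparison is strict, so an acuity of exactly 6/12 does not
#' trigger. Comparison is performed on the exact Snellen ratios by
#' cross-multiplication, so equal notations never differ by floating-point
#' noise.
#'
#' @param va Character vector of Snellen acuities (`NA` = not assessed).
#' @param threshold Single Snellen string; default `"6/12"`.
#' @return Logical vector: `TRUE` where `va` is strictly worse than
#'   `threshold`, `NA` where `va` is not assessed.
#' @examples
#' va_worse_than(c("6/12", "6/18", "6/6"))
#' @export
va_worse_than <- function(va, threshold = "6/12") {
  p <- parse_snellen(va)
  t <- parse_snellen(threshold)
  if (nrow(t) != 1 || is.na(t$logmar)) {
    stop("`threshold` must be a single well-formed Snellen string", call. = FALSE)
  }
  # worse vision  <=>  larger denominator/numerator ratio
  p$denominator * t$numerator > t$denominator * p$numerator
}

#' Reporting bands for distance acuity
#'
#' Survey-style bands over the (better-eye) presenting acuity:
#' 6/6 to 6/12 inclusive is within the screening norm, 6/18 to 6/60
#' inclusive is impaired, and worse than 6/60 is severe. A missing acuity
#' (children, whose vision is not assessed) maps to `"not_assessed"`.
#'
#' @inheritParams parse_snellen
#' @return Factor with levels `normal_6_6_to_6_12`, `impaired_6_18_to_6_60`,
#'   `severe_below_6_60`, `not_assessed`.
#' @examples
#' acuity_band(c("6/12", "6/60", "3/60", NA))
#' @export
acuity_band <- function(x) {
  p <- parse_snellen(x)
  ratio <- p$denominator / p$numerator
  band <- dplyr::case_when(
    is.na(ratio) ~ "not_assessed",
    ratio <= 2 ~ "normal_6_6_to_6_12",
    ratio <= 10 ~ "impaired_6_18_to_6_60",
    TRUE ~ "severe_below_6_60"
  )
  factor(band, levels = c(
    "normal_6_6_to_6_12", "impaired_6_18_to_6_60",
    "severe_below_6_60", "not_assessed"
  ))
}

#' Discrete Snellen chart lines by reporting band
#'
#' The chart lines the simulator samples from, one row per line, with the
#' band each line belongs to and its logMAR value.
#'
#' @return A tibble with columns `band`, `snellen`, `logmar`.
#' @export
snellen_chart <- function() {
  lines <- c(
    normal_6_6_to_6_12 = "6/6", normal_6_6_to_6_12 = "6/9",
    normal_6_6_to_6_12 = "6/12",
    impaired_6_18_to_6_60 = "6/18", impaired_6_18_to_6_60 = "6/24",
    impaired_6_18_to_6_60 = "6/36", impaired_6_18_to_6_60 = "6/60",
    severe_below_6_60 = "4/60", severe_below_6_60 = "3/60",
    severe_below_6_60 = "2/60", severe_below_6_60 = "1/60"
  )
  tibble::tibble(
    band = names(lines),
    snellen = unname(lines),
    logmar = snellen_logmar(unname(lines))
  )
}
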