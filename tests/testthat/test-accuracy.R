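test_that("confusion tables are built with fixed orientation and strict checks", {
  t1 <- build_confusion(TRUE, TRUE)
  expect_equal(unlist(t1[, c("tp", "fn", "fp", "tn")]),
    c(tp = 1L, fn = 0L, fp = 0L, tn = 0L))
  t2 <- build_confusion(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, TRUE))
  expect_equal(t2$tp, 0L)
  expect_equal(t2$fp, 0L)
  expect_equal(t2$fn, 2L)
  expect_error(build_confusion(c(TRUE, NA), c(TRUE, TRUE)), "position")
  expect_error(build_confusion(TRUE, c(TRUE, FALSE)), "length")
  expect_error(confusion_table(-1, 0, 0, 0), "non-negative")
})

test_that("the final-iteration study counts reproduce the printed accuracy", {
  m <- accuracy_summary(confusion_table(344, 34, 43, 153))
  est <- stats::setNames(round(100 * m$estimate, 1), m$metric)
  expect_equal(unname(est), c(91.0, 78.1, 88.9, 81.8))
  lo <- stats::setNames(round(100 * m$ci_low, 1), m$metric)
  hi <- stats::setNames(round(100 * m$ci_high, 1), m$metric)
  expect_equal(unname(lo), c(87.7, 71.6, 85.3, 75.5))
  expect_equal(unname(hi), c(93.7, 83.6, 91.8, 87.1))
})

test_that("degenerate denominators are flagged undefined, not fabricated", {
  m <- accuracy_summary(confusion_table(5, 0, 0, 7))
  expect_true(all(m$defined))
  expect_equal(m$estimate, rep(1, 4))
  m0 <- accuracy_summary(confusion_table(0, 0, 3, 7))
  expect_false(m0$defined[m0$metric == "sensitivity"])
  expect_true(is.na(m0$estimate[m0$metric == "sensitivity"]))
})

test_that("Clopper-Pearson matches an independent tail-inversion oracle", {
  # oracle: invert the binomial tail probabilities by bisection
  oracle_ci <- function(k, n, level = 0.95, tol = 1e-10) {
    alpha <- 1 - level
    bisect <- function(f, lo, hi) {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f(mid)) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    low <- if (k == 0) 0 else {
      bisect(function(p) stats::pbinom(k - 1, n, p) > 1 - alpha / 2, 0, 1)
    }
    high <- if (k == n) 1 else {
      bisect(function(p) stats::pbinom(k, n, p) > alpha / 2, 0, 1)
    }
    c(low, high)
  }
  for (case in list(c(3, 12), c(0, 10), c(10, 10), c(344, 378), c(1, 25))) {
    ci <- exact_binomial_ci(case[1], case[2])
    expect_equal(unlist(ci), oracle_ci(case[1], case[2]),
      tolerance = 1e-9, ignore_attr = TRUE)
    # and the stats package's own exact interval agrees
    bt <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(unlist(ci), as.numeric(bt), tolerance = 1e-8,
      ignore_attr = TRUE)
  }
  expect_equal(exact_binomial_ci(0, 10)$low, 0)
  expect_equal(exact_binomial_ci(10, 10)$high, 1)
  expect_error(exact_binomial_ci(5, 4), "k")
  expect_error(exact_binomial_ci(1, 4, level = 1.2), "level")
})

test_that("interval endpoints are monotone in the success count", {
  for (n in c(7, 20)) {
    ci <- exact_binomial_ci(0:n, n)
    expect_true(all(diff(ci$low) >= -1e-12))
    expect_true(all(diff(ci$high) >= -1e-12))
  }
})

test_that("kappa reproduces the interrater study and its boundary cases", {
  k <- cohen_kappa(reconstruct_2x2(59, 44, 49, 0.848))
  expect_equal(round(k$kappa, 2), 0.55)
  expect_equal(k$band, "moderate")
  expect_equal(round(cohen_kappa(confusion_table(10, 0, 0, 5))$kappa, 10), 1)
  expect_equal(cohen_kappa(confusion_table(25, 25, 25, 25))$kappa, 0)
  # bounded, 1 iff off-diagonal empty, invariant under transposition
  withr::with_seed(44, {
    for (i in 1:25) {
      cells <- stats::rpois(4, 8)
      if (sum(cells) == 0) next
      t <- confusion_table(cells[1], cells[2], cells[3], cells[4])
      tt <- confusion_table(cells[1], cells[3], cells[2], cells[4])
      k1 <- cohen_kappa(t)
      k2 <- cohen_kappa(tt)
      if (!k1$defined) next
      expect_gte(k1$kappa, -1)
      expect_lte(k1$kappa, 1)
      expect_equal(k1$kappa, k2$kappa)
      if (cells[2] + cells[3] > 0) expect_lt(k1$kappa, 1)
    }
  })
  # degenerate marginals leave kappa undefined
  kd <- cohen_kappa(confusion_table(10, 0, 0, 0))
  expect_false(kd$defined)
  expect_true(is.na(kd$kappa))
})

test_that("the kappa bands follow the published scheme", {
  expect_equal(cohen_kappa(reconstruct_2x2(100, 50, 50, 1))$band, "good")
  expect_equal(eyescreen:::kappa_band(c(0.3, 0.5, 0.7, 0.9)),
    c("poor", "moderate", "fair", "good"))
})

test_that("2x2 reconstruction from marginals is exact and round-trips", {
  t <- reconstruct_2x2(59, 44, 49, 0.848)
  expect_equal(unlist(t[, c("tp", "fn", "fp", "tn")]),
    c(tp = 42L, fn = 2L, fp = 7L, tn = 8L))
  expect_equal(round(percent_agreement(t), 3), round(50 / 59, 3))
  t2 <- reconstruct_2x2(10, 10, 10, 1)
  expect_equal(t2$tp, 10L)
  expect_equal(t2$tn, 0L)
  # degenerate all-discordant table is accepted as tp=0 fn=5 fp=5 tn=0
  t3 <- reconstruct_2x2(10, 5, 5, 0)
  expect_equal(unlist(t3[, c("tp", "fn", "fp", "tn")]),
    c(tp = 0L, fn = 5L, fp = 5L, tn = 0L))
  expect_error(reconstruct_2x2(10, 9, 9, 0), "negative")
  expect_error(reconstruct_2x2(10, 5, 4, 0.4), "odd")
  # round-trip: marginals and agreement recovered exactly
  withr::with_seed(55, {
    for (i in 1:30) {
      cells <- stats::rpois(4, 6)
      n <- sum(cells)
      if (n == 0) next
      t <- confusion_table(cells[1], cells[2], cells[3], cells[4])
      r <- reconstruct_2x2(n, t$tp + t$fn, t$tp + t$fp, percent_agreement(t))
      expect_equal(r, t)
    }
  })
})

test_that("percent agreement is the diagonal share", {
  expect_equal(percent_agreement(confusion_table(42, 2, 7, 8)), 50 / 59)
  expect_equal(percent_agreement(confusion_table(3, 0, 0, 2)), 1)
  expect_equal(percent_agreement(confusion_table(0, 4, 6, 0)), 0)
})

test_that("Buderer sample sizes and achieved precision are reproduced", {
  ss <- sample_size_sensitivity(0.90, 0.05, 0.30)
  expect_equal(ss$cases, 139L)
  expect_equal(ss$n, 464L)
  expect_equal(round(achieved_half_width(155, 0.90), 3), 0.047)
  # monotone: tighter precision needs more participants
  widths <- c(0.10, 0.05, 0.025, 0.0125)
  ns <- vapply(widths,
    function(w) sample_size_sensitivity(0.9, w, 0.3)$n, integer(1))
  expect_true(all(diff(ns) > 0))
  expect_error(sample_size_sensitivity(0.9, 0, 0.3), "between 0 and 1")
})
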