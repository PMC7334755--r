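test_that("iteration evaluation cross-tabulates index against reference", {
  recs <- manual_records()
  ev <- evaluate_iteration(recs, iteration = 7)
  expect_s3_class(ev, "iteration_eval")
  expect_equal(unlist(ev$confusion[, c("tp", "fn", "fp", "tn")]),
    c(tp = 5L, fn = 0L, fp = 0L, tn = 3L))
  expect_equal(glance(ev)$sensitivity, 1)
  td <- tidy(ev)
  expect_identical(td$metric,
    c("sensitivity", "specificity", "ppv", "npv"))
  expect_true(all(td$iteration == 7))
})

test_that("missing reference decisions are excluded and accounted, not dropped", {
  recs <- manual_records()
  recs$reference_referral[3] <- NA
  ev <- evaluate_iteration(recs, iteration = 7)
  expect_equal(ev$flow$eligible, 8L)
  expect_equal(ev$flow$excluded_incomplete, 1L)
  expect_equal(ev$flow$analyzed, 7L)
  total <- with(ev$confusion, tp + fn + fp + tn)
  expect_equal(total, 7L)
})

test_that("an all-referable cohort leaves specificity undefined, flagged", {
  recs <- manual_records()
  recs$reference_referral <- TRUE
  ev <- evaluate_iteration(recs, iteration = 7)
  m <- ev$metrics
  expect_false(m$defined[m$metric == "specificity"])
  expect_true(is.na(m$estimate[m$metric == "specificity"]))
})

test_that("counterfactual strategies consult only their own fields", {
  recs <- manual_records()
  cmp <- compare_strategies(recs)
  expect_setequal(cmp$strategy,
    c("full_algorithm", "va_only", "symptoms_only", "age40_or_symptoms"))
  one <- function(strategy, row) {
    eyescreen:::strategy_decision(recs, strategy)[row]
  }
  # age 50, va 6/6+6/12, no symptoms, N8 pass (row 7)
  expect_false(one("va_only", 7))
  expect_true(one("age40_or_symptoms", 7))
  # age 10, vision difficulty only (row 8)
  expect_true(one("symptoms_only", 8))
  expect_false(one("va_only", 8))
  # age 25, va 6/18 one eye, no symptoms (row 5)
  expect_true(one("va_only", 5))
  expect_false(one("symptoms_only", 5))
  expect_error(compare_strategies(recs, strategies = "nonsense"), "unknown")
})

test_that("the full algorithm's referrals contain the va-only referrals", {
  recs <- simulate_participants(n = 1500, seed = 41)
  full <- eyescreen:::strategy_decision(recs, "full_algorithm")
  va <- eyescreen:::strategy_decision(recs, "va_only")
  expect_true(all(full[va]))
  # and the reference margin is strategy-invariant
  cmp <- compare_strategies(recs)
  expect_equal(unique(cmp$tp + cmp$fn), sum(recs$reference_referral))
})

test_that("the final rule equals the union of its trigger sets over a full grid", {
  grid <- tidyr::expand_grid(
    age_years = c(30L, 45L),
    pain_discomfort = c("yes", "no"),
    vision_difficulty = c("yes", "no"),
    va_right = c("6/6", "6/18"),
    near_n8 = c("pass", "fail")
  ) |>
    dplyr::mutate(
      id = sprintf("G%02d", dplyr::row_number()),
      sex = "female", child_problem = NA_character_, va_left = "6/6",
      near_n8 = dplyr::if_else(.data$age_years >= 40, .data$near_n8,
        NA_character_)
    ) |>
    dplyr::distinct(dplyr::across(!dplyr::any_of("id")), .keep_all = TRUE)
  kid_grid <- tibble::tibble(
    id = c("K1", "K2"), age_years = c(2L, 5L), sex = "male",
    child_problem = c("yes", "no"), pain_discomfort = NA_character_,
    vision_difficulty = NA_character_, va_right = NA_character_,
    va_left = NA_character_, near_n8 = NA_character_
  )
  grid <- dplyr::bind_rows(grid, kid_grid)
  dec <- decide_referrals(grid, iteration = 7)
  expected <- with(grid,
    (age_years < 6 & !is.na(child_problem) & child_problem == "yes") |
      (age_years >= 6 & (
        va_worse_than(va_right) %in% TRUE |
          va_worse_than(va_left) %in% TRUE |
          pain_discomfort %in% "yes" |
          vision_difficulty %in% "yes" |
          (age_years >= 40 & near_n8 %in% "fail")
      )))
  expect_identical(dec$refer, expected)
})

test_that("flow accounting distinguishes complete from incomplete records", {
  recs <- manual_records()
  expect_equal(screening_flow(recs)$excluded_incomplete, 0L)
  broken <- recs
  broken$va_right[5] <- NA
  broken$reference_referral[3] <- NA
  fl <- screening_flow(broken, iteration = 7)
  expect_equal(fl$eligible, 8L)
  expect_equal(fl$excluded_incomplete, 2L)
  expect_equal(fl$analyzed, 6L)
  # iterations 1-2 do not require acuity, so only the reference gap counts
  expect_equal(screening_flow(broken, iteration = 1)$excluded_incomplete, 1L)
  allbad <- recs
  allbad$reference_referral <- NA
  expect_equal(screening_flow(allbad)$analyzed, 0L)
  expect_equal(flow_from_totals(607, 33)$analyzed, 574L)
})

test_that("plot methods return ggplot objects", {
  recs <- simulate_participants(n = 300, seed = 8)
  expect_s3_class(autoplot(evaluate_iteration(recs, 7)), "ggplot")
  expect_s3_class(autoplot(compare_strategies(recs)), "ggplot")
})
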