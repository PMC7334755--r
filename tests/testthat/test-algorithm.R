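test_that("the catalog lists the seven rule sets with their deltas", {
  cat <- algorithm_catalog()
  expect_equal(nrow(cat), 7)
  expect_equal(cat$iteration, 1:7)
  expect_identical(cat$distance_va_mandatory,
    c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(cat$near_vision_required_40plus,
    c(rep(FALSE, 6), TRUE))
  expect_identical(cat$problem_question_scope[1:4],
    c("any_duration", "any_duration", "any_duration", "today_only"))
  expect_identical(cat$symptom_questions[[5]],
    c("eye_pain", "vision_difficulty"))
  expect_identical(cat$symptom_questions[[7]],
    c("eye_pain_or_discomfort", "vision_difficulty"))
})

test_that("the final rule refers on each trigger with the right reason code", {
  dec <- decide_referrals(manual_records(), iteration = 7)
  expect_identical(dec$refer,
    c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(dec$reasons[[1]], "child_problem")
  expect_identical(dec$reasons[[4]], "near_vision_fail")
  expect_identical(dec$reasons[[5]], "low_distance_va")
  expect_identical(dec$reasons[[6]], c("low_distance_va", "pain_or_discomfort"))
  expect_identical(dec$reasons[[8]], "vision_difficulty")
  # refer iff reasons nonempty
  expect_identical(dec$refer, lengths(dec$reasons) > 0)
})

test_that("earlier iterations apply their own question subsets", {
  recs <- manual_records()
  # iteration 1-2: any-duration problem question, acuity consulted if present
  d1 <- decide_referrals(recs, iteration = 1)
  expect_identical(d1$refer[6], TRUE)
  expect_identical(sort(d1$reasons[[6]]),
    c("any_eye_problem", "low_distance_va"))
  expect_false(d1$refer[4]) # near-vision failure not consulted before it 7
  # acuity absent is not an error and not a trigger under iterations 1-2
  sparse <- recs
  sparse$va_right <- NA_character_
  sparse$va_left <- NA_character_
  expect_false(decide_referrals(sparse, iteration = 2)$refer[5])
  # iteration 5 asks pain only: discomfort-only row 6 still refers on acuity
  d5 <- decide_referrals(recs, iteration = 5)
  expect_identical(d5$reasons[[6]], "low_distance_va")
  # iteration 6 expands to pain-or-discomfort
  d6 <- decide_referrals(recs, iteration = 6)
  expect_identical(d6$reasons[[6]], c("low_distance_va", "pain_or_discomfort"))
})

test_that("mandatory fields are enforced by name, never defaulted", {
  recs <- manual_records()
  nova <- recs
  nova$va_left[5] <- NA
  expect_error(decide_referrals(nova, iteration = 7), "va_left")
  expect_error(decide_referrals(nova, iteration = 7), "iteration 7")
  nonear <- recs
  nonear$near_n8[4] <- NA
  expect_error(decide_referrals(nonear, iteration = 7), "near_n8")
  noq <- recs[, setdiff(names(recs), c("problem_any"))]
  expect_error(decide_referrals(noq, iteration = 3), "problem_any")
  nochild <- recs
  nochild$child_problem[1] <- NA
  expect_error(decide_referrals(nochild, iteration = 7), "child_problem")
})

test_that("decisions are monotone in acuity and in the trigger set", {
  withr::with_seed(202, {
    recs <- simulate_participants(n = 400, seed = 31)
    dec <- decide_referrals(recs, iteration = 7)
    chart <- snellen_chart()
    worst <- chart$snellen[which.max(chart$logmar)]
    adult <- recs$age_years >= 6
    # worsening either eye to the worst chart line never removes a referral
    worse <- recs
    worse$va_right[adult] <- worst
    decw <- decide_referrals(worse, iteration = 7)
    expect_true(all(decw$refer[dec$refer & adult]))
    # adding a triggered symptom never removes a referral
    sym <- recs
    sym$pain_discomfort[adult] <- "yes"
    decs <- decide_referrals(sym, iteration = 7)
    expect_true(all(decs$refer[dec$refer & adult]))
  })
})

test_that("children are decided by the guardian answer alone", {
  withr::with_seed(9, {
    recs <- simulate_participants(n = 400, seed = 17)
    kids <- recs[recs$age_years < 6, , drop = FALSE]
    expect_gt(nrow(kids), 10)
    dec <- decide_referrals(kids, iteration = 7)
    expect_identical(dec$refer, kids$child_problem == "yes")
    # perturbing every other field changes nothing for children
    kids2 <- kids
    kids2$sex <- "male"
    expect_identical(decide_referrals(kids2, iteration = 7)$refer, dec$refer)
  })
})

test_that("iterations 6 and 7 agree for everyone under 40", {
  recs <- simulate_participants(n = 600, seed = 23)
  under40 <- recs[recs$age_years < 40, , drop = FALSE]
  expect_identical(
    decide_referrals(under40, iteration = 6)$refer,
    decide_referrals(under40, iteration = 7)$refer
  )
})

test_that("a custom referral threshold is honoured", {
  recs <- manual_records()
  # with a 6/60 threshold the 6/18 and 6/36 acuities no longer trigger
  dec <- decide_referrals(recs, iteration = 7, threshold = "6/60")
  expect_false(dec$refer[5])
  expect_identical(dec$reasons[[6]], "pain_or_discomfort")
})
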