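covs <- function(mean_age = 60, sd_age = 10, p = c(a = 0.5, b = 0.3, c = 0.2))
  list(age = list(type = "continuous", mean = mean_age, sd = sd_age),
       lines = list(type = "categorical", proportions = p))

test_that("identical control arms raise no drift flags", {
  s <- control_summary("R1", binom_outcome(26, 63), covariates = covs())
  s2 <- control_summary("R2", binom_outcome(26, 63), covariates = covs())
  rep <- drift_report(list(s, s2))
  expect_equal(rep$rates$difference, 0)
  expect_equal(rep$covariates$std_difference, c(0, 0))
  expect_false(rep$any_flag)
})

test_that("the worked response-rate comparison is descriptive and unflagged", {
  s1 <- control_summary("R1", binom_outcome(26, 63))
  s2 <- control_summary("R2", binom_outcome(7, 16))
  rep <- drift_report(list(s1, s2), flag_threshold = 0.10)
  expect_equal(rep$rates$rate_a, 27 / 65)
  expect_equal(rep$rates$rate_b, 8 / 18)
  expect_equal(rep$rates$abs_difference, abs(27 / 65 - 8 / 18))
  expect_lt(rep$rates$abs_difference, 0.03)
  expect_false(rep$rates$flag)
})

test_that("standardized differences flag imbalanced covariates", {
  s1 <- control_summary("R1", binom_outcome(10, 30),
                        covariates = list(x = list(type = "continuous",
                                                   mean = 0, sd = 1)))
  s2 <- control_summary("R2", binom_outcome(10, 30),
                        covariates = list(x = list(type = "continuous",
                                                   mean = 1, sd = 1)))
  rep <- drift_report(list(s1, s2), flag_threshold = 0.2)
  expect_equal(rep$covariates$std_difference, 1)
  expect_true(rep$covariates$flag)
  expect_true(rep$any_flag)
})

test_that("the drift report is symmetric under swapping rounds", {
  s1 <- control_summary("R1", binom_outcome(26, 63),
                        covariates = covs(58, 9, c(a = .6, b = .25, c = .15)))
  s2 <- control_summary("R2", binom_outcome(7, 16),
                        covariates = covs(63, 12, c(a = .45, b = .35, c = .2)))
  fwd <- drift_report(list(s1, s2))
  rev <- drift_report(list(s2, s1))
  expect_equal(fwd$rates$difference, -rev$rates$difference)
  expect_equal(fwd$rates$abs_difference, rev$rates$abs_difference)
  expect_equal(sort(fwd$covariates$std_difference),
               sort(rev$covariates$std_difference))
  expect_identical(fwd$any_flag, rev$any_flag)
})

test_that("mismatched covariate schemas are rejected", {
  s1 <- control_summary("R1", binom_outcome(5, 10), covariates = covs())
  s2 <- control_summary("R2", binom_outcome(5, 10),
                        covariates = list(age = list(type = "continuous",
                                                     mean = 60, sd = 10)))
  expect_error(drift_report(list(s1, s2)), "mismatched")
  expect_error(drift_report(list(s1)), "at least two")
})

test_that("weight-sensitivity endpoints reproduce the no-borrowing and pooled analyses", {
  tab <- weight_sensitivity(r2_control(), r2_experimental(),
                            history = list(binom_outcome(26, 63)),
                            weights = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(nrow(tab), 5)
  expect_equal(tab$weight, c(0, 0.25, 0.5, 0.75, 1))

  # weight 0 row: concurrent-only analysis, exactly
  fit0 <- round_analysis(r2_control(), r2_experimental())
  expect_equal(tab$post_alpha[1], fit0$posterior_control$alpha)
  expect_equal(tab$post_beta[1], fit0$posterior_control$beta)
  expect_equal(tab$prob[1], fit0$prob)

  # weight 1 row: full pooling of the two control datasets, exactly
  pooled <- round_analysis(binom_outcome(26 + 7, 63 + 16), r2_experimental())
  expect_equal(tab$post_alpha[5], pooled$posterior_control$alpha)
  expect_equal(tab$post_beta[5], pooled$posterior_control$beta)
  expect_equal(tab$prob[5], pooled$prob)
})

test_that("sensitivity probabilities vary continuously and monotonically on the fixture", {
  # history generated at the concurrent control rate, clearly superior
  # experimental arm: borrowing sharpens the control posterior around the
  # same rate, so the probability is non-decreasing in the weight here
  fine <- weight_sensitivity(binom_outcome(6, 16), binom_outcome(41, 63),
                             history = list(binom_outcome(24, 63)),
                             weights = seq(0, 1, by = 0.01))
  expect_true(all(abs(diff(fine$prob)) < 0.05))
  expect_true(all(diff(fine$prob) > -1e-9))
})

test_that("weighting decision records validate and round-trip through JSON", {
  s1 <- control_summary("R1", binom_outcome(26, 63))
  s2 <- control_summary("R2", binom_outcome(7, 16))
  rep <- drift_report(list(s1, s2))
  rec <- weighting_decision_record(rep, 0.75,
                                   rationale = "populations remain similar",
                                   care_change_note = "none",
                                   recruitment_gap_months = 6)
  js <- decision_record_json(rec)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$chosen_weight, 0.75)
  expect_equal(parsed$rationale, "populations remain similar")
  expect_equal(parsed$care_change_note, "none")
  expect_equal(parsed$recruitment_gap_months, 6)
  expect_equal(parsed$drift$flag_threshold, rep$flag_threshold)
  expect_equal(nrow(parsed$drift$rates), 1)

  tmp <- tempfile(fileext = ".json")
  decision_record_json(rec, tmp)
  expect_equal(jsonlite::fromJSON(tmp)$chosen_weight, 0.75)

  expect_error(weighting_decision_record(rep, 1.2, "x"), "\\[0, 1\\]")
  expect_error(weighting_decision_record(rep, 0.75, ""), "rationale")
})
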