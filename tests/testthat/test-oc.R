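test_that("simulation converges on exact enumeration", {
  sc <- scenario(small_design(14, 14), 0.40, 0.65)
  ex <- exact_oc(sc)
  expect_equal(ex$method, "exact_enumeration")
  expect_equal(ex$mc_se, 0)
  sim <- simulate_oc(sc, reps = 10000, seed = 21)
  expect_lt(abs(sim$prob_success - ex$prob_success), 3 * sim$mc_se)

  # with borrowing in the prior as well
  d2 <- round_design("S2", 8, 20,
                     history = list(borrow_spec("S", 14, 0.75)))
  sc2 <- scenario(d2, 0.40, 0.65, historical_rates = 0.40)
  ex2 <- exact_oc(sc2)
  sim2 <- simulate_oc(sc2, reps = 10000, seed = 22)
  expect_lt(abs(sim2$prob_success - ex2$prob_success), 3 * sim2$mc_se)
})

test_that("degenerate scenarios give the indicator of the forced outcome", {
  d <- small_design(10, 10)
  # an experimental arm that can never respond cannot meet a 15-point margin
  sc0 <- scenario(d, 0.40, 0)
  expect_equal(exact_oc(sc0)$prob_success, 0, tolerance = 1e-12)
  expect_equal(simulate_oc(sc0, reps = 500, seed = 1)$prob_success, 0)

  # margin -1 is met by every outcome
  sc_all <- scenario(d, 0.40, 0.40, rule = decision_rule(margin = -1))
  expect_equal(exact_oc(sc_all)$prob_success, 1)

  # certainty 0 declares success for every posterior
  sc_c0 <- scenario(d, 0.40, 0.40, rule = decision_rule(certainty = 0))
  expect_equal(exact_oc(sc_c0)$prob_success, 1)

  # degenerate true rates collapse to a single outcome cell
  sc_det <- scenario(d, 1, 1)
  expect_true(exact_oc(sc_det)$prob_success %in% c(0, 1))
})

test_that("operating characteristics are monotone in effect size", {
  d <- small_design(12, 12)
  oc <- vapply(c(0.30, 0.40, 0.55, 0.65, 0.80),
               function(pe) exact_oc(scenario(d, 0.40, pe))$prob_success, 0)
  expect_true(all(diff(oc) > 0))
})

test_that("raising the certainty threshold never increases the OC", {
  d <- small_design(12, 12)
  oc <- vapply(c(0.50, 0.60, 0.70, 0.80), function(ct)
    exact_oc(scenario(d, 0.40, 0.65,
                      rule = decision_rule(certainty = ct)))$prob_success, 0)
  expect_true(all(diff(oc) <= 1e-12))
})

test_that("borrowing same-rate history at full weight does not hurt a large effect", {
  base <- round_design("B", 10, 20)
  oc_w <- function(w) {
    d <- round_design("B", 10, 20,
                      history = list(borrow_spec("A", 30, w)))
    exact_oc(scenario(d, 0.40, 0.65, historical_rates = 0.40))$prob_success
  }
  expect_gte(oc_w(1), oc_w(0))
})

test_that("heavier borrowing raises the round-2 OC for the +25pp permutation", {
  oc_at <- function(w) {
    d <- three_round_design(w)$R2
    exact_oc(scenario(d, 0.40, 0.65, historical_rates = 0.40))$prob_success
  }
  expect_gt(oc_at(0.75), oc_at(0.5))
})

test_that("oc_table is deterministic under a fixed seed with one row per scenario", {
  g <- build_scenario_grid(c(0.40, 0.60), c(-0.10, 0, 0.15, 0.25),
                           certainties = 0.60, weights = NA,
                           designs = small_design(10, 10))
  t1 <- oc_table(g, reps = 400, seed = 123)
  t2 <- oc_table(g, reps = 400, seed = 123)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 8)
  expect_true(all(t1$prob_success >= 0 & t1$prob_success <= 1))
  expect_true(all(c("round", "hist_rates", "hist_counts", "true_control_rate",
                    "true_exp_rate", "difference", "weight", "margin",
                    "certainty", "reps", "seed", "method", "prob_success",
                    "mc_se") %in% names(t1)))
  t3 <- oc_table(g, reps = 400, seed = 124)
  expect_false(identical(t1$prob_success, t3$prob_success))

  # exact method drops Monte-Carlo error entirely
  te <- oc_table(g, method = "exact")
  expect_true(all(te$mc_se == 0))
})

test_that("simulation and enumeration reject invalid requests with context", {
  sc <- scenario(small_design(10, 10), 0.40, 0.65)
  expect_error(simulate_oc(sc, reps = 0), "at least 1")
  big <- scenario(round_design("X", 2000, 2000), 0.4, 0.6)
  expect_error(exact_oc(big), "enumeration bound")
  expect_error(oc_table(list(big), method = "exact"), "scenario 1")
  expect_error(oc_table(list()), "non-empty")
})

test_that("re-simulated history propagates historical sampling variability", {
  d <- round_design("S2", 8, 16, history = list(borrow_spec("S1", 12, 0.75)))
  sc <- scenario(d, 0.40, 0.65, historical_rates = 0.40)
  r1 <- simulate_oc(sc, reps = 2000, seed = 9, resample_history = TRUE)
  r2 <- simulate_oc(sc, reps = 2000, seed = 9, resample_history = TRUE)
  expect_identical(r1$prob_success, r2$prob_success)
  expect_true(r1$prob_success >= 0 && r1$prob_success <= 1)
  # it should stay in the neighbourhood of the fixed-history OC
  fixed <- exact_oc(sc)$prob_success
  expect_lt(abs(r1$prob_success - fixed), 0.15)
})
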