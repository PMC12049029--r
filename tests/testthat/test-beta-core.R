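test_that("conjugate Beta-Binomial updating adds responders and failures", {
  post <- beta_posterior(beta_params(1, 1), binom_outcome(26, 63))
  expect_equal(post$alpha, 27)
  expect_equal(post$beta, 38)

  # fractional power-prior shapes are carried through exactly
  post2 <- beta_posterior(beta_params(20.5, 28.75), binom_outcome(7, 16))
  expect_equal(post2$alpha, 27.5)
  expect_equal(post2$beta, 37.75)

  # empty data leaves the prior unchanged
  post3 <- beta_posterior(beta_params(1, 1), binom_outcome(0, 0))
  expect_equal(post3$alpha, 1)
  expect_equal(post3$beta, 1)
})

test_that("corrupt or invalid inputs are rejected", {
  expect_error(binom_outcome(64, 63), "exceeds")
  expect_error(binom_outcome(-1, 10), "non-negative")
  expect_error(beta_params(0, 1), "positive")
  expect_error(weighted_outcome(binom_outcome(1, 2), 1.2), "\\[0, 1\\]")
  expect_error(weighted_outcome(binom_outcome(1, 2), -0.1), "\\[0, 1\\]")
  expect_error(decision_rule(margin = 1.5), "\\[-1, 1\\]")
})

test_that("power prior applies weighted pseudo-counts to the initial prior", {
  pp <- power_prior(beta_params(1, 1),
                    list(weighted_outcome(26, 0.75, total = 63)))
  expect_equal(pp$alpha, 1 + 0.75 * 26)
  expect_equal(pp$beta, 1 + 0.75 * 37)

  # weight 0: no borrowing, initial prior unchanged
  pp0 <- power_prior(beta_params(1, 1),
                     list(weighted_outcome(26, 0, total = 63)))
  expect_equal(pp0$alpha, 1)
  expect_equal(pp0$beta, 1)

  # weight 1: full borrowing, identical to pooling the data
  pp1 <- power_prior(beta_params(1, 1),
                     list(weighted_outcome(26, 1, total = 63)))
  pooled <- beta_posterior(beta_params(1, 1), binom_outcome(26, 63))
  expect_equal(pp1$alpha, pooled$alpha)
  expect_equal(pp1$beta, pooled$beta)
})

test_that("power-prior updating is associative with conjugate updating", {
  set.seed(11)
  for (i in 1:20) {
    init <- beta_params(runif(1, 0.5, 5), runif(1, 0.5, 5))
    n1 <- sample(5:60, 1); s1 <- sample(0:n1, 1); w <- runif(1)
    n2 <- sample(5:60, 1); s2 <- sample(0:n2, 1)
    h <- weighted_outcome(s1, w, total = n1)
    d <- binom_outcome(s2, n2)
    a <- beta_posterior(power_prior(init, list(h)), d)
    b <- power_prior(init, list(h, weighted_outcome(d, 1)))
    expect_equal(a$alpha, b$alpha)
    expect_equal(a$beta, b$beta)
  }
})

test_that("posterior tail probability matches closed forms", {
  u <- beta_params(1, 1)
  # difference of two independent uniforms: P(U2 - U1 >= d) = (1-d)^2 / 2
  for (d in c(0, 0.15, 0.3, 0.5, 0.9))
    expect_equal(prob_diff_at_least(u, u, d), (1 - d)^2 / 2,
                 tolerance = 1e-6)
  expect_equal(prob_diff_at_least(u, u, 0.15), 0.36125, tolerance = 1e-6)
  # P(p_e >= p_c) for uniform vs Beta(2,1): int 1 - x^2 dx = 2/3
  expect_equal(prob_diff_at_least(u, beta_params(2, 1), 0), 2 / 3,
               tolerance = 1e-6)
  # symmetry: identical continuous posteriors, margin 0
  b <- beta_params(27, 38)
  expect_equal(prob_diff_at_least(b, b, 0), 0.5, tolerance = 1e-6)
  # negative margins: mass below the reflected range is picked up
  expect_equal(prob_diff_at_least(u, u, -0.25), 1 - 0.75^2 / 2,
               tolerance = 1e-6)
})

test_that("quadrature agrees with a frozen high-precision sampling oracle", {
  # 10^7 paired draws under seed 42 gave 0.829768 (se 0.000119) for the
  # worked posteriors Beta(27,38) vs Beta(42,23) at margin 0.15
  q <- prob_diff_at_least(beta_params(27, 38), beta_params(42, 23), 0.15)
  expect_equal(q, 0.829768, tolerance = 3 * 0.000119 / 0.829768)
})

test_that("quadrature tracks the sampling oracle over random Beta pairs", {
  set.seed(314)
  for (i in 1:6) {
    ctrl <- beta_params(runif(1, 0.5, 60), runif(1, 0.5, 60))
    expr <- beta_params(runif(1, 0.5, 60), runif(1, 0.5, 60))
    m <- runif(1, -0.5, 0.5)
    oracle <- mc_prob_diff(ctrl, expr, m, n = 1e6)
    q <- prob_diff_at_least(ctrl, expr, m)
    expect_lt(abs(q - oracle$p), 3 * max(oracle$se, 1e-6))
  }
})

test_that("tail probability is non-increasing in the margin with unit endpoints", {
  set.seed(99)
  for (i in 1:5) {
    ctrl <- beta_params(runif(1, 1, 40), runif(1, 1, 40))
    expr <- beta_params(runif(1, 1, 40), runif(1, 1, 40))
    margins <- seq(-1, 1, by = 0.25)
    p <- vapply(margins, function(m) prob_diff_at_least(ctrl, expr, m), 0)
    expect_true(all(diff(p) <= 1e-9))
    expect_equal(p[1], 1)
    expect_equal(p[length(p)], 0)
  }
})

test_that("the success rule counts the boundary as success", {
  rule <- default_rule()
  expect_true(decide_success(0.60, rule))
  expect_false(decide_success(0.599, rule))
  expect_true(decide_success(1.0, decision_rule(certainty = 0.99)))
  expect_error(decide_success(1.2, rule), "\\[0, 1\\]")
})

test_that("effective sample size adds weight-scaled historical patients", {
  h <- list(weighted_outcome(26, 0.75, total = 63))
  e <- effective_sample_size(16, h)
  expect_equal(as.numeric(e), 63.25)
  expect_equal(attr(e, "rounded"), 63L)

  expect_equal(as.numeric(effective_sample_size(
    16, list(weighted_outcome(26, 0, total = 63)))), 16)

  # both earlier control arms borrowed at 0.75
  e3 <- effective_sample_size(16, list(weighted_outcome(26, 0.75, total = 63),
                                       weighted_outcome(7, 0.75, total = 16)))
  expect_equal(as.numeric(e3), 75.25)
})

test_that("effective sample size is linear in each borrowing weight", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:80, 1); s <- sample(0:n, 1)
    w1 <- runif(1); w2 <- runif(1); lam <- runif(1)
    ess_w <- function(w) as.numeric(
      effective_sample_size(16, list(weighted_outcome(s, w, total = n))))
    expect_equal(ess_w(lam * w1 + (1 - lam) * w2),
                 lam * ess_w(w1) + (1 - lam) * ess_w(w2))
    expect_equal(ess_w(0), 16)
  }
})
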