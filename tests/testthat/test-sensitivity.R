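# Scenario transforms, one-way DSA, PSA, uncertainty intervals, CEAC.
# Pipeline-level runs use a reduced two-stratum, short-horizon book so
# the whole file stays fast.

fast_pipeline <- function(params) pipeline_default(params)

test_that("apply_scenario transforms are correct and empty scenarios are
           identity", {
  p <- small_book()
  expect_identical(apply_scenario(p, list()), p)
  p2 <- apply_scenario(p, list(adherence = 0.5))
  expect_equal(p2$model$adherence, 0.5)
  # effective rr under adherence scaling: 1 - 0.5 * (1 - 0.7) = 0.85
  sc <- treatment_scenario("treated", rr_events = c(chd = 0.7, stroke = 0.7),
                           adherence = 0.5)
  M <- build_transition_matrix(p$strata[1, ], sc, p)
  M1 <- build_transition_matrix(p$strata[1, ],
          treatment_scenario("treated",
                             rr_events = c(chd = 0.85, stroke = 0.85)), p)
  expect_equal(M["controlled", ], M1["controlled", ], tolerance = 1e-12)
  # pill disutility folds into treated-state weights via combine_dw
  p3 <- apply_scenario(p, list(pill_disutility = 0.049))
  expect_true(p3$model$apply_pill_disutility)
  expect_equal(combine_dw(0.171, 0.049), 0.211621)
  expect_error(apply_scenario(p, list(bogus = 1)), "unknown scenario")
})

test_that("one-way DSA: degenerate range reproduces base case; drug
           price moves treated-arm cost monotonically", {
  p <- small_book()
  base_icer <- fast_pipeline(p)$icer
  d0 <- one_way_dsa(p, "costs.antihypertensive_cost_multiplier", 1, 1,
                    fast_pipeline)
  expect_equal(d0$at_low$icer, base_icer)
  expect_equal(d0$at_high$icer, base_icer)
  cost_at <- function(m) {
    fit <- htn_cea(param_set(p, "costs.antihypertensive_cost_multiplier", m))
    fit$comparison$cost_treated
  }
  expect_lt(cost_at(0.8), cost_at(1))
  expect_lt(cost_at(1), cost_at(1.2))
  # discounting: raising the rate lowers both arms' discounted costs
  d6 <- one_way_dsa(p, "costs.discount_rate", 0.03, 0.06, fast_pipeline)
  f3 <- htn_cea(param_set(p, "costs.discount_rate", 0.03))
  f6 <- htn_cea(param_set(p, "costs.discount_rate", 0.06))
  expect_lt(f6$comparison$cost_treated, f3$comparison$cost_treated)
  expect_lt(f6$comparison$cost_untreated, f3$comparison$cost_untreated)
})

test_that("PSA with point-mass books reproduces the deterministic run
           bit-for-bit and fixed seeds reproduce draws", {
  p <- small_book()
  # collapse all sampled parameters to their means
  for (k in htncea:::psa_default_include(p)) {
    u <- htncea:::param_get(p, k)
    p <- param_set(p, k, u$mean)
  }
  det <- fast_pipeline(p)
  psa <- run_psa(p, n_draws = 3, seed = 123, pipeline = fast_pipeline)
  expect_identical(psa$draws$delta_cost, rep(det$delta_cost, 3))
  expect_identical(psa$draws$delta_dalys, rep(det$delta_dalys, 3))
  expect_identical(psa$draws$nmb, rep(det$nmb, 3))
  # reproducibility from the seed on a stochastic book
  q <- small_book()
  a <- run_psa(q, n_draws = 5, seed = 77, pipeline = fast_pipeline)
  b <- run_psa(q, n_draws = 5, seed = 77, pipeline = fast_pipeline)
  expect_identical(a$draws, b$draws)
})

test_that("a construction where treatment always saves cost yields
           fraction cost-saving 1 and a flat CEAC at 1", {
  always_saves <- function(params) {
    list(delta_cost = 100, delta_dalys = 2, icer = 50, nmb = 100100)
  }
  p <- small_book()
  psa <- run_psa(p, n_draws = 10, seed = 5, pipeline = always_saves,
                 include = "dw.hypertensive_heart_disease")
  expect_equal(psa$fraction_cost_saving, 1)
  expect_equal(unname(psa$quadrants["dominant"]), 1)
  cv <- ceac(psa, c(0, 100, 1e6))
  expect_equal(cv$prob_cost_effective, rep(1, 3))
})

test_that("ceac limits: wtp = 0 gives the cost-saving fraction, large
           wtp converges to the fraction with positive DALYs averted", {
  p <- small_book()
  psa <- run_psa(p, n_draws = 15, seed = 9, pipeline = fast_pipeline)
  cv <- ceac(psa, c(0, 1e9))
  expect_equal(cv$prob_cost_effective[1],
               mean(psa$draws$delta_cost > 0))
  expect_equal(cv$prob_cost_effective[2],
               mean(psa$draws$delta_dalys > 0))
  # hand-count toy: one draw in favour, one against at wtp = 10
  toy <- structure(list(draws = data.frame(delta_cost = c(-5, -20),
                                           delta_dalys = c(1, 1))),
                   class = "htn_psa")
  expect_equal(ceac(toy, 10)$prob_cost_effective, 0.5)
  expect_error(ceac(psa, numeric()), "non-empty")
})

test_that("uncertainty intervals use linear interpolation and nest with
           level", {
  expect_equal(uncertainty_interval(1:1000), c(25.975, 975.025))
  expect_equal(uncertainty_interval(rep(7, 10)), c(7, 7))
  u90 <- uncertainty_interval(1:1000, 0.90)
  u99 <- uncertainty_interval(1:1000, 0.99)
  expect_gt(u90[1], 25.975); expect_lt(u90[2], 975.025)
  expect_lt(u99[1], 25.975); expect_gt(u99[2], 975.025)
  expect_error(uncertainty_interval(5), "at least 2")
})

test_that("Monte Carlo recovery: a known Bernoulli fraction is
           reproduced within three binomial standard errors", {
  p_true <- 0.3
  n <- 1000
  p <- small_book()
  p$dw$hypertensive_heart_disease <- uncertain(0.246, 0.16, 0.34, "beta")
  d <- expand_uncertain(p$dw$hypertensive_heart_disease)
  # threshold at the true 30% quantile of the sampling distribution, so
  # each draw is a Bernoulli(0.3) cost-saving indicator
  thresh <- stats::qbeta(p_true, d$pars[["shape1"]], d$pars[["shape2"]])
  bern_pipeline <- function(params) {
    w <- params$dw$hypertensive_heart_disease$mean
    list(delta_cost = if (w < thresh) 1 else -1, delta_dalys = 1,
         icer = 1, nmb = 1)
  }
  psa <- run_psa(p, n_draws = n, seed = 31, pipeline = bern_pipeline,
                 include = "dw.hypertensive_heart_disease")
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(psa$fraction_cost_saving - p_true), 3 * se)
})
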