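# End-to-end model object: arm symmetry, trace invariants, reporting
# surface.

test_that("equal-risk arms produce identical traces and a null
           comparison", {
  p <- small_book(cycles = 15)
  # abolish every treatment difference: no event effect, equal mortality,
  # equal state weights
  p$risks$rr_chd_treatment <- uncertain(1)
  p$risks$rr_stroke_treatment <- uncertain(1)
  p$risks$mort_rr_untreated <- uncertain(1)
  p$dw$untreated <- uncertain(0.323)
  p$dw$treated_controlled <- uncertain(0.323)
  p$dw$treated_uncontrolled <- uncertain(0.323)
  fit <- htn_cea(p)
  for (r in fit$strata) {
    tt <- trace_to_tallies(r$treated$trace)
    tu <- trace_to_tallies(r$untreated$trace)
    expect_equal(unname(tt$deaths), unname(tu$deaths), tolerance = 1e-9)
    expect_equal(unname(tt$events), unname(tu$events), tolerance = 1e-9)
  }
  expect_equal(fit$comparison$dalys_treated, fit$comparison$dalys_untreated,
               tolerance = 1e-9)
})

test_that("fitted model satisfies cohort invariants and reports a
           coherent summary", {
  p <- small_book(cycles = 20)
  fit <- htn_cea(p)
  for (r in fit$strata) for (arm in c("treated", "untreated")) {
    tr <- r[[arm]]$trace
    expect_equal(unname(rowSums(tr)), rep(r$stratum$population,
                 nrow(tr)), tolerance = 1e-6)
    expect_true(all(diff(tr[, "dead"]) >= -1e-12))
    expect_true(all(tr >= -1e-9))
  }
  # treatment averts DALYs under the default effect sizes
  expect_gt(fit$comparison$delta_dalys, 0)
  # by-band table is internally consistent
  bb <- fit$by_band
  expect_equal(bb$incremental_cost, bb$cost_untreated - bb$cost_treated)
  expect_equal(bb$icer, bb$incremental_cost / bb$incremental_dalys)
  s <- summary(fit)
  expect_s3_class(s, "summary.htn_cea")
  expect_output(print(s), "ICER")
  expect_output(print(fit), "DALYs averted")
})

test_that("pill disutility raises treated-arm DALYs, lag delays the
           effect, and adherence attenuates it", {
  p <- small_book(cycles = 15)
  base <- htn_cea(p)
  pill <- htn_cea(apply_scenario(p, list(pill_disutility = TRUE)))
  expect_gt(pill$comparison$dalys_treated, base$comparison$dalys_treated)
  expect_equal(pill$comparison$dalys_untreated,
               base$comparison$dalys_untreated)
  # a 1-year lag suspends the risk reduction in cycle 1 only: first-cycle
  # treated-arm events rise, later cycles are driven by occupancy alone
  lag <- htn_cea(apply_scenario(p, list(lag_years = 1)))
  ev_lag <- trace_to_tallies(lag$strata[[1]]$treated$trace)$events
  ev_base <- trace_to_tallies(base$strata[[1]]$treated$trace)$events
  expect_gt(sum(ev_lag[1, ]), sum(ev_base[1, ]))
  expect_equal(trace_to_tallies(lag$strata[[1]]$untreated$trace)$events,
               trace_to_tallies(base$strata[[1]]$untreated$trace)$events)
  # halved adherence weakens the risk reduction: more treated-arm events
  adh <- htn_cea(apply_scenario(p, list(adherence = 0.5)))
  ev_adh <- trace_to_tallies(adh$strata[[1]]$treated$trace)$events
  expect_gt(sum(ev_adh), sum(ev_base))
  expect_gt(adh$comparison$delta_dalys, 0)
})

test_that("linear risk mode preserves overall risk but reshapes timing", {
  p <- small_book(cycles = 10)
  lin <- htn_cea(apply_scenario(p, list(linear_risk = TRUE)))
  con <- htn_cea(p)
  # both run and produce finite, different results
  expect_true(is.finite(lin$comparison$delta_dalys))
  expect_false(isTRUE(all.equal(lin$comparison$dalys_untreated,
                                con$comparison$dalys_untreated)))
  # early-cycle untreated events are rarer under linearly increasing risk
  ev_lin <- trace_to_tallies(lin$strata[[1]]$untreated$trace)$events
  ev_con <- trace_to_tallies(con$strata[[1]]$untreated$trace)$events
  expect_lt(sum(ev_lin[1, ]), sum(ev_con[1, ]))
})

test_that("plot methods run without error on fitted objects", {
  p <- small_book(cycles = 8)
  fit <- htn_cea(p)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_no_error(plot(fit, type = "trace"))
  expect_no_error(plot(fit, type = "ce"))
  psa <- simulate(fit, nsim = 4, seed = 2)
  expect_no_error(plot(psa, type = "scatter"))
  expect_no_error(plot(psa, type = "ceac", wtp_grid = c(0, 1000)))
  grDevices::dev.off()
  unlink(f)
})
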