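# Markov engine: risk annualisation, mortality combination, treatment
# effects, transition matrices, cohort runs, tallies; cross-checked
# against closed forms and an exhaustive path-enumeration oracle.

test_that("annualize_risk: constant mode matches the closed form and
           linear mode preserves the 10-year risk", {
  expect_equal(annualize_risk(0, "constant"), rep(0, 10))
  expect_equal(annualize_risk(0.2, "constant"),
               rep(1 - 0.8^(1 / 10), 10), tolerance = 1e-12)
  for (p10 in c(0.05, 0.2, 0.6, 0.95)) {
    sched <- annualize_risk(p10, "linear_increasing")
    expect_equal(diff(sched), rep(sched[1], 9), tolerance = 1e-9)
    expect_equal(prod(1 - sched), 1 - p10, tolerance = 1e-9)
  }
  expect_error(annualize_risk(1.2), "\\[0,1\\]")
})

test_that("combine_mortality is multiplicative on the survival scale", {
  expect_equal(combine_mortality(0, 0.3), 0.3)
  expect_equal(combine_mortality(0.01, 0.02), 0.0298)
  expect_equal(combine_mortality(1, 0.5), 1)
  expect_error(combine_mortality(-0.1, 0.5), "\\[0,1\\]")
})

test_that("apply_treatment_effect scales and clips", {
  expect_equal(apply_treatment_effect(0.1, 1), 0.1)
  expect_equal(apply_treatment_effect(0.1, 0.7), 0.07)
  expect_equal(apply_treatment_effect(0.8, 1.5), 1)
  expect_error(apply_treatment_effect(0.5, 0), "positive")
})

test_that("bp_response: no drugs is identity, 185 mmHg on four drugs
           lands near 143, interpolation and monotonicity hold", {
  expect_equal(bp_response(170, 0), 170)
  sbp <- bp_response(185, 4)
  expect_equal(sbp, 143, tolerance = 0.5)
  expect_gt(sbp, 140)   # four drugs still miss the <140 target
  # hand interpolation between the 150 and 160 rows (drops 7.9, 9.0)
  expect_equal(bp_response(155, 2), 155 - 2 * (7.9 + 9.0) / 2)
  # monotone in drugs and baseline
  drops <- vapply(0:4, function(k) bp_response(170, k), numeric(1))
  expect_true(all(diff(drops) < 0))
  base <- vapply(c(145, 155, 165, 180), function(b) bp_response(b, 3),
                 numeric(1))
  expect_true(all(diff(base) > 0))
  expect_error(bp_response(120, 1), "outside table range")
  expect_equal(bp_response(120, 1, extrapolate = TRUE),
               120 - 6.8)
})

test_that("build_transition_matrix honours the row contracts", {
  p <- small_book()
  st <- p$strata[1, ]
  sc <- treatment_scenario("treated")
  M <- build_transition_matrix(st, sc, p)
  expect_equal(rowSums(M), setNames(rep(1, nrow(M)), rownames(M)))
  expect_true(all(M >= 0 & M <= 1))
  # dead row is the identity row
  expect_equal(unname(M["dead", ]), as.numeric(htn_states() == "dead"))
  # tunnel contract: event rows split all mass between post and dead
  for (e in c("mi", "stroke")) {
    row <- M[paste0("event_", e), ]
    expect_equal(unname(row[paste0("post_", e)] + row["dead"]), 1)
  }
  # zero risks reduce to background mortality only
  p0 <- p
  for (s in c("male", "female")) {
    p0$risks$p10_chd[[s]][] <- 0
    p0$risks$p10_stroke[[s]][] <- 0
  }
  p0$risks$case_fatality[] <- 0
  p0$risks$mort_rr_untreated <- uncertain(1)
  p0$risks$post_event_mort_rr[] <- 1
  q <- p0$epi$background_mortality$male[["30-100"]]
  M0 <- build_transition_matrix(p0$strata[1, ],
                                treatment_scenario("untreated"), p0)
  H <- hand_mortality_matrix(htn_states(), q)
  # treated entry row splits to controlled/uncontrolled by design, and
  # event tunnels pass survivors to post-event instead of staying
  keep <- setdiff(htn_states(), c("treated", paste0("event_", c("mi", "ua",
                  "sa", "stroke", "tia"))))
  expect_equal(M0[keep, ], H[keep, ], tolerance = 1e-12)
  expect_equal(unname(M0["event_mi", "post_mi"]), 1 - q)
  # and with zero mortality the living rows reduce to the identity
  p0$epi$background_mortality$male[] <- 0
  Mi <- build_transition_matrix(p0$strata[1, ],
                                treatment_scenario("untreated"), p0)
  expect_equal(Mi[keep, ], diag(length(htn_states()))[match(keep,
               htn_states()), ], ignore_attr = TRUE)
  expect_equal(unname(Mi["event_stroke", "post_stroke"]), 1)
  # overloaded rows are rejected with the state named
  pbad <- p
  pbad$risks$p10_chd$male[] <- 1
  pbad$risks$p10_stroke$male[] <- 1
  pbad$epi$background_mortality$male[] <- 0.9
  expect_error(build_transition_matrix(pbad$strata[1, ],
                                       treatment_scenario("untreated"),
                                       pbad),
               "untreated")
})

test_that("run_cohort reproduces hand-computed chains and conserves
           mass", {
  states <- htn_states()
  S <- length(states)
  # identity matrix: constant trace
  I <- diag(S); dimnames(I) <- list(states, states)
  init <- setNames(c(rep(0, S - 2), 100, 0), states)  # all in post_tia
  tr <- run_cohort(I, init, 80)
  expect_equal(unname(tr[81, ]), unname(init))
  # two-state reduction: alive -> dead with p = 0.5
  M <- I
  M["untreated", "untreated"] <- 0.5
  M["untreated", "dead"] <- 0.5
  init2 <- setNames(numeric(S), states); init2["untreated"] <- 1
  tr2 <- run_cohort(M, init2, 2)
  expect_equal(unname(tr2[3, "dead"]), 0.75)
  expect_equal(rowSums(tr2), setNames(rep(1, 3), 0:2), tolerance = 1e-6)
  tl <- trace_to_tallies(tr2)
  expect_equal(unname(tl$deaths), c(0.5, 0.25))
  expect_equal(sum(tl$events), 0)
})

test_that("run_cohort matches exhaustive path enumeration on small
           random chains", {
  set.seed(7)
  for (rep in 1:5) {
    states <- c("a", "b", "c", "dead")
    M <- matrix(0, 4, 4, dimnames = list(states, states))
    for (i in 1:3) {
      w <- stats::rexp(4)
      M[i, ] <- w / sum(w)
    }
    M[4, 4] <- 1
    init <- setNames(stats::runif(4), states)
    cycles <- 5
    tr <- run_cohort(M, init, cycles)
    expect_equal(unname(tr[cycles + 1, ]),
                 unname(enum_occupancy(M, init, cycles)),
                 tolerance = 1e-12)
  }
})

test_that("model-built traces conserve mass, keep occupancy in range,
           and death is monotone", {
  p <- small_book(cycles = 30)
  for (arm in c("treated", "untreated")) {
    sc <- treatment_scenario(arm)
    M <- build_transition_matrix(p$strata[1, ], sc, p)
    init <- setNames(numeric(length(htn_states())), htn_states())
    init[if (arm == "treated") "treated" else "untreated"] <- 1000
    tr <- run_cohort(M, init, 30)
    expect_equal(unname(rowSums(tr)), rep(1000, 31), tolerance = 1e-6)
    expect_true(all(tr >= -1e-9 & tr <= 1000 + 1e-9))
    expect_true(all(diff(tr[, "dead"]) >= -1e-12))
  }
})

test_that("null treatment effect makes the controlled state equivalent
           to untreated risks", {
  p <- small_book(cycles = 20)
  p$risks$rr_chd_treatment <- uncertain(1)
  p$risks$rr_stroke_treatment <- uncertain(1)
  p$risks$mort_rr_untreated <- uncertain(1)
  sc_t <- treatment_scenario("treated", control_rate = 1,
                             rr_events = c(chd = 1, stroke = 1))
  sc_u <- treatment_scenario("untreated",
                             rr_events = c(chd = 1, stroke = 1))
  Mt <- build_transition_matrix(p$strata[1, ], sc_t, p)
  Mu <- build_transition_matrix(p$strata[1, ], sc_u, p)
  expect_equal(unname(Mt["controlled", setdiff(htn_states(), c("controlled",
               "untreated"))]),
               unname(Mu["untreated", setdiff(htn_states(), c("controlled",
               "untreated"))]),
               tolerance = 1e-12)
})

test_that("lowering an event probability never increases cumulative
           deaths", {
  p <- small_book(cycles = 25)
  deaths_at <- function(p10) {
    p$risks$p10_chd$male[] <- p10
    M <- build_transition_matrix(p$strata[1, ],
                                 treatment_scenario("untreated"), p)
    init <- setNames(numeric(length(htn_states())), htn_states())
    init["untreated"] <- 1
    tr <- run_cohort(M, init, 25)
    tr[26, "dead"]
  }
  set.seed(11)
  for (rep in 1:5) {
    lo <- stats::runif(1, 0, 0.4)
    hi <- lo + stats::runif(1, 0, 0.4)
    expect_lte(deaths_at(lo), deaths_at(hi) + 1e-12)
  }
})
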