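# Discrete-time cohort state-transition engine: treated/untreated
# hypertension, controlled/uncontrolled, acute CVD event tunnel states,
# post-event states, and absorbing death.

EVENT_TYPES <- c("mi", "ua", "sa", "stroke", "tia")

#' Model state space
#'
#' Ordered states of the cohort model. The five acute event states are
#' tunnels (occupied for exactly one cycle, so that acute management
#' costs and weights apply once); \code{dead} is the single absorbing
#' state.
#'
#' @return Character vector of state names.
#' @export
htn_states <- function() {
  c("untreated", "treated", "controlled", "uncontrolled",
    paste0("event_", EVENT_TYPES), paste0("post_", EVENT_TYPES), "dead")
}

living_states <- function() setdiff(htn_states(), "dead")
event_states <- function() paste0("event_", EVENT_TYPES)

#' Convert a 10-year risk to an annual probability schedule
#'
#' @param p10 Ten-year cumulative event probability in \code{[0,1]}.
#' @param mode \code{"constant"}: the same annual probability
#'   \code{1 - (1 - p10)^(1/10)} in every year. \code{"linear_increasing"}:
#'   ten annual probabilities increasing linearly from year 1 to 10
#'   (\code{p_t = s t}) whose cumulative ten-year risk equals \code{p10};
#'   the slope is found by root-solving the survival product.
#' @return Numeric vector of 10 annual probabilities.
#' @export
annualize_risk <- function(p10, mode = c("constant", "linear_increasing")) {
  mode <- match.arg(mode)
  if (!is.finite(p10) || p10 < 0 || p10 > 1)
    stop("annualize_risk(): p10 must lie in [0,1]")
  if (p10 == 0) return(rep(0, 10))
  if (mode == "constant") return(rep(1 - (1 - p10)^(1 / 10), 10))
  if (p10 == 1) return(c(rep(0, 9), 1))
  f <- function(s) prod(1 - s * (1:10)) - (1 - p10)
  s <- stats::uniroot(f, c(0, 0.1), tol = 1e-14)$root
  s * (1:10)
}

#' Combine independent mortality sources
#'
#' Disease-related and disease-unrelated death probabilities are
#' combined multiplicatively on the survival scale:
#' \code{1 - (1 - p_background) (1 - p_disease)}.
#'
#' @param p_background,p_disease Annual death probabilities in
#'   \code{[0,1]}.
#' @return Combined annual death probability.
#' @export
combine_mortality <- function(p_background, p_disease) {
  if (any(!is.finite(c(p_background, p_disease))) ||
      any(c(p_background, p_disease) < 0) ||
      any(c(p_background, p_disease) > 1))
    stop("combine_mortality(): probabilities must lie in [0,1]")
  1 - (1 - p_background) * (1 - p_disease)
}

#' Apply a treatment relative risk to an event probability
#'
#' The same relative risk is assumed to act on every event type and
#' age/sex group; the product is clipped at 1.
#'
#' @param p_event Annual event probability in \code{[0,1]}.
#' @param rr Relative risk (> 0).
#' @return \code{min(1, rr * p_event)}.
#' @export
apply_treatment_effect <- function(p_event, rr) {
  if (any(p_event < 0) || any(p_event > 1))
    stop("apply_treatment_effect(): p_event must lie in [0,1]")
  if (any(rr <= 0)) stop("apply_treatment_effect(): rr must be positive")
  pmin(1, rr * p_event)
}

#' Expected on-treatment systolic blood pressure
#'
#' The systolic reduction per standard-dose agent is a function of the
#' pre-treatment level (larger drops at higher baselines), read from a
#' dose-response table by linear interpolation, and multiplied by the
#' number of agents. With the default table a patient at 185 mmHg on
#' four drugs reaches about 143 mmHg - above a 140 mmHg target.
#'
#' @param baseline_sbp Pre-treatment systolic pressure, mmHg.
#' @param n_drugs Number of standard-dose agents, 0 to 4.
#' @param effect_table Data frame with columns \code{baseline_sbp} and
#'   \code{drop_per_drug}; defaults to the book's table.
#' @param extrapolate If \code{FALSE} (default), a baseline outside the
#'   table range is an error; if \code{TRUE}, the edge value is used.
#' @return Expected on-treatment SBP in mmHg.
#' @export
bp_response <- function(baseline_sbp, n_drugs,
                        effect_table = default_parameters()$risks$bp_effect_table,
                        extrapolate = FALSE) {
  if (!(n_drugs %in% 0:4)) stop("bp_response(): n_drugs must be 0..4")
  if (n_drugs == 0) return(baseline_sbp)
  rng <- range(effect_table$baseline_sbp)
  if ((baseline_sbp < rng[1] || baseline_sbp > rng[2]) && !extrapolate)
    stop("bp_response(): baseline ", baseline_sbp,
         " mmHg outside table range [", rng[1], ", ", rng[2],
         "]; set extrapolate = TRUE to clamp")
  drop <- stats::approx(effect_table$baseline_sbp, effect_table$drop_per_drug,
                        xout = min(max(baseline_sbp, rng[1]), rng[2]),
                        rule = 2)$y
  baseline_sbp - n_drugs * drop
}

#' Define a treatment scenario
#'
#' @param label \code{"treated"} or \code{"untreated"} (the null,
#'   natural-history comparator).
#' @param control_rate Fraction of the treated arm reaching the BP
#'   target.
#' @param rr_events Named relative risks \code{c(chd = , stroke = )} on
#'   treatment versus no treatment.
#' @param adherence Adherence multiplier \code{a} in \code{[0,1]}; the
#'   effective relative risk is \code{1 - a (1 - rr)} so that
#'   \code{a = 1} reproduces trial efficacy and \code{a = 0} abolishes
#'   the treatment effect.
#' @param lag_years Whole years before the treated arm attains the
#'   target-BP risk reduction; during the lag the arm faces untreated
#'   event risks.
#' @return A list of class \code{"htn_scenario"}.
#' @export
treatment_scenario <- function(label = c("treated", "untreated"),
                               control_rate = 0.70,
                               rr_events = c(chd = 0.78, stroke = 0.62),
                               adherence = 1, lag_years = 0) {
  label <- match.arg(label)
  if (control_rate < 0 || control_rate > 1)
    stop("treatment_scenario(): control_rate must lie in [0,1]")
  if (any(rr_events <= 0)) stop("treatment_scenario(): rr must be positive")
  if (adherence < 0 || adherence > 1)
    stop("treatment_scenario(): adherence must lie in [0,1]")
  if (lag_years < 0) stop("treatment_scenario(): lag_years must be >= 0")
  structure(list(label = label, control_rate = control_rate,
                 rr_events = rr_events, adherence = adherence,
                 lag_years = lag_years),
            class = "htn_scenario")
}

# effective relative risk after adherence scaling
effective_rr <- function(rr, adherence) 1 - adherence * (1 - rr)

band_label <- function(age_low, age_high) paste0(age_low, "-", age_high)

# annual event probabilities for one stratum at a given model cycle
stratum_event_probs <- function(sex, band, params, cycle = 1) {
  mode <- params$risks$risk_mode
  yr <- if (mode == "constant") 1 else ((cycle - 1) %% 10) + 1
  p_chd <- annualize_risk(params$risks$p10_chd[[sex]][[band]], mode)[yr]
  p_cvd <- annualize_risk(params$risks$p10_stroke[[sex]][[band]], mode)[yr]
  c(mi = p_chd * params$risks$chd_split[["mi"]],
    ua = p_chd * params$risks$chd_split[["ua"]],
    sa = p_chd * params$risks$chd_split[["sa"]],
    stroke = p_cvd * params$risks$cvd_split[["stroke"]],
    tia = p_cvd * params$risks$cvd_split[["tia"]])
}

#' Build the one-cycle transition matrix for a stratum
#'
#' Rows sum to one: the residual mass after event and death transitions
#' remains in the current state. Acute event rows are tunnels that pass
#' all surviving mass to the matching post-event state; the dead row is
#' the identity row. Treated-arm risk reductions apply to the controlled
#' state (and, optionally, to the uncontrolled state); during a target-BP
#' lag the reduction is suspended.
#'
#' @param stratum A row of \code{params$strata} (or a list with
#'   \code{sex}, \code{age_low}, \code{age_high}).
#' @param scenario A \code{\link{treatment_scenario}}.
#' @param params An \code{"htn_params"} book.
#' @param cycle Model cycle (1-based); matters for linearly increasing
#'   risk and for the treatment lag.
#' @return A square matrix over \code{\link{htn_states}}.
#' @export
build_transition_matrix <- function(stratum, scenario, params, cycle = 1) {
  states <- htn_states()
  S <- length(states)
  M <- matrix(0, S, S, dimnames = list(states, states))
  sex <- stratum$sex
  band <- band_label(stratum$age_low, stratum$age_high)
  q_bg <- params$epi$background_mortality[[sex]][[band]]
  if (is.null(q_bg) || is.na(q_bg))
    stop("build_transition_matrix(): no background mortality for ",
         sex, " ", band)
  p_ev <- stratum_event_probs(sex, band, params, cycle)
  in_lag <- scenario$label == "treated" && cycle <= scenario$lag_years
  rr_chd <- effective_rr(scenario$rr_events[["chd"]], scenario$adherence)
  rr_str <- effective_rr(scenario$rr_events[["stroke"]], scenario$adherence)
  if (in_lag) rr_chd <- rr_str <- 1
  rr_vec <- c(mi = rr_chd, ua = rr_chd, sa = rr_chd,
              stroke = rr_str, tia = rr_str)
  p_ev_rx <- apply_treatment_effect(p_ev, rr_vec)
  q_unt <- min(1, q_bg * params$risks$mort_rr_untreated$mean)
  q_ctl <- min(1, q_bg * params$risks$mort_rr_controlled)

  fill_row <- function(state, dest) {
    tot <- sum(dest)
    if (tot > 1 + 1e-12)
      stop("build_transition_matrix(): probabilities for state '", state,
           "' sum to ", signif(tot, 6), " > 1")
    M[state, names(dest)] <<- dest
    M[state, state] <<- M[state, state] + (1 - tot)
  }

  ev_dest <- function(p) stats::setNames(p, paste0("event_", EVENT_TYPES))

  # untreated natural history: full event risks, excess mortality
  fill_row("untreated", c(ev_dest(p_ev), dead = q_unt))
  # treated entry state: classified into controlled/uncontrolled in one
  # cycle, facing background mortality only during classification
  cr <- scenario$control_rate
  fill_row("treated", c(controlled = cr * (1 - q_bg),
                        uncontrolled = (1 - cr) * (1 - q_bg),
                        dead = q_bg))
  M["treated", "treated"] <- 0   # entry state fully vacated
  # controlled: treatment-reduced event risks, background mortality
  fill_row("controlled", c(ev_dest(p_ev_rx), dead = q_ctl))
  # uncontrolled: untreated risks unless partial effect is enabled
  p_unc <- if (isTRUE(params$model$rr_applies_to_uncontrolled)) p_ev_rx
           else p_ev
  fill_row("uncontrolled", c(ev_dest(p_unc), dead = q_unt))
  # tunnels: survivors of the acute cycle all move to post-event
  for (e in EVENT_TYPES) {
    d <- combine_mortality(q_bg, params$risks$case_fatality[[e]])
    M[paste0("event_", e), "dead"] <- d
    M[paste0("event_", e), paste0("post_", e)] <- 1 - d
  }
  # post-event: elevated background mortality, otherwise stay
  for (e in EVENT_TYPES) {
    q <- min(1, q_bg * params$risks$post_event_mort_rr[[e]])
    M[paste0("post_", e), "dead"] <- q
    M[paste0("post_", e), paste0("post_", e)] <- 1 - q
  }
  M["dead", "dead"] <- 1
  validate_transition_matrix(M)
  M
}

validate_transition_matrix <- function(M) {
  if (any(M < -1e-12) || any(M > 1 + 1e-12))
    stop("transition matrix entries must lie in [0,1]")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition matrix rows must sum to 1 (worst: ",
         rownames(M)[which.max(abs(rs - 1))], ")")
  invisible(M)
}

#' Run the cohort through the model
#'
#' Left-multiplies the initial occupancy vector through the per-cycle
#' transition matrices. State membership is counted at cycle start (no
#' half-cycle correction).
#'
#' @param matrices A single transition matrix (used every cycle) or a
#'   list of length \code{cycles}.
#' @param init Named non-negative occupancy vector over the state space.
#' @param cycles Number of one-year cycles (default 80).
#' @return A \code{(cycles + 1) x n_states} occupancy matrix of class
#'   \code{"htn_trace"}; row \code{k + 1} is occupancy after \code{k}
#'   cycles.
#' @export
run_cohort <- function(matrices, init, cycles = 80) {
  if (is.matrix(matrices)) matrices <- rep(list(matrices), cycles)
  if (length(matrices) != cycles)
    stop("run_cohort(): need one matrix per cycle (got ", length(matrices),
         " for ", cycles, " cycles)")
  states <- colnames(matrices[[1]])
  if (is.null(names(init))) names(init) <- states
  if (!identical(sort(names(init)), sort(states)))
    stop("run_cohort(): init states do not match matrix states")
  init <- init[states]
  if (any(init < 0)) stop("run_cohort(): init must be non-negative")
  trace <- matrix(0, cycles + 1, length(states),
                  dimnames = list(0:cycles, states))
  trace[1, ] <- init
  occ <- init
  for (k in seq_len(cycles)) {
    M <- matrices[[k]]
    validate_transition_matrix(M)
    occ <- as.numeric(occ %*% M)
    trace[k + 1, ] <- occ
  }
  structure(trace, class = c("htn_trace", "matrix", "array"))
}

#' Per-cycle tallies from a cohort trace
#'
#' Person-years in each living state use the cycle-start convention
#' (occupancy at the start of the cycle). Incident events in cycle
#' \code{k} are the tunnel-state occupancies at the end of that cycle
#' (tunnels are fully vacated every cycle, so end-of-cycle occupancy is
#' exactly that cycle's inflow). Deaths are the increase in absorbing
#' occupancy.
#'
#' @param trace An \code{"htn_trace"}.
#' @return A list of class \code{"htn_tallies"}: \code{person_years}
#'   (cycles x living states), \code{events} (cycles x event types),
#'   \code{deaths} (length cycles).
#' @export
trace_to_tallies <- function(trace) {
  cycles <- nrow(trace) - 1
  liv <- living_states()
  py <- trace[seq_len(cycles), liv, drop = FALSE]
  ev <- trace[seq_len(cycles) + 1, event_states(), drop = FALSE]
  colnames(ev) <- EVENT_TYPES
  deaths <- diff(trace[, "dead"])
  rownames(py) <- rownames(ev) <- names(deaths) <- seq_len(cycles)
  structure(list(person_years = py, events = ev, deaths = deaths),
            class = "htn_tallies")
}

#' @export
print.htn_trace <- function(x, ...) {
  cycles <- nrow(x) - 1
  cat(sprintf("Cohort trace: %d cycles, %d states, initial cohort %g\n",
              cycles, ncol(x), sum(x[1, ])))
  cat(sprintf("  dead at end: %g (%.1f%%)\n", x[nrow(x), "dead"],
              100 * x[nrow(x), "dead"] / max(sum(x[1, ]), 1e-300)))
  invisible(x)
}
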