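# Top-level model object: run the full treated-versus-untreated cohort
# analysis and expose it with the usual S3 surface.

band_for_age <- function(age, bands) {
  hit <- which(age >= bands$age_low & age < bands$age_high)
  if (length(hit) == 0) hit <- nrow(bands)   # clamp above the last band
  bands[hit[1], ]
}

# state disability weights for one arm (means; PSA replaces the
# uncertain entries with sampled point masses upstream)
state_weights <- function(params, arm) {
  dw <- params$dw
  w <- c(untreated = dw$untreated$mean,
         treated = dw$treated_uncontrolled$mean,
         controlled = dw$treated_controlled$mean,
         uncontrolled = dw$treated_uncontrolled$mean,
         stats::setNames(dw$event[EVENT_TYPES],
                         paste0("event_", EVENT_TYPES)),
         stats::setNames(dw$post_event[EVENT_TYPES],
                         paste0("post_", EVENT_TYPES)))
  if (arm == "treated" && isTRUE(params$model$apply_pill_disutility)) {
    pill <- dw$pill_disutility$mean
    for (s in c("treated", "controlled", "uncontrolled"))
      w[s] <- combine_dw(w[s], pill)
  }
  w[living_states()]
}

# run one stratum through one arm: trace, tallies, DALYs, costs
run_stratum_arm <- function(stratum, arm, params) {
  cycles <- params$model$cycles
  scenario <- treatment_scenario(
    label = arm,
    control_rate = params$epi$control_rate$mean,
    rr_events = c(chd = params$risks$rr_chd_treatment$mean,
                  stroke = params$risks$rr_stroke_treatment$mean),
    adherence = params$model$adherence,
    lag_years = if (arm == "treated") params$model$lag_years else 0)
  sex <- stratum$sex
  bands <- params$strata[params$strata$sex == sex, ]
  age0 <- (stratum$age_low + stratum$age_high) / 2
  cache <- list()
  matrices <- vector("list", cycles)
  ages <- age0 + (seq_len(cycles) - 1)
  for (t in seq_len(cycles)) {
    b <- band_for_age(ages[t], bands)
    key <- paste(band_label(b$age_low, b$age_high),
                 t <= scenario$lag_years,
                 if (params$risks$risk_mode == "constant") 1
                 else ((t - 1) %% 10) + 1)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_transition_matrix(b, scenario, params, cycle = t)
    matrices[[t]] <- cache[[key]]
  }
  # treated cohorts are classified at entry: the control rate splits the
  # arm into controlled/uncontrolled at time zero, which keeps equal-risk
  # arms exactly symmetric (the "treated" entry state is retained in the
  # state space for single-matrix work)
  init <- stats::setNames(rep(0, length(htn_states())), htn_states())
  if (arm == "treated") {
    cr <- scenario$control_rate
    init["controlled"] <- stratum$population * cr
    init["uncontrolled"] <- stratum$population * (1 - cr)
  } else {
    init["untreated"] <- stratum$population
  }
  trace <- run_cohort(matrices, init, cycles)
  tallies <- trace_to_tallies(trace)

  # burden: prevalence YLDs per cycle, YLLs at residual life expectancy
  w <- state_weights(params, arm)
  yld_t <- as.numeric(tallies$person_years[, names(w)] %*% w)
  le <- params$epi$life_expectancy[[sex]]
  rle <- pmax(le - ages, 0)
  yll_t <- tallies$deaths * rle
  out_disc <- if (isTRUE(params$costs$discount_outcomes))
    params$costs$discount_rate else 0
  dalys <- sum(discount(yll_t + yld_t, out_disc, seq_len(cycles) - 1))

  # costs (USD, discounted)
  cc <- params$costs
  fx <- cc$exchange_rate[["2021"]]
  on_rx <- rowSums(tallies$person_years[, c("treated", "controlled",
                                            "uncontrolled"), drop = FALSE])
  drug <- if (is_uncertain(cc$annual_drug_cost)) cc$annual_drug_cost$mean
          else cc$annual_drug_cost
  e <- cc$employment_rate[[sex]]
  time_cost_etb <- cc$annual_visits *
    (e * cc$daily_wage_patient + (1 - e) * cc$daily_wage_unemployed)
  nonmed_usd <- convert_currency(
    cc$annual_visits * cc$transport_cost_per_visit + time_cost_etb, fx)
  treat_cost_t <- if (arm == "treated")
    on_rx * (drug * cc$antihypertensive_cost_multiplier +
             cc$annual_monitoring_cost +
             annual_outpatient_cost(cc$visit_cost_usd, cc$annual_visits) +
             cc$program_cost_per_person_annum + nonmed_usd)
  else rep(0, cycles)
  event_cost_t <- as.numeric(
    tallies$events[, EVENT_TYPES] %*% cc$event_cost_usd[EVENT_TYPES])
  post_py <- tallies$person_years[, paste0("post_", EVENT_TYPES),
                                  drop = FALSE]
  post_cost_t <- as.numeric(post_py %*% cc$post_event_annual_usd[EVENT_TYPES])
  indirect_usd_t <- convert_currency(
    vapply(seq_len(cycles), function(t)
      productivity_loss_annual(yll_t[t] + yld_t[t], sex, params),
      numeric(1)), fx)
  r <- cc$discount_rate
  tt <- seq_len(cycles) - 1
  cost <- sum(discount(treat_cost_t + event_cost_t + post_cost_t +
                       indirect_usd_t, r, tt))
  list(trace = trace, tallies = tallies, dalys = dalys, cost = cost,
       yll = sum(yll_t), yld = sum(yld_t),
       deaths = sum(tallies$deaths))
}

#' Run the hypertension treatment cost-effectiveness model
#'
#' Runs the Markov cohort model for every sex-by-age stratum under the
#' treated and untreated (null) scenarios, computes discounted societal
#' costs and DALYs per arm, and summarises incremental cost-
#' effectiveness overall and per age band.
#'
#' @param params An \code{"htn_params"} book; see
#'   \code{\link{default_parameters}}.
#' @param cycles Number of one-year cycles (defaults to the book's 80).
#' @return An object of class \code{"htn_cea"} with elements
#'   \code{params}, \code{strata} (per-stratum arm results),
#'   \code{by_band} (a Table-4-shaped data.frame), \code{comparison}
#'   (overall \code{\link{incremental}}), \code{icer}, \code{acer},
#'   \code{nmb} at the book's willingness-to-pay, and
#'   \code{classification}.
#' @examples
#' \donttest{
#' fit <- htn_cea()
#' summary(fit)
#' }
#' @export
htn_cea <- function(params = load_parameters(), cycles = NULL) {
  stopifnot(inherits(params, "htn_params"))
  if (!is.null(cycles)) params$model$cycles <- cycles
  validate_parameters(params)
  res <- vector("list", nrow(params$strata))
  for (i in seq_len(nrow(params$strata))) {
    st <- params$strata[i, ]
    res[[i]] <- list(
      stratum = st,
      treated = run_stratum_arm(st, "treated", params),
      untreated = run_stratum_arm(st, "untreated", params))
  }
  per <- do.call(rbind, lapply(res, function(r) data.frame(
    sex = r$stratum$sex,
    age_band = band_label(r$stratum$age_low, r$stratum$age_high),
    cost_treated = r$treated$cost, cost_untreated = r$untreated$cost,
    dalys_treated = r$treated$dalys, dalys_untreated = r$untreated$dalys,
    deaths_treated = r$treated$deaths,
    deaths_untreated = r$untreated$deaths,
    stringsAsFactors = FALSE)))
  agg <- function(v) tapply(per[[v]], per$age_band, sum)
  bands <- sort(unique(per$age_band))
  by_band <- data.frame(
    age_band = bands,
    cost_treated = as.numeric(agg("cost_treated")[bands]),
    cost_untreated = as.numeric(agg("cost_untreated")[bands]),
    dalys_treated = as.numeric(agg("dalys_treated")[bands]),
    dalys_untreated = as.numeric(agg("dalys_untreated")[bands]),
    stringsAsFactors = FALSE)
  by_band$incremental_cost <- by_band$cost_untreated - by_band$cost_treated
  by_band$incremental_dalys <- by_band$dalys_untreated - by_band$dalys_treated
  by_band$icer <- by_band$incremental_cost / by_band$incremental_dalys
  cmp <- incremental(sum(per$cost_treated), sum(per$cost_untreated),
                     sum(per$dalys_treated), sum(per$dalys_untreated))
  # headline ratio: for a dominant intervention report savings per DALY
  # averted (the source tables' orientation); otherwise the conventional
  # incurred-cost-per-DALY-averted ratio
  ic <- if (cmp$delta_dalys == 0) NA_real_
    else if (cmp$dominance == "intervention_dominant") icer(cmp)
    else cmp$cost_incurred / cmp$dalys_gained
  cls <- if (is.finite(ic) && ic >= 0 && cmp$dominance == "none")
    classify(ic, params$thresholds, "gdp_multiple") else NULL
  structure(list(params = params, strata = res, per_stratum = per,
                 by_band = by_band, comparison = cmp, icer = ic,
                 acer = if (cmp$delta_dalys > 0)
                   acer(cmp$cost_treated, cmp$delta_dalys) else NA_real_,
                 nmb = nmb(params$thresholds$wtp, cmp),
                 classification = cls),
            class = "htn_cea")
}

#' @export
print.htn_cea <- function(x, ...) {
  cat("Hypertension treatment cost-effectiveness (Markov cohort model)\n")
  cat(sprintf("  cohort: %s persons, %d cycles\n",
              format(sum(x$params$strata$population), big.mark = ","),
              x$params$model$cycles))
  cmp <- x$comparison
  cat(sprintf("  incremental cost (untreated - treated): %.2f USD\n",
              cmp$delta_cost))
  cat(sprintf("  DALYs averted: %.2f\n", cmp$delta_dalys))
  if (cmp$dominance == "intervention_dominant")
    cat("  treatment is dominant (saves cost and averts DALYs); the\n",
        " ratio below reads as savings per DALY averted\n")
  if (is.finite(x$icer))
    cat(sprintf("  ICER: %.2f USD per DALY averted\n", x$icer))
  if (!is.null(x$classification))
    cat(sprintf("  threshold class: %s\n",
                gsub("_", " ", x$classification$label)))
  invisible(x)
}

#' @export
summary.htn_cea <- function(object, ...) {
  out <- list(by_band = object$by_band,
              per_stratum = object$per_stratum,
              comparison = object$comparison,
              icer = object$icer, acer = object$acer,
              nmb = object$nmb, classification = object$classification)
  class(out) <- "summary.htn_cea"
  out
}

#' @export
print.summary.htn_cea <- function(x, ...) {
  cat("Incremental results by age band (USD, DALYs):\n")
  tab <- x$by_band
  tab[, -1] <- lapply(tab[, -1], function(v) round(v, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("\nOverall ICER: %.2f USD/DALY averted; ACER: %.2f; NMB at %s: %.2f\n",
              x$icer, x$acer, format(x$nmb$wtp, big.mark = ","), x$nmb$nmb))
  if (x$comparison$dominance != "none")
    cat("Dominance:", x$comparison$dominance, "\n")
  invisible(x)
}

#' Plot a fitted model
#'
#' \code{type = "trace"} shows state-occupancy curves for a stratum and
#' arm; \code{type = "ce"} shows the per-age-band incremental points on
#' the cost-effectiveness plane with the GDP-multiple threshold lines.
#'
#' @param x An \code{"htn_cea"} object.
#' @param type \code{"trace"} or \code{"ce"}.
#' @param stratum Stratum index for \code{type = "trace"}.
#' @param arm \code{"treated"} or \code{"untreated"}.
#' @param ... Passed to \code{matplot}/\code{plot}.
#' @export
plot.htn_cea <- function(x, type = c("trace", "ce"), stratum = 1,
                         arm = "treated", ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- x$strata[[stratum]][[arm]]$trace
    grp <- cbind(hypertensive = rowSums(tr[, c("untreated", "treated",
                                               "controlled",
                                               "uncontrolled")]),
                 post_event = rowSums(tr[, paste0("post_", EVENT_TYPES)]),
                 dead = tr[, "dead"])
    graphics::matplot(0:(nrow(tr) - 1), grp, type = "l", lty = 1,
                      xlab = "cycle (years)", ylab = "persons",
                      main = sprintf("%s arm, %s %s", arm,
                                     x$strata[[stratum]]$stratum$sex,
                                     band_label(
                                       x$strata[[stratum]]$stratum$age_low,
                                       x$strata[[stratum]]$stratum$age_high)),
                      ...)
    graphics::legend("right", colnames(grp), col = 1:3, lty = 1, bty = "n")
  } else {
    tab <- x$by_band
    de <- tab$incremental_dalys
    dc <- -tab$incremental_cost   # incurred orientation for the plane
    graphics::plot(de, dc, pch = 19,
                   xlab = "DALYs averted", ylab = "incremental cost (USD)",
                   main = "Cost-effectiveness plane by age band", ...)
    graphics::abline(h = 0, v = 0, col = "grey")
    for (m in x$params$thresholds$ce_band)
      graphics::abline(0, m, lty = 2, col = "grey40")
    graphics::text(de, dc, tab$age_band, pos = 3, cex = 0.8)
  }
  invisible(x)
}
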