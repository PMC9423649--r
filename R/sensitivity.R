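# Deterministic and probabilistic sensitivity analysis: scenario
# transforms, one-way bound-to-bound runs, Monte Carlo parameter
# sampling, uncertainty intervals, and the acceptability curve.

#' Apply a named scenario transform to a parameter book
#'
#' Supported keys: \code{adherence} (multiplier on the achieved relative
#' risk reduction), \code{lag_years} (delay before the treated arm
#' attains the target-BP risk reduction), \code{pill_disutility}
#' (\code{TRUE} to fold the pill-taking weight into treated-state
#' disability weights, or a numeric weight to use), \code{linear_risk}
#' (\code{TRUE} switches the annual-risk derivation to the linearly
#' increasing 10-year profile), \code{discount_rate},
#' \code{discount_outcomes}.
#'
#' @param params An \code{"htn_params"} book.
#' @param scenario Named list of scenario keys; empty returns the book
#'   unchanged.
#' @return A transformed copy of \code{params}.
#' @export
apply_scenario <- function(params, scenario = list()) {
  stopifnot(inherits(params, "htn_params"))
  known <- c("adherence", "lag_years", "pill_disutility", "linear_risk",
             "discount_rate", "discount_outcomes")
  bad <- setdiff(names(scenario), known)
  if (length(bad))
    stop("apply_scenario(): unknown scenario key(s): ",
         paste(bad, collapse = ", "))
  for (key in names(scenario)) {
    v <- scenario[[key]]
    params <- switch(key,
      adherence = param_set(params, "model.adherence", v),
      lag_years = param_set(params, "model.lag_years", v),
      pill_disutility = {
        if (is.numeric(v))
          params <- param_set(params, "dw.pill_disutility", v)
        param_set(params, "model.apply_pill_disutility",
                  isTRUE(v) || is.numeric(v))
      },
      linear_risk = param_set(params, "risks.risk_mode",
                              if (isTRUE(v)) "linear_increasing"
                              else "constant"),
      discount_rate = param_set(params, "costs.discount_rate", v),
      discount_outcomes = param_set(params, "costs.discount_outcomes", v))
  }
  params
}

#' Default evaluation pipeline
#'
#' Runs \code{\link{htn_cea}} and reduces it to the quantities tracked
#' by the sensitivity analyses.
#'
#' @param params An \code{"htn_params"} book.
#' @return A list: \code{delta_cost}, \code{delta_dalys} (comparator
#'   minus intervention), \code{icer}, \code{nmb} at the book's WTP.
#' @export
pipeline_default <- function(params) {
  fit <- htn_cea(params)
  list(delta_cost = fit$comparison$delta_cost,
       delta_dalys = fit$comparison$delta_dalys,
       icer = fit$icer, nmb = fit$nmb$nmb)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the pipeline with one parameter at its lower and upper bound,
#' everything else at base case.
#'
#' @param params Base-case book.
#' @param key Dotted parameter path (see \code{\link{param_set}}).
#' @param low,high Bound values (\code{low <= high}).
#' @param pipeline Function of a book returning at least \code{icer} and
#'   \code{nmb}; default \code{\link{pipeline_default}}.
#' @return A list of class \code{"htn_dsa"} with base/low/high pipeline
#'   results.
#' @export
one_way_dsa <- function(params, key, low, high,
                        pipeline = pipeline_default) {
  if (low > high) stop("one_way_dsa(): low must be <= high")
  base <- pipeline(params)
  at <- function(v) pipeline(param_set(params, key, v))
  structure(list(parameter = key, low = low, high = high,
                 base = base, at_low = at(low), at_high = at(high)),
            class = "htn_dsa")
}

#' @export
print.htn_dsa <- function(x, ...) {
  cat(sprintf("One-way DSA on %s [%g, %g]\n", x$parameter, x$low, x$high))
  cat(sprintf("  ICER base %.2f | low %.2f | high %.2f\n",
              x$base$icer, x$at_low$icer, x$at_high$icer))
  invisible(x)
}

# default set of jointly sampled parameters
psa_default_include <- function(params) {
  keys <- c("risks.rr_chd_treatment", "risks.rr_stroke_treatment",
            "risks.mort_rr_untreated", "dw.hypertensive_heart_disease",
            "dw.treated_uncontrolled", "costs.annual_drug_cost",
            "costs.monthly_wage_unemployed")
  if (isTRUE(params$model$apply_pill_disutility))
    keys <- c(keys, "dw.pill_disutility")
  keys
}

#' Probabilistic sensitivity analysis
#'
#' Samples every included uncertain parameter from its fitted
#' distribution (see \code{\link{expand_uncertain}}) independently,
#' re-evaluates the pipeline per draw, and summarises the (incremental
#' cost, incremental DALY) cloud. Point-mass parameters reproduce the
#' deterministic run exactly, so an all-point book yields a degenerate
#' cloud identical to the base case.
#'
#' @param params Base-case book.
#' @param n_draws Number of Monte Carlo draws (the study used 1000).
#' @param seed RNG seed; the draw table is fully reproducible from it.
#' @param pipeline As in \code{\link{one_way_dsa}}.
#' @param include Character vector of dotted parameter paths to sample;
#'   defaults to the treatment-effect, mortality, disability-weight and
#'   cost parameters.
#' @return An object of class \code{"htn_psa"}: \code{draws} (one row
#'   per draw with sampled values and outputs), \code{ui} (95\%
#'   uncertainty intervals), \code{fraction_cost_saving}, and
#'   \code{quadrants}.
#' @export
run_psa <- function(params, n_draws = 1000, seed = 20200901,
                    pipeline = pipeline_default,
                    include = psa_default_include(params)) {
  stopifnot(n_draws >= 1)
  dists <- lapply(include, function(k) {
    p <- param_get(params, k)
    if (!is_uncertain(p))
      stop("run_psa(): parameter '", k, "' has no sampling specification")
    expand_uncertain(p)
  })
  names(dists) <- include
  set.seed(seed)
  samples <- vapply(dists, sample_dist, numeric(n_draws), n = n_draws)
  if (n_draws == 1) samples <- matrix(samples, 1,
                                      dimnames = list(NULL, include))
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    pd <- params
    for (k in include) pd <- param_set(pd, k, samples[d, k])
    out <- pipeline(pd)
    rows[[d]] <- data.frame(draw = d, delta_cost = out$delta_cost,
                            delta_dalys = out$delta_dalys,
                            icer = out$icer, nmb = out$nmb)
  }
  draws <- cbind(do.call(rbind, rows), as.data.frame(samples))
  ui <- lapply(c(delta_cost = "delta_cost", delta_dalys = "delta_dalys",
                 icer = "icer", nmb = "nmb"),
               function(v) uncertainty_interval(draws[[v]]))
  quad <- c(
    dominant = mean(draws$delta_cost > 0 & draws$delta_dalys > 0),
    costly_effective = mean(draws$delta_cost < 0 & draws$delta_dalys > 0),
    dominated = mean(draws$delta_cost < 0 & draws$delta_dalys < 0),
    saving_harmful = mean(draws$delta_cost > 0 & draws$delta_dalys < 0))
  structure(list(n_draws = n_draws, seed = seed, draws = draws,
                 ui = if (n_draws >= 2) ui else NULL,
                 fraction_cost_saving = mean(draws$delta_cost > 0),
                 quadrants = quad),
            class = "htn_psa")
}

#' @export
print.htn_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  cost saving in %.1f%% of draws\n",
              100 * x$fraction_cost_saving))
  if (!is.null(x$ui))
    cat(sprintf("  incremental DALYs averted 95%% UI: [%.2f, %.2f]\n",
                x$ui$delta_dalys[1], x$ui$delta_dalys[2]))
  invisible(x)
}

#' Empirical uncertainty interval
#'
#' Central interval from the empirical percentiles with linear
#' interpolation between order statistics (\code{quantile} type 7).
#'
#' @param draws Numeric vector with at least 2 draws.
#' @param level Coverage level, default 0.95.
#' @return Length-2 vector \code{c(low, high)}.
#' @export
uncertainty_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2)
    stop("uncertainty_interval(): need at least 2 draws")
  if (level <= 0 || level >= 1)
    stop("uncertainty_interval(): level must lie in (0,1)")
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), type = 7, names = FALSE))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit. At \code{wtp = 0} this is the fraction
#' of cost-saving draws; as \code{wtp} grows it converges to the
#' fraction of draws with positive DALYs averted.
#'
#' @param psa An \code{"htn_psa"}.
#' @param wtp_grid Non-empty numeric vector of WTP values (USD/DALY).
#' @return A data.frame of class \code{"htn_ceac"} with columns
#'   \code{wtp} and \code{prob_cost_effective}.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "htn_psa"))
  if (length(wtp_grid) == 0) stop("ceac(): wtp grid must be non-empty")
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_dalys + psa$draws$delta_cost > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_cost_effective = prob)
  class(out) <- c("htn_ceac", "data.frame")
  out
}

#' Plot PSA results
#'
#' @param x An \code{"htn_psa"}.
#' @param type \code{"scatter"} for the cost-effectiveness plane cloud,
#'   \code{"ceac"} for the acceptability curve.
#' @param wtp_grid WTP grid for \code{type = "ceac"}.
#' @param ... Passed to the underlying plot.
#' @export
plot.htn_psa <- function(x, type = c("scatter", "ceac"),
                         wtp_grid = seq(0, 5000, by = 100), ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    graphics::plot(x$draws$delta_dalys, -x$draws$delta_cost, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.5),
                   xlab = "DALYs averted",
                   ylab = "incremental cost incurred (USD)",
                   main = "PSA scatter", ...)
    graphics::abline(h = 0, v = 0, col = "grey")
  } else {
    cv <- ceac(x, wtp_grid)
    graphics::plot(cv$wtp, cv$prob_cost_effective, type = "l",
                   ylim = c(0, 1), xlab = "willingness to pay (USD/DALY)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
  }
  invisible(x)
}

#' Simulate (PSA) method for fitted models
#'
#' \code{simulate} on a fitted \code{\link{htn_cea}} object runs the
#' probabilistic sensitivity analysis around its parameter book.
#'
#' @param object An \code{"htn_cea"} fit.
#' @param nsim Number of PSA draws.
#' @param seed RNG seed.
#' @param ... Passed to \code{\link{run_psa}}.
#' @return An \code{"htn_psa"} object.
#' @export
simulate.htn_cea <- function(object, nsim = 1000, seed = 20200901, ...) {
  run_psa(object$params, n_draws = nsim, seed = seed, ...)
}
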