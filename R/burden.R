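# YLL / YLD / DALY accounting under GBD-2010 conventions: prevalence
# YLDs, no time discounting, no age weights, multiplicative comorbidity
# adjustment.

#' Years lived with disability
#'
#' Prevalence approach: cases x duration till remission or death x
#' disability weight.
#'
#' @param cases Number of prevalent cases (>= 0).
#' @param duration Duration in years (>= 0).
#' @param dw Disability weight in \code{[0,1]}.
#' @return YLD in years; vectorised and additive over disjoint groups.
#' @export
yld <- function(cases, duration, dw) {
  if (any(cases < 0) || any(duration < 0))
    stop("yld(): cases and duration must be non-negative")
  if (any(dw < 0) || any(dw > 1)) stop("yld(): dw must lie in [0,1]")
  sum(cases * duration * dw)
}

#' Years of life lost
#'
#' Deaths x residual life expectancy at the age of death; with
#' age-specific inputs, the sum over ages.
#'
#' @param deaths Death counts (>= 0), scalar or per-age vector.
#' @param life_expectancy_at_death Residual life expectancy (years),
#'   matching \code{deaths} in length.
#' @return YLL in years.
#' @export
yll <- function(deaths, life_expectancy_at_death) {
  if (any(deaths < 0) || any(life_expectancy_at_death < 0))
    stop("yll(): inputs must be non-negative")
  sum(deaths * life_expectancy_at_death)
}

#' Disability-adjusted life years
#'
#' @param yll,yld Non-negative burden components in years.
#' @return Exact sum \code{yll + yld}.
#' @export
daly <- function(yll, yld) {
  if (any(yll < 0) || any(yld < 0)) stop("daly(): components must be >= 0")
  yll + yld
}

#' Combined prevalence of two independent conditions
#'
#' \code{P12 = P1 + P2 - P1 P2 = 1 - (1 - P1)(1 - P2)}, assuming
#' independence within an age-sex group.
#'
#' @param p1,p2 Prevalences in \code{[0,1]}.
#' @return Combined prevalence; symmetric, bounded by
#'   \code{[max(p1,p2), min(1, p1+p2)]}.
#' @export
combine_prevalence <- function(p1, p2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("combine_prevalence(): prevalences must lie in [0,1]")
  1 - (1 - p1) * (1 - p2)
}

#' Combined disability weight for comorbid conditions
#'
#' Multiplicative model: \code{DW12 = 1 - (1 - DW1)(1 - DW2)}. Used both
#' for true comorbidity and to add the pill-taking disutility onto
#' treated-state weights (keeping the result in \code{[0,1]}).
#'
#' @param dw1,dw2 Disability weights in \code{[0,1]}.
#' @return Combined weight; symmetric and subadditive.
#' @export
combine_dw <- function(dw1, dw2) {
  if (any(c(dw1, dw2) < 0) || any(c(dw1, dw2) > 1))
    stop("combine_dw(): weights must lie in [0,1]")
  1 - (1 - dw1) * (1 - dw2)
}

#' Combined per-person YLD rate for comorbid conditions
#'
#' \code{YLD12 = 1 - (1 - YLD1)(1 - YLD2)} for per-person YLD rates.
#' Absolute year totals (> 1) are rejected: the multiplicative
#' combination is only meaningful on the per-person rate scale.
#'
#' @param y1,y2 Per-person YLD rates in \code{[0,1]}.
#' @return Combined rate.
#' @export
combine_yld_rates <- function(y1, y2) {
  if (any(c(y1, y2) < 0) || any(c(y1, y2) > 1))
    stop("combine_yld_rates(): per-person YLD rates must lie in [0,1]; ",
         "absolute year totals are not valid inputs")
  1 - (1 - y1) * (1 - y2)
}

#' Construct a burden table
#'
#' @param cause,sex,age_band,year Index columns (recycled).
#' @param yll,yld Burden components in years.
#' @return A data.frame of class \code{"htn_burden"} with
#'   \code{daly = yll + yld}.
#' @export
burden_result <- function(cause, sex, age_band, year, yll, yld) {
  if (any(yll < 0) || any(yld < 0))
    stop("burden_result(): components must be >= 0")
  out <- data.frame(cause = cause, sex = sex, age_band = age_band,
                    year = year, yll = yll, yld = yld,
                    daly = yll + yld, stringsAsFactors = FALSE)
  class(out) <- c("htn_burden", "data.frame")
  out
}

#' Excess burden of the hypertensive cohort over the general population
#'
#' Element-wise subtraction of general-population burden from cohort
#' burden on matching (cause, sex, age_band, year) strata. Differences
#' are reported signed.
#'
#' @param cohort,general \code{"htn_burden"} tables with identical
#'   strata.
#' @return A data.frame with the same index columns and signed
#'   \code{yll}, \code{yld}, \code{daly} differences.
#' @export
excess_burden <- function(cohort, general) {
  idx <- c("cause", "sex", "age_band", "year")
  key <- function(d) do.call(paste, c(d[idx], sep = "\r"))
  if (nrow(cohort) != nrow(general) ||
      !identical(sort(key(cohort)), sort(key(general))))
    stop("excess_burden(): stratum mismatch between cohort and general ",
         "population tables")
  general <- general[match(key(cohort), key(general)), ]
  out <- cohort
  for (v in c("yll", "yld", "daly")) out[[v]] <- cohort[[v]] - general[[v]]
  class(out) <- "data.frame"
  out
}
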