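# Synthetic inputs: sample-size calculator, stratified cohorts,
# facility-allocated patient-level cost records, and PSA fixtures.
# Everything is fully determined by (specification, seed).

#' Single-population-proportion sample size
#'
#' \code{n0 = Z^2 p (1 - p) / d^2}, rounded to the nearest integer for
#' reporting; the non-response inflation is applied to that integer and
#' kept fractional (e.g. 203.5), then the design effect multiplies it
#' and the final value is rounded up to a whole participant. With the
#' default control-rate proportion of 14\%, 10\% non-response and a
#' design effect of 2 this reproduces the published chain
#' 185 -> 203.5 -> 407.
#'
#' @param p Anticipated proportion in (0,1); default 0.14 (the reported
#'   BP control rate; the alternative reading of 28.4\% treatment
#'   coverage yields a smaller n and is not the default).
#' @param z Standard normal deviate, default 1.96.
#' @param d Margin of error (> 0), default 0.05.
#' @param nonresponse_rate Non-response inflation fraction, default 0.
#' @param design_effect Design-effect multiplier (>= 1), default 1.
#' @return A list with \code{n0} (base integer), \code{adjusted}
#'   (fractional intermediate) and \code{n} (final integer).
#' @examples
#' sample_size(0.14, nonresponse_rate = 0.10, design_effect = 2)$n  # 407
#' @export
sample_size <- function(p = 0.14, z = 1.96, d = 0.05,
                        nonresponse_rate = 0, design_effect = 1) {
  if (p <= 0 || p >= 1) stop("sample_size(): p must lie in (0,1)")
  if (d <= 0) stop("sample_size(): margin of error d must be positive")
  if (design_effect < 1) stop("sample_size(): design effect must be >= 1")
  if (nonresponse_rate < 0 || nonresponse_rate >= 1)
    stop("sample_size(): nonresponse_rate must lie in [0,1)")
  n0 <- round(z^2 * p * (1 - p) / d^2)
  adjusted <- n0 * (1 + nonresponse_rate)
  # tolerance guards the ceiling against floating-point creep
  # (185 * 1.1 * 2 is 407 + 1e-13 in double arithmetic)
  final <- ceiling(adjusted * design_effect - 1e-9)
  list(n0 = n0, adjusted = adjusted, n = as.integer(final))
}

#' Generate a stratified synthetic hypertensive cohort
#'
#' Draws individual ages uniformly within each stratum band, assigns
#' treatment status at the coverage rate and, among the treated,
#' controlled status at the control rate. Expected stratum proportions
#' match the specification; the realisation is fully reproducible from
#' the seed.
#'
#' @param params An \code{"htn_params"} book supplying strata,
#'   treatment coverage and control rate.
#' @param n Total cohort size; defaults to the book's stratum
#'   populations.
#' @param seed RNG seed.
#' @return A data.frame (one row per person): \code{sex, age, age_band,
#'   treated, controlled}.
#' @export
generate_population <- function(params = default_parameters(), n = NULL,
                                seed = 20200901) {
  st <- params$strata
  if (sum(st$population) <= 0) stop("generate_population(): empty cohort")
  counts <- if (is.null(n)) st$population
            else round(st$population / sum(st$population) * n)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(st)), function(i) {
    k <- counts[i]
    if (k == 0) return(NULL)
    data.frame(sex = st$sex[i],
               age = stats::runif(k, st$age_low[i], st$age_high[i]),
               age_band = band_label(st$age_low[i], st$age_high[i]),
               stringsAsFactors = FALSE)
  })
  pop <- do.call(rbind, rows)
  cov <- params$epi$treatment_coverage$mean
  ctl <- params$epi$control_rate$mean
  pop$treated <- stats::runif(nrow(pop)) < cov
  pop$controlled <- pop$treated & (stats::runif(nrow(pop)) < ctl)
  rownames(pop) <- NULL
  pop
}

#' Generate patient-level cost-survey records
#'
#' Emulates a facility-based cost survey: patients allocated exactly to
#' facilities, each with age, sex, comorbidity flags, a sampled
#' antihypertensive regimen, Poisson visit counts, laboratory items and
#' occasional hospitalizations, every line priced from the unit-price
#' book.
#'
#' @param n Number of patients, default 407.
#' @param allocation Facility allocation summing to \code{n}; default
#'   \code{c(212, 107, 88)}.
#' @param price_book Unit-price data.frame; default the bundled book.
#' @param seed RNG seed.
#' @param comorbidity Named fractions \code{c(diabetes = , ckd = )}.
#' @return A list with \code{patients} (one row per patient) and
#'   \code{ledger} (an \code{"htn_ledger"} of priced line items).
#' @export
generate_patient_records <- function(n = 407, allocation = c(212, 107, 88),
                                     price_book = unit_price_book(),
                                     seed = 20200901,
                                     comorbidity = c(diabetes = 0.15,
                                                     ckd = 0.05)) {
  if (sum(allocation) != n)
    stop("generate_patient_records(): allocation must sum to n")
  if (n == 0)
    return(list(patients = data.frame(), ledger = cost_ledger()))
  set.seed(seed)
  facilities <- paste0("facility_", seq_along(allocation))
  drugs <- price_book[price_book$category == "drug", ]
  pat <- paste0("amlodipine|nifedipine|enalapril|captopril|hct|atenolol|",
                "methyldopa|hydrochlorothiazide")
  aht <- drugs[grepl(pat, drugs$item, ignore.case = TRUE), ]
  labs <- price_book[price_book$category == "lab", ]
  visit_price <- price_book$price_usd_2021[
    price_book$item == "visit_secondary_hospital"]
  bed_price <- price_book$price_usd_2021[
    price_book$item == "bed_day_secondary_hospital"]
  patients <- data.frame(
    patient_id = seq_len(n),
    facility = rep(facilities, allocation),
    age = pmax(30, round(stats::rnorm(n, 55, 12))),
    sex = sample(c("male", "female"), n, replace = TRUE),
    diabetes = stats::runif(n) < comorbidity[["diabetes"]],
    ckd = stats::runif(n) < comorbidity[["ckd"]],
    n_drugs = sample(1:3, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    visits = stats::rpois(n, 10) + 1,
    n_labs = stats::rpois(n, 3),
    hosp_days = stats::rpois(n, 0.4),
    stringsAsFactors = FALSE)
  lines <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- patients[i, ]
    reg <- aht[sample(nrow(aht), pt$n_drugs), ]
    lab <- if (pt$n_labs > 0) labs[sample(nrow(labs), pt$n_labs,
                                          replace = TRUE), ] else labs[0, ]
    lines[[i]] <- cost_ledger(
      category = c(rep("direct_medical",
                       pt$n_drugs + nrow(lab) + 1 +
                         (pt$hosp_days > 0))),
      item = c(reg$item, lab$item, "visit_secondary_hospital",
               if (pt$hosp_days > 0) "bed_day_secondary_hospital"),
      # annual packs: 365 tablets at the pack price per 100 tablets is
      # approximated as 4 packs/year per agent
      quantity = c(rep(4, pt$n_drugs), rep(1, nrow(lab)), pt$visits,
                   if (pt$hosp_days > 0) pt$hosp_days),
      unit_price = c(reg$price_usd_2021, lab$price_usd_2021, visit_price,
                     if (pt$hosp_days > 0) bed_price))
  }
  ledger <- do.call(rbind, lines)
  class(ledger) <- c("htn_ledger", "data.frame")
  list(patients = patients, ledger = ledger)
}

#' Generate a PSA parameter-draw fixture
#'
#' One row per draw with a column per sampled parameter; reproducible
#' from the seed, marginal means matching the book within Monte Carlo
#' error.
#'
#' @param params An \code{"htn_params"} book.
#' @param n_draws Number of draws.
#' @param seed RNG seed.
#' @param include Dotted paths of uncertain parameters to sample.
#' @return A data.frame with \code{draw} plus one column per parameter.
#' @export
generate_psa_fixture <- function(params = default_parameters(),
                                 n_draws = 1000, seed = 20200901,
                                 include = psa_default_include(params)) {
  dists <- lapply(include, function(k) expand_uncertain(param_get(params, k)))
  set.seed(seed)
  samples <- vapply(dists, sample_dist, numeric(n_draws), n = n_draws)
  if (n_draws == 1) samples <- matrix(samples, 1)
  colnames(samples) <- include
  cbind(data.frame(draw = seq_len(n_draws)), as.data.frame(samples))
}
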