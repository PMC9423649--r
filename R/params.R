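# Parameter book: every model input with its uncertainty range, plus
# loading, validation, override, and round-trip serialisation.

#' Unit price book
#'
#' Reads the bundled 2021 USD unit-price table (drug packs at regional
#' supply-hub retail prices, laboratory and imaging fees, WHO-CHOICE
#' facility visit and bed-day costs inflated to 2021, acute-episode and
#' annual outpatient costs, staff salaries).
#'
#' @param path Optional path to a CSV with columns
#'   \code{item, unit, price_usd_2021, category}; defaults to the
#'   bundled book.
#' @return A data.frame with one row per priced item.
#' @export
unit_price_book <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "unit_prices.csv", package = "htncea",
                        mustWork = TRUE)
  book <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "unit", "price_usd_2021", "category")
  if (!all(need %in% names(book)))
    stop("unit price book must have columns: ", paste(need, collapse = ", "))
  if (any(book$price_usd_2021 < 0)) stop("unit prices must be non-negative")
  book
}

#' Default model parameter book
#'
#' Returns the full default \code{ParameterSet}: epidemiology, disability
#' weights, transition-probability inputs, costs, and willingness-to-pay
#' thresholds for the Ethiopian adult hypertensive cohort. Epidemiology,
#' unit costs, wages, thresholds and headline disability weights are the
#' published study inputs; age-specific event risks, case fatalities and
#' background mortality are documented placeholder schedules (the study's
#' supplementary tables are not public) and are fully configurable.
#'
#' Strata are sex by half-open age band; default bands
#' \code{[30,40) [40,65) [65,100)} with a cohort of 100,000 hypertensive
#' adults split by the national age structure and a 50/50 sex ratio.
#'
#' @return A list of class \code{"htn_params"}. Sections:
#'   \code{strata}, \code{epi}, \code{risks}, \code{dw}, \code{costs},
#'   \code{thresholds}, \code{model}.
#' @export
default_parameters <- function() {
  strata <- data.frame(
    sex = rep(c("male", "female"), each = 3),
    age_low = rep(c(30, 40, 65), 2),
    age_high = rep(c(40, 65, 100), 2),
    population = rep(c(17000, 26000, 7000), 2),
    stringsAsFactors = FALSE)

  epi <- list(
    # prevalence bands as published (15-30 retained for population work
    # even though the model cohort starts at 30)
    prevalence_by_band = c("15-30" = 0.196, "30-40" = 0.230,
                           "40-49" = 0.259, "50+" = 0.419),
    mean_prevalence = 0.2139,
    treatment_coverage = uncertain(0.284, 0.25, 0.32, "beta"),
    control_rate = uncertain(0.70, 0.50, 0.70, "point"),
    rr_mortality_htn = uncertain(1.39, 0.95, 1.95, "lognormal"),
    rr_high_bp = uncertain(3.13, 2.91, 3.37, "lognormal"),
    hr_high_bp = uncertain(2.96, 2.56, 3.42, "lognormal"),
    crude_death_rate = 6.29,             # deaths / 1000 / year
    life_expectancy = c(male = 66.7, female = 70.4),
    # annual all-cause background mortality per age band and sex;
    # placeholder schedule consistent with the 6.29/1000 crude rate
    background_mortality = list(
      male = c("30-40" = 0.0030, "40-65" = 0.0085, "65-100" = 0.0450),
      female = c("30-40" = 0.0024, "40-65" = 0.0065, "65-100" = 0.0400)),
    # annual probability a normotensive re-enters the hypertensive pool;
    # asserted qualitatively in the source model, never quantified
    incidence_normotensive = 0)

  risks <- list(
    # 10-year first-event probabilities by age band (placeholders in the
    # Framingham range for an untreated hypertensive cohort)
    p10_chd = list(male = c("30-40" = 0.030, "40-65" = 0.110,
                            "65-100" = 0.240),
                   female = c("30-40" = 0.015, "40-65" = 0.070,
                              "65-100" = 0.180)),
    p10_stroke = list(male = c("30-40" = 0.012, "40-65" = 0.055,
                               "65-100" = 0.160),
                      female = c("30-40" = 0.010, "40-65" = 0.050,
                                 "65-100" = 0.150)),
    risk_mode = "constant",              # or "linear_increasing"
    # allocation of incident CHD to MI / unstable / stable angina and of
    # cerebrovascular events to stroke / TIA
    chd_split = c(mi = 0.45, ua = 0.25, sa = 0.30),
    cvd_split = c(stroke = 0.80, tia = 0.20),
    # one-cycle case fatality in the event tunnel states
    case_fatality = c(mi = 0.30, ua = 0.08, sa = 0.02,
                      stroke = 0.25, tia = 0.01),
    # multiplier on background mortality in post-event states
    post_event_mort_rr = c(mi = 2.5, ua = 1.8, sa = 1.4,
                           stroke = 2.8, tia = 1.2),
    # treatment effect: relative risk of events on treatment, from
    # meta-analyses of BP-lowering trials
    rr_chd_treatment = uncertain(0.78, 0.70, 0.87, "lognormal"),
    rr_stroke_treatment = uncertain(0.62, 0.53, 0.72, "lognormal"),
    # all-cause mortality multiplier by BP state (controlled referenced
    # to background; untreated/uncontrolled carry the excess)
    mort_rr_untreated = uncertain(1.39, 0.95, 1.95, "lognormal"),
    mort_rr_controlled = 1.0,
    # standard-dose BP response: SBP drop per drug by baseline SBP
    bp_effect_table = data.frame(
      baseline_sbp = c(140, 150, 160, 170, 185),
      drop_per_drug = c(6.8, 7.9, 9.0, 9.8, 10.5)))

  dw <- list(
    hypertensive_heart_disease = uncertain(0.246, 0.201, 0.300, "beta"),
    untreated = uncertain(0.323, 0.323, 0.323, "point"),
    treated_controlled = uncertain(0.171, 0.171, 0.171, "point"),
    treated_uncontrolled = uncertain(0.246, 0.201, 0.300, "beta"),
    pill_disutility = uncertain(0.049, 0.031, 0.072, "beta"),
    # event / post-event weights (GBD-style placeholders)
    event = c(mi = 0.432, ua = 0.130, sa = 0.080,
              stroke = 0.316, tia = 0.070),
    post_event = c(mi = 0.080, ua = 0.080, sa = 0.049,
                   stroke = 0.190, tia = 0.020))

  costs <- list(
    unit_price_book = unit_price_book(),
    exchange_rate = c("2016" = 20.999, "2021" = 43.5),  # ETB per USD
    inflation_factor = 1.372,            # 2015 -> 2021 ETB
    discount_rate = 0.03,
    discount_rate_alt = 0.06,
    discount_outcomes = FALSE,
    employment_rate = c(male = 0.88, female = 0.33),
    monthly_income_employed = 2059.078,  # ETB, inflation-adjusted
    monthly_wage_unemployed = uncertain(796, 420, 1172, "gamma"),  # ETB
    daily_wage_patient = 97.00,          # ETB, time cost of care
    daily_wage_unemployed = 26.53,       # ETB
    transport_cost_per_visit = 42.00,    # ETB
    annual_visits = 12,
    # annual treated-state medication cost in USD; placeholder built
    # from dual low-dose therapy at book prices, +/-20% in DSA
    annual_drug_cost = uncertain(16.0, 12.8, 19.2, "gamma"),
    annual_monitoring_cost = 10.0,       # labs + ECG, USD
    antihypertensive_cost_multiplier = 1.0,
    visit_cost_usd = 0.49,               # secondary-hospital visit
    # acute-episode cost per incident event (MI and stroke from the
    # price book; UA/SA/TIA scaled placeholders)
    event_cost_usd = c(mi = 1040, ua = 520, sa = 45,
                       stroke = 940, tia = 235),
    # annual outpatient cost per post-event person-year
    post_event_annual_usd = c(mi = 45, ua = 45, sa = 45,
                              stroke = 67, tia = 67),
    program_national_annual = 34158641.24,  # USD
    program_population_proportion = 0.03,
    program_cost_per_person_annum = 128.28) # USD

  thresholds <- list(
    gdp_per_capita = 936.30,             # USD, 2020
    ce_band = c(936.30, 2808.90),        # 1x and 3x GDP per capita
    half_gdp = 468.15,
    wtp = 50000)

  model <- list(
    cycles = 80,
    cycle_length = 1,
    half_cycle_correction = FALSE,
    rr_applies_to_uncontrolled = FALSE,
    apply_pill_disutility = FALSE,
    adherence = 1,
    lag_years = 0)

  p <- structure(list(strata = strata, epi = epi, risks = risks, dw = dw,
                      costs = costs, thresholds = thresholds, model = model),
                 class = "htn_params")
  validate_parameters(p)
  p
}

#' Validate a parameter book
#'
#' Checks every invariant: fractions in \code{[0,1]}, positive ratios and
#' exchange rates, ordered confidence intervals, non-negative prices,
#' age bands partitioning \code{[30,100)}, ordered threshold band and
#' \code{half_gdp = gdp/2}, and untreated disability weight at least the
#' treated-controlled weight.
#'
#' @param p An \code{"htn_params"} object.
#' @return \code{p} invisibly; stops with an error naming the offending
#'   field otherwise.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "htn_params"))
  frac_ok <- function(x, nm) {
    v <- if (is_uncertain(x)) c(x$low, x$mean, x$high) else x
    if (any(v < 0 | v > 1))
      stop("validation error: ", nm, " must lie in [0,1]", call. = FALSE)
  }
  pos_ok <- function(x, nm) {
    v <- if (is_uncertain(x)) c(x$low, x$mean, x$high) else x
    if (any(v < 0))
      stop("validation error: ", nm, " must be non-negative", call. = FALSE)
  }
  # strata partition [30, 100)
  for (s in unique(p$strata$sex)) {
    b <- p$strata[p$strata$sex == s, ]
    b <- b[order(b$age_low), ]
    if (b$age_low[1] != 30 || b$age_high[nrow(b)] != 100 ||
        (nrow(b) > 1 && any(b$age_high[-nrow(b)] != b$age_low[-1])))
      stop("validation error: strata age bands must partition [30,100) for ",
           s, call. = FALSE)
  }
  if (any(p$strata$population < 0))
    stop("validation error: strata population must be non-negative",
         call. = FALSE)
  frac_ok(p$epi$prevalence_by_band, "epi.prevalence_by_band")
  frac_ok(p$epi$mean_prevalence, "epi.mean_prevalence")
  frac_ok(p$epi$treatment_coverage, "epi.treatment_coverage")
  frac_ok(p$epi$control_rate, "epi.control_rate")
  for (nm in c("rr_mortality_htn", "rr_high_bp", "hr_high_bp")) {
    x <- p$epi[[nm]]
    if (x$low <= 0) stop("validation error: epi.", nm, " must be positive",
                         call. = FALSE)
  }
  for (s in names(p$epi$background_mortality))
    frac_ok(p$epi$background_mortality[[s]],
            paste0("epi.background_mortality.", s))
  for (s in names(p$risks$p10_chd)) {
    frac_ok(p$risks$p10_chd[[s]], paste0("risks.p10_chd.", s))
    frac_ok(p$risks$p10_stroke[[s]], paste0("risks.p10_stroke.", s))
  }
  frac_ok(p$risks$case_fatality, "risks.case_fatality")
  if (abs(sum(p$risks$chd_split) - 1) > 1e-9 ||
      abs(sum(p$risks$cvd_split) - 1) > 1e-9)
    stop("validation error: risks event splits must each sum to 1",
         call. = FALSE)
  for (nm in c("hypertensive_heart_disease", "untreated",
               "treated_controlled", "treated_uncontrolled",
               "pill_disutility"))
    frac_ok(p$dw[[nm]], paste0("dw.", nm))
  frac_ok(p$dw$event, "dw.event")
  frac_ok(p$dw$post_event, "dw.post_event")
  if (p$dw$untreated$mean < p$dw$treated_controlled$mean)
    stop("validation error: dw.untreated must be >= dw.treated_controlled",
         call. = FALSE)
  pos_ok(p$costs$unit_price_book$price_usd_2021, "costs.unit_price_book")
  if (any(p$costs$exchange_rate <= 0))
    stop("validation error: costs.exchange_rate must be positive",
         call. = FALSE)
  for (nm in c("discount_rate", "discount_rate_alt")) {
    r <- p$costs[[nm]]
    if (r < 0 || r >= 1)
      stop("validation error: costs.", nm, " must lie in [0,1)",
           call. = FALSE)
  }
  frac_ok(p$costs$employment_rate, "costs.employment_rate")
  pos_ok(p$costs$monthly_income_employed, "costs.monthly_income_employed")
  pos_ok(p$costs$monthly_wage_unemployed, "costs.monthly_wage_unemployed")
  pos_ok(p$costs$annual_drug_cost, "costs.annual_drug_cost")
  pos_ok(p$costs$event_cost_usd, "costs.event_cost_usd")
  pos_ok(p$costs$post_event_annual_usd, "costs.post_event_annual_usd")
  pos_ok(p$costs$visit_cost_usd, "costs.visit_cost_usd")
  frac_ok(p$costs$program_population_proportion,
          "costs.program_population_proportion")
  th <- p$thresholds
  if (th$ce_band[1] > th$ce_band[2])
    stop("validation error: thresholds.ce_band must be ordered",
         call. = FALSE)
  if (abs(th$half_gdp - th$gdp_per_capita / 2) > 1e-6)
    stop("validation error: thresholds.half_gdp must equal gdp_per_capita/2",
         call. = FALSE)
  frac_ok(p$model$adherence, "model.adherence")
  if (p$model$lag_years < 0)
    stop("validation error: model.lag_years must be >= 0", call. = FALSE)
  invisible(p)
}

#' Set a parameter by dotted path
#'
#' @param p An \code{"htn_params"} object.
#' @param key Dotted path such as \code{"costs.discount_rate"} or
#'   \code{"epi.control_rate"}. Replacing an uncertain parameter with a
#'   plain number keeps its interval collapsed to a point.
#' @param value New value.
#' @return The modified, re-validated parameter book.
#' @export
param_set <- function(p, key, value) {
  stopifnot(inherits(p, "htn_params"))
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- p
  for (i in seq_along(path)) {
    nm <- path[i]
    if (is.null(node[[nm]]) && !(nm %in% names(node)))
      stop("configuration error: unknown parameter key '", key, "'",
           call. = FALSE)
    node <- node[[nm]]
  }
  old <- p[[path]]
  if (is_uncertain(old) && is.numeric(value) && length(value) == 1)
    value <- uncertain(value, value, value, "point")
  p[[path]] <- value
  validate_parameters(p)
  p
}

param_get <- function(p, key) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- p
  for (nm in path) {
    if (!(nm %in% names(node)))
      stop("configuration error: unknown parameter key '", key, "'",
           call. = FALSE)
    node <- node[[nm]]
  }
  node
}

#' Load a parameter book with optional overrides
#'
#' Starts from \code{\link{default_parameters}} and overlays overrides
#' given either as a named list of dotted keys, a JSON file with the
#' same structure, or a long-format CSV with columns
#' \code{key, mean, low, high, family} (uncertain overrides) or
#' \code{key, value} (scalars).
#'
#' @param config \code{NULL} (defaults), a named list, or a path to a
#'   \code{.json} or \code{.csv} file.
#' @return A validated \code{"htn_params"} object.
#' @export
load_parameters <- function(config = NULL) {
  p <- default_parameters()
  if (is.null(config)) return(p)
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      ov <- jsonlite::read_json(config, simplifyVector = TRUE)
      config <- as.list(ov)
    } else if (grepl("\\.csv$", config, ignore.case = TRUE)) {
      tab <- utils::read.csv(config, stringsAsFactors = FALSE)
      config <- list()
      for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        config[[row$key]] <-
          if (all(c("mean", "low", "high", "family") %in% names(tab)) &&
              !is.na(row$family) && nzchar(row$family))
            uncertain(row$mean, row$low, row$high, row$family)
          else if ("value" %in% names(tab)) row$value
          else row$mean
      }
    } else stop("configuration error: unsupported config format: ", config)
  }
  if (!is.list(config))
    stop("configuration error: config must be NULL, a list, or a file path")
  for (key in names(config)) p <- param_set(p, key, config[[key]])
  p
}

#' Serialise a parameter book to JSON
#'
#' Writes the complete book (uncertain parameters, named vectors and
#' embedded tables carry type markers) so that
#' \code{read_parameters(write_parameters(p, f))} round-trips exactly.
#'
#' @param p An \code{"htn_params"} object.
#' @param path Output file path.
#' @return \code{path} invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "htn_params"))
  ser <- function(x) {
    if (is_uncertain(x))
      list(".uncertain" = unclass(x)[c("mean", "low", "high", "family")])
    else if (is.data.frame(x)) list(".df" = as.list(x))
    else if (is.list(x)) lapply(x, ser)
    else if (is.atomic(x) && !is.null(names(x)))
      list(".nv" = list(names = names(x), values = unname(x)))
    else x
  }
  out <- lapply(unclass(p), ser)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter book written by \code{write_parameters}
#'
#' @param path JSON file produced by \code{\link{write_parameters}}.
#' @return A validated \code{"htn_params"} object.
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(x) {
    if (is.list(x) && identical(names(x), ".uncertain"))
      uncertain(x$.uncertain$mean, x$.uncertain$low, x$.uncertain$high,
                x$.uncertain$family)
    else if (is.list(x) && identical(names(x), ".df"))
      as.data.frame(x$.df, stringsAsFactors = FALSE)
    else if (is.list(x) && identical(names(x), ".nv"))
      stats::setNames(x$.nv$values, x$.nv$names)
    else if (is.list(x)) lapply(x, de)
    else x
  }
  p <- structure(lapply(raw, de), class = "htn_params")
  validate_parameters(p)
  p
}

#' @export
print.htn_params <- function(x, ...) {
  cat("Hypertension CEA parameter book\n")
  cat(sprintf("  strata: %d (%s)\n", nrow(x$strata),
              paste(unique(sprintf("[%g,%g)", x$strata$age_low,
                                   x$strata$age_high)), collapse = " ")))
  cat(sprintf("  cohort: %s persons\n",
              format(sum(x$strata$population), big.mark = ",")))
  cat(sprintf("  treatment coverage %.1f%%, control rate %.0f%%\n",
              100 * x$epi$treatment_coverage$mean,
              100 * x$epi$control_rate$mean))
  cat(sprintf("  discount rate %.0f%%, exchange rate %.1f ETB/USD (2021)\n",
              100 * x$costs$discount_rate, x$costs$exchange_rate[["2021"]]))
  cat(sprintf("  thresholds: GDP %.2f USD, band [%.2f, %.2f], WTP %s\n",
              x$thresholds$gdp_per_capita, x$thresholds$ce_band[1],
              x$thresholds$ce_band[2],
              format(x$thresholds$wtp, big.mark = ",")))
  invisible(x)
}
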