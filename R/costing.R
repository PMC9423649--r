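# Societal costing: bottom-up direct medical/non-medical costs,
# human-capital productivity-loss monetization, inflation, currency
# conversion, discounting, and program-cost scaling.

#' Construct a cost ledger
#'
#' A tidy line-item ledger; \code{amount = quantity * unit_price} is
#' enforced at construction.
#'
#' @param category One of \code{direct_medical}, \code{direct_nonmedical},
#'   \code{indirect}, \code{program} (recycled).
#' @param item Item label.
#' @param quantity,unit_price Non-negative numerics.
#' @param year Price year (default 2021).
#' @param currency Currency tag (default \code{"USD"}).
#' @return A data.frame of class \code{"htn_ledger"}.
#' @export
cost_ledger <- function(category = character(), item = character(),
                        quantity = numeric(), unit_price = numeric(),
                        year = 2021, currency = "USD") {
  ok <- c("direct_medical", "direct_nonmedical", "indirect", "program")
  if (length(category) && !all(category %in% ok))
    stop("cost_ledger(): category must be one of ",
         paste(ok, collapse = ", "))
  if (any(quantity < 0) || any(unit_price < 0))
    stop("cost_ledger(): quantities and prices must be non-negative")
  n <- length(quantity)
  out <- data.frame(category = rep_len(category, n),
                    item = rep_len(item, n), quantity = quantity,
                    unit_price = unit_price, year = rep_len(year, n),
                    currency = rep_len(currency, n),
                    amount = quantity * unit_price,
                    stringsAsFactors = FALSE)
  class(out) <- c("htn_ledger", "data.frame")
  out
}

#' Annual monetized productivity loss (human-capital approach)
#'
#' Monetizes lost productive years: each year is valued at twelve months
#' of the employment-weighted wage mix,
#' \code{12 (e w_employed + (1 - e) w_unemployed)} with sex-specific
#' employment rate \code{e}. With the default book this is the published
#' per-sex monetization of YLL/YLD years in ETB.
#'
#' @param years Productive years lost (YLL or YLD), >= 0.
#' @param sex \code{"male"} or \code{"female"}.
#' @param params An \code{"htn_params"} book (wages and employment
#'   rates are read from \code{params$costs}).
#' @return Amount in ETB.
#' @examples
#' p <- default_parameters()
#' productivity_loss_annual(10121, "male", p)   # 231,670,739.35 ETB
#' @export
productivity_loss_annual <- function(years, sex, params = default_parameters()) {
  if (any(years < 0)) stop("productivity_loss_annual(): years must be >= 0")
  e <- params$costs$employment_rate
  if (!(sex %in% names(e)))
    stop("productivity_loss_annual(): unknown sex '", sex, "'")
  e <- e[[sex]]
  w_emp <- params$costs$monthly_income_employed
  w_un <- params$costs$monthly_wage_unemployed
  if (is_uncertain(w_un)) w_un <- w_un$mean
  sum(years * 12 * (e * w_emp + (1 - e) * w_un))
}

#' Cost of productivity lost to premature mortality
#'
#' Potential productive years per death are the residual life expectancy
#' at the age of death, \code{Z = max(LE - age, 0)}; summed over ages
#' weighted by death counts and monetized with
#' \code{\link{productivity_loss_annual}}.
#'
#' @param deaths_by_age Death counts per age group (>= 0).
#' @param age_at_death Ages at death matching \code{deaths_by_age}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param params An \code{"htn_params"} book.
#' @return Amount in ETB.
#' @export
premature_mortality_cost <- function(deaths_by_age, age_at_death, sex,
                                     params = default_parameters()) {
  if (any(deaths_by_age < 0))
    stop("premature_mortality_cost(): death counts must be >= 0")
  if (length(deaths_by_age) != length(age_at_death))
    stop("premature_mortality_cost(): deaths and ages must align")
  le <- params$epi$life_expectancy[[sex]]
  if (is.null(le)) stop("premature_mortality_cost(): unknown sex '", sex, "'")
  z <- pmax(le - age_at_death, 0)
  productivity_loss_annual(sum(z * deaths_by_age), sex, params)
}

#' Convert ETB to USD
#'
#' @param amount Amount in ETB.
#' @param rate Exchange rate in ETB per USD (> 0); default 43.5 (2021).
#' @return Amount in USD.
#' @export
convert_currency <- function(amount, rate = 43.5) {
  if (any(rate <= 0)) stop("convert_currency(): rate must be positive")
  amount / rate
}

#' Inflation adjustment
#'
#' @param amount Amount.
#' @param factor Cumulative inflation multiplier (> 0); the book's
#'   2015-to-2021 factor is 1.372.
#' @return \code{amount * factor}.
#' @export
inflate <- function(amount, factor) {
  if (any(factor <= 0)) stop("inflate(): factor must be positive")
  amount * factor
}

#' Present value of a future amount
#'
#' @param amount Amount accruing \code{t} years from now.
#' @param rate Annual discount rate in \code{[0,1)}; default 3\%.
#' @param t Years from now (>= 0); vectorised, so a cost stream can be
#'   discounted and summed in one call.
#' @return \code{amount / (1 + rate)^t}.
#' @export
discount <- function(amount, rate = 0.03, t) {
  if (any(rate < 0) || any(rate >= 1))
    stop("discount(): rate must lie in [0,1)")
  if (any(t < 0)) stop("discount(): t must be >= 0")
  amount / (1 + rate)^t
}

#' Bottom-up ledger totals
#'
#' @param ledger An \code{"htn_ledger"}.
#' @return A list with \code{by_category} (named sums) and \code{total};
#'   mixing currencies without prior conversion is an error.
#' @export
bottom_up_total <- function(ledger) {
  if (nrow(ledger) == 0)
    return(list(by_category = stats::setNames(numeric(), character()),
                total = 0))
  if (length(unique(ledger$currency)) > 1)
    stop("bottom_up_total(): mixed currencies; convert first")
  by_cat <- tapply(ledger$amount, ledger$category, sum)
  list(by_category = by_cat, total = sum(ledger$amount))
}

#' Annual outpatient visit cost
#'
#' Twelve monthly visits at the per-visit facility price.
#'
#' @param per_visit Cost per outpatient visit.
#' @param visits_per_year Annual visit count (default 12).
#' @return Annual cost.
#' @export
annual_outpatient_cost <- function(per_visit, visits_per_year = 12) {
  if (any(per_visit < 0)) stop("annual_outpatient_cost(): price must be >= 0")
  visits_per_year * per_visit
}

#' Scale a national program cost to the study population
#'
#' @param national_annual National annual program cost.
#' @param proportion Study-population share of the national population
#'   in \code{[0,1]} (default 3\%).
#' @return Scaled amount.
#' @export
scale_program_cost <- function(national_annual, proportion = 0.03) {
  if (proportion < 0 || proportion > 1)
    stop("scale_program_cost(): proportion must lie in [0,1]")
  national_annual * proportion
}

#' Monthly per-person program cost
#'
#' @param per_person_annum Annual per-person program cost.
#' @return One twelfth of the annual figure.
#' @export
program_cost_per_month <- function(per_person_annum) per_person_annum / 12
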