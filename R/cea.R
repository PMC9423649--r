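# Cost-effectiveness metrics: incremental comparison with dominance,
# ICER, ACER, net monetary benefit, and GDP-multiple threshold labels.

#' Incremental comparison of treated versus untreated arms
#'
#' Deltas are stored in the reporting orientation of the source tables -
#' comparator minus intervention (\code{untreated - treated}) - so a
#' positive \code{delta_cost} means the intervention saves cost and a
#' positive \code{delta_dalys} means it averts DALYs. The conventional
#' intervention-minus-comparator quantities are carried alongside as
#' \code{cost_incurred} and \code{dalys_gained} so dominance is never
#' hidden behind a bare ratio.
#'
#' @param cost_treated,cost_untreated Total arm costs (USD).
#' @param dalys_treated,dalys_untreated Total arm DALYs (years).
#' @return A list of class \code{"htn_comparison"} with the four inputs,
#'   both delta orientations, and a \code{dominance} label in
#'   \code{none}, \code{intervention_dominant},
#'   \code{intervention_dominated}.
#' @export
incremental <- function(cost_treated, cost_untreated,
                        dalys_treated, dalys_untreated) {
  v <- c(cost_treated, cost_untreated, dalys_treated, dalys_untreated)
  if (any(!is.finite(v))) stop("incremental(): inputs must be finite")
  delta_cost <- cost_untreated - cost_treated
  delta_dalys <- dalys_untreated - dalys_treated
  dominance <- if (delta_cost > 0 && delta_dalys > 0) "intervention_dominant"
    else if (delta_cost < 0 && delta_dalys < 0) "intervention_dominated"
    else "none"
  structure(list(cost_treated = cost_treated,
                 cost_untreated = cost_untreated,
                 dalys_treated = dalys_treated,
                 dalys_untreated = dalys_untreated,
                 delta_cost = delta_cost, delta_dalys = delta_dalys,
                 cost_incurred = -delta_cost, dalys_gained = delta_dalys,
                 dominance = dominance),
            class = "htn_comparison")
}

#' @export
print.htn_comparison <- function(x, ...) {
  cat("Incremental comparison (comparator minus intervention)\n")
  cat(sprintf("  incremental cost:  %12.2f\n", x$delta_cost))
  cat(sprintf("  incremental DALYs: %12.2f\n", x$delta_dalys))
  if (x$dominance != "none") cat("  dominance:", x$dominance, "\n")
  else cat(sprintf("  ICER: %.2f per DALY averted\n", icer(x)))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' \code{delta_cost / delta_dalys} in a consistent orientation (the
#' ratio is identical in both orientations). The dominance status of the
#' comparison should always be reported alongside: a dominant
#' intervention yields a positive ratio that reads as savings per DALY
#' averted, not a price.
#'
#' @param c An \code{"htn_comparison"}.
#' @return ICER in USD per DALY averted.
#' @export
icer <- function(c) {
  stopifnot(inherits(c, "htn_comparison"))
  if (c$delta_dalys == 0)
    stop("icer(): undefined ratio - incremental DALYs are zero")
  c$delta_cost / c$delta_dalys
}

#' Average cost-effectiveness ratio
#'
#' Total intervention cost per DALY averted versus the null, the
#' generalized-CEA summary.
#'
#' @param total_cost Total cost (USD).
#' @param dalys_averted DALYs averted (> 0).
#' @return ACER in USD per DALY averted.
#' @export
acer <- function(total_cost, dalys_averted) {
  if (dalys_averted <= 0)
    stop("acer(): dalys_averted must be positive")
  total_cost / dalys_averted
}

#' Net monetary benefit
#'
#' \code{wtp x DALYs averted - incremental cost incurred} by the
#' intervention. Zero at \code{wtp = ICER} when the incurred cost and
#' the health gain share sign; linear and increasing in \code{wtp}
#' whenever DALYs are averted.
#'
#' @param wtp Willingness to pay, USD per DALY averted (>= 0).
#' @param c An \code{"htn_comparison"}.
#' @return A list of class \code{"htn_nmb"} with \code{wtp} and
#'   \code{nmb}.
#' @export
nmb <- function(wtp, c) {
  stopifnot(inherits(c, "htn_comparison"))
  if (any(wtp < 0)) stop("nmb(): wtp must be >= 0")
  structure(list(wtp = wtp, nmb = wtp * c$dalys_gained - c$cost_incurred),
            class = "htn_nmb")
}

#' Threshold classification of an ICER
#'
#' \code{gdp_multiple} rule: very cost-effective below one GDP per
#' capita per DALY averted; cost-effective from one to three times GDP
#' (both endpoints included); not cost-effective above three times.
#' \code{half_gdp} rule: cost-effective at or below half GDP per capita,
#' otherwise not.
#'
#' @param icer_value Finite ICER in USD per DALY averted. Negative
#'   ratios should be reported with dominance flags, not labels; they
#'   are rejected here.
#' @param thresholds The book's \code{thresholds} list.
#' @param rule \code{"gdp_multiple"} (default) or \code{"half_gdp"}.
#' @return A list of class \code{"htn_threshold_class"} with
#'   \code{label} and \code{rule}.
#' @export
classify <- function(icer_value,
                     thresholds = default_parameters()$thresholds,
                     rule = c("gdp_multiple", "half_gdp")) {
  rule <- match.arg(rule)
  if (!is.finite(icer_value)) stop("classify(): icer must be finite")
  if (icer_value < 0)
    stop("classify(): negative ICER - report the dominance flag instead ",
         "of a threshold label")
  label <- if (rule == "gdp_multiple") {
    if (icer_value < thresholds$ce_band[1]) "very_cost_effective"
    else if (icer_value <= thresholds$ce_band[2]) "cost_effective"
    else "not_cost_effective"
  } else {
    if (icer_value <= thresholds$half_gdp) "cost_effective"
    else "not_cost_effective"
  }
  structure(list(label = label, rule = rule, icer = icer_value),
            class = "htn_threshold_class")
}

#' @export
print.htn_threshold_class <- function(x, ...) {
  cat(sprintf("%.2f USD/DALY averted: %s (%s rule)\n", x$icer,
              gsub("_", " ", x$label), x$rule))
  invisible(x)
}
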