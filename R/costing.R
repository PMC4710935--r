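# Drug-acquisition costing under the health-care payer perspective.

#' Convert Moroccan dirhams to US dollars
#'
#' @param amount_mad cost in MAD.
#' @param rate_mad_per_usd exchange rate, MAD per USD (default 9.297, the
#'   2013 rate used for the base case).
#' @return cost in USD.
#' @export
#' @examples
#' convert_currency(92.97) # 10
convert_currency <- function(amount_mad, rate_mad_per_usd = 9.297) {
  if (!is.numeric(rate_mad_per_usd) || rate_mad_per_usd <= 0)
    stop("exchange rate must be a positive number of MAD per USD",
         call. = FALSE)
  amount_mad / rate_mad_per_usd
}

#' Annualize a six-month cost
#'
#' Projects a 6-month drug-acquisition cost to one year as two identical
#' half-year blocks (doubling). Applied to unrounded per-patient costs;
#' rounding happens only at report time.
#'
#' @param cost_6mo six-month cost, any currency.
#' @return the one-year cost.
#' @export
annualize <- function(cost_6mo) {
  stopifnot(all(cost_6mo >= 0))
  2 * cost_6mo
}

#' Discount a cost to present value
#'
#' Standard exponential discounting: `cost / (1 + rate)^year_index`, with
#' year 0 undiscounted. In the base case the horizon is one year and all
#' costs fall in year 0, so discounting is a no-op there; it is exercised by
#' multi-year extensions.
#'
#' @param cost undiscounted cost.
#' @param rate annual discount rate (default 0.03).
#' @param year_index integer year in which the cost is incurred (0 = now).
#' @return present value.
#' @export
#' @examples
#' discount(103, 0.03, 1) # 100
discount <- function(cost, rate = 0.03, year_index = 0) {
  stopifnot(all(rate >= 0), all(year_index >= 0))
  cost / (1 + rate)^year_index
}

#' Per-patient cost breakdown
#'
#' Sums the six monthly drug costs of each patient-phase, applies the
#' configured inflation factor, annualizes, and discounts (year 0 in the
#' base case, hence undiscounted). Costs recorded in MAD are converted to
#' USD first when `currency = "MAD"`.
#'
#' @param df a cohort data frame (see [read_cohort()]).
#' @param config a [cea_config()] object.
#' @param currency currency of the recorded monthly costs, `"USD"` (default)
#'   or `"MAD"`.
#' @return a data frame `patient_id, arm, cost_6mo, cost_1yr` in USD.
#' @export
patient_costs <- function(df, config = cea_config(), currency = c("USD", "MAD")) {
  currency <- match.arg(currency)
  df <- validate_cohort(df)
  monthly <- as.matrix(df[paste0("cost_", 1:6)])
  if (currency == "MAD")
    monthly <- convert_currency(monthly, config$exchange_mad_per_usd)
  cost_6mo <- rowSums(monthly) * config$inflation_factor
  cost_1yr <- discount(annualize(cost_6mo), config$discount_rate, 0)
  data.frame(patient_id = df$patient_id, arm = df$arm,
             cost_6mo = cost_6mo, cost_1yr = cost_1yr,
             stringsAsFactors = FALSE)
}
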