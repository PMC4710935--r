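#' Analysis configuration
#'
#' Collects the tunable constants of the cost-effectiveness analysis: the
#' haemoglobin target range defining clinical success, the economic
#' perspective parameters (exchange rate, inflation index, discount rate,
#' horizon), the willingness-to-pay threshold, and the probabilistic
#' sensitivity-analysis size.
#'
#' @param hb_low lower bound of the Hb target range, g/dL (default 10.5).
#' @param hb_high upper bound of the Hb target range, g/dL (default 12).
#' @param closure which ends of the target range are in range: `"closed"`
#'   (default; both bounds count as success), `"left"` (only the lower bound
#'   included), `"right"`, or `"open"`.
#' @param discount_rate annual discount rate applied to costs (default 0.03).
#'   With the one-year horizon all costs fall in year 0, so the base case is
#'   unaffected; the rate matters for multi-year extensions.
#' @param horizon_years analysis horizon in years (default 1).
#' @param exchange_mad_per_usd Moroccan dirhams per US dollar (default 9.297).
#' @param inflation_factor multiplicative consumer-price-index adjustment
#'   (default 1; applied to all patient-level costs).
#' @param gdp_per_capita_usd per-capita GDP in USD used to build the
#'   willingness-to-pay threshold (default 3092, Morocco 2013).
#' @param threshold_multiplier WTP threshold = multiplier x GDP per capita
#'   (default 3, the WHO convention).
#' @param threshold_override literal WTP threshold in USD; when non-`NULL` it
#'   replaces `threshold_multiplier * gdp_per_capita_usd`.
#' @param psa_iterations Monte Carlo sample size for [psa()] (default 50000).
#' @param rng_seed integer seed used by stochastic components when set.
#' @param effectiveness_mode `"TABLE"` replays a published average
#'   effectiveness stored in the arm summary when available; `"CSR"` always
#'   uses the computed clinical success rate. The two differ in the published
#'   base case (0.55/0.59 versus 0.653/0.707) and are never silently
#'   interchanged.
#' @return an object of class `cea_config` (a validated list).
#' @seealso [read_cea_config()] to load the same fields from a YAML file.
#' @export
#' @examples
#' cfg <- cea_config()
#' cfg$hb_low
#' cea_config(effectiveness_mode = "CSR", psa_iterations = 1000)$psa_iterations
cea_config <- function(hb_low = 10.5,
                       hb_high = 12,
                       closure = c("closed", "left", "right", "open"),
                       discount_rate = 0.03,
                       horizon_years = 1L,
                       exchange_mad_per_usd = 9.297,
                       inflation_factor = 1,
                       gdp_per_capita_usd = 3092,
                       threshold_multiplier = 3,
                       threshold_override = NULL,
                       psa_iterations = 50000L,
                       rng_seed = NULL,
                       effectiveness_mode = c("TABLE", "CSR")) {
  closure <- match.arg(closure)
  effectiveness_mode <- match.arg(effectiveness_mode)
  if (!is.numeric(hb_low) || !is.numeric(hb_high) || hb_low >= hb_high)
    stop("hb_low must be strictly less than hb_high", call. = FALSE)
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (exchange_mad_per_usd <= 0)
    stop("exchange_mad_per_usd must be positive", call. = FALSE)
  if (inflation_factor <= 0)
    stop("inflation_factor must be positive", call. = FALSE)
  if (psa_iterations < 1) stop("psa_iterations must be >= 1", call. = FALSE)
  if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  structure(list(
    hb_low = hb_low, hb_high = hb_high, closure = closure,
    discount_rate = discount_rate, horizon_years = as.integer(horizon_years),
    exchange_mad_per_usd = exchange_mad_per_usd,
    inflation_factor = inflation_factor,
    gdp_per_capita_usd = gdp_per_capita_usd,
    threshold_multiplier = threshold_multiplier,
    threshold_override = threshold_override,
    psa_iterations = as.integer(psa_iterations),
    rng_seed = rng_seed,
    effectiveness_mode = effectiveness_mode
  ), class = "cea_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Any subset of the [cea_config()] fields may appear in the file; missing
#' fields keep their defaults, unknown fields are an error.
#'
#' @param path path to a YAML file of `key: value` pairs.
#' @return a `cea_config` object.
#' @export
read_cea_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cea_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(cea_config, vals)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("CEA configuration\n")
  cat(sprintf("  Hb target range: [%.1f, %.1f] g/dL (%s)\n",
              x$hb_low, x$hb_high, x$closure))
  cat(sprintf("  WTP threshold:   %.0f $ (%g x GDP %g $%s)\n",
              wtp_threshold(x), x$threshold_multiplier, x$gdp_per_capita_usd,
              if (!is.null(x$threshold_override)) ", overridden" else ""))
  cat(sprintf("  discount %.1f%%/yr, horizon %d yr, %.3f MAD/USD, inflation x%g\n",
              100 * x$discount_rate, x$horizon_years, x$exchange_mad_per_usd,
              x$inflation_factor))
  cat(sprintf("  effectiveness mode %s, PSA iterations %d\n",
              x$effectiveness_mode, x$psa_iterations))
  invisible(x)
}

# The operative willingness-to-pay threshold in USD per unit effectiveness.
wtp_threshold <- function(config) {
  config$threshold_override %||%
    (config$threshold_multiplier * config$gdp_per_capita_usd)
}
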