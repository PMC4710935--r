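# Clinical-success-rate effectiveness from monthly haemoglobin trajectories.

in_target_range <- function(mean_hb, config) {
  lo <- config$hb_low; hi <- config$hb_high
  switch(config$closure,
    closed = mean_hb >= lo & mean_hb <= hi,
    left   = mean_hb >= lo & mean_hb <  hi,
    right  = mean_hb >  lo & mean_hb <= hi,
    open   = mean_hb >  lo & mean_hb <  hi
  )
}

#' Classify patient-phases by mean haemoglobin
#'
#' Each patient-phase is classified by the mean of its six consecutive
#' monthly Hb measures against the target range: `IN_RANGE` (clinical
#' success), `BELOW`, or `ABOVE`. The published range is 10.5--12 g/dL with
#' both bounds counting as success (closed interval; see the `closure` field
#' of [cea_config()] for half-open variants).
#'
#' @param df a cohort data frame.
#' @param config a [cea_config()] object.
#' @return a data frame `patient_id, arm, mean_hb, category` with `category`
#'   a factor with levels `BELOW, IN_RANGE, ABOVE`.
#' @export
#' @examples
#' co <- simulate_cohort(sim_params(n_patients = 10, seed = 42))
#' table(classify_phases(co)$category)
classify_phases <- function(df, config = cea_config()) {
  df <- validate_cohort(df)
  mean_hb <- rowMeans(as.matrix(df[paste0("hb_", 1:6)]))
  category <- ifelse(in_target_range(mean_hb, config), "IN_RANGE",
                     ifelse(mean_hb < config$hb_low, "BELOW", "ABOVE"))
  # a mean above hb_high excluded by a half-open bound is ABOVE, not BELOW
  category[!in_target_range(mean_hb, config) & mean_hb >= config$hb_high] <- "ABOVE"
  category[!in_target_range(mean_hb, config) & mean_hb <= config$hb_low] <- "BELOW"
  data.frame(patient_id = df$patient_id, arm = df$arm, mean_hb = mean_hb,
             category = factor(category, levels = c("BELOW", "IN_RANGE", "ABOVE")),
             stringsAsFactors = FALSE)
}

#' Per-arm effectiveness and cost summary
#'
#' Aggregates a classified cohort into per-arm summaries: success/failure
#' counts, the clinical success rate (CSR = proportion of patients with
#' phase-mean Hb in the target range), mean and SD of 6-month and annualized
#' drug costs, and the mean cost within each Hb category (`BELOW` and
#' `ABOVE` pooled as treatment failure). The per-range costs feed the
#' decision-tree leaves in [cea()].
#'
#' @param df a cohort data frame.
#' @param config a [cea_config()] object.
#' @param currency currency of the recorded costs, passed to
#'   [patient_costs()].
#' @return an `arm_summary` data frame, one row per arm present, with the
#'   columns documented in [load_table3()]. `avg_effectiveness` equals the
#'   CSR for cohort-derived summaries. `cost_success`/`cost_fail` are `NA`
#'   when a category is empty.
#' @export
summarize_arms <- function(df, config = cea_config(),
                           currency = c("USD", "MAD")) {
  df <- validate_cohort(df)
  cls <- classify_phases(df, config)
  costs <- patient_costs(df, config, currency = match.arg(currency))
  arms <- intersect(arm_levels, unique(df$arm))
  rows <- lapply(arms, function(a) {
    sel <- df$arm == a
    if (!any(sel)) stop("empty arm: ", a, call. = FALSE)
    n <- sum(sel)
    success <- cls$category[sel] == "IN_RANGE"
    c6 <- costs$cost_6mo[sel]
    c1 <- costs$cost_1yr[sel]
    data.frame(
      arm = a, n = n,
      n_success = sum(success), n_fail = sum(!success),
      csr = mean(success),
      avg_effectiveness = mean(success),
      mean_cost_6mo = mean(c6),
      sd_cost_6mo = if (n > 1) sd(c6) else NA_real_,
      mean_cost_1yr = mean(c1),
      sd_cost_1yr = if (n > 1) sd(c1) else NA_real_,
      cost_success = if (any(success)) mean(c6[success]) else NA_real_,
      cost_fail = if (any(!success)) mean(c6[!success]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("arm_summary", "data.frame")
  out
}

#' Proportions of patients below, within, and above the Hb target range
#'
#' @param cls a classification table from [classify_phases()], or a cohort
#'   data frame (classified with `config` first).
#' @param config a [cea_config()] object (used only when `cls` is a cohort).
#' @return a data frame `arm, n, n_below, n_in_range, n_above, p_below,
#'   p_in_range, p_above`; the three proportions sum to 1 per arm.
#' @export
#' @examples
#' # published counts: 14/49/12 of 75 print as 18.7 / 65.3 / 16.0 percent
#' percent(14 / 75)
range_proportions <- function(cls, config = cea_config()) {
  if (!all(c("category", "arm") %in% names(cls)))
    cls <- classify_phases(cls, config)
  if (nrow(cls) == 0) stop("no classified phases", call. = FALSE)
  arms <- intersect(arm_levels, unique(cls$arm))
  rows <- lapply(arms, function(a) {
    tab <- table(cls$category[cls$arm == a])
    n <- sum(tab)
    data.frame(arm = a, n = n,
               n_below = as.integer(tab[["BELOW"]]),
               n_in_range = as.integer(tab[["IN_RANGE"]]),
               n_above = as.integer(tab[["ABOVE"]]),
               p_below = tab[["BELOW"]] / n,
               p_in_range = tab[["IN_RANGE"]] / n,
               p_above = tab[["ABOVE"]] / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
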