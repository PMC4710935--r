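# Two-arm decision-tree cost-effectiveness engine.
#
# Each arm is a chance node with two leaves: clinical success (probability p,
# effectiveness 1, leaf cost = mean cost among in-range patients) and failure
# (probability 1-p, effectiveness 0, leaf cost = mean cost among out-of-range
# patients). Rolling back gives the arm's expected cost and effectiveness;
# the two arms are then compared on the incremental scale.

#' Build a two-leaf decision-tree arm
#'
#' @param p probability of clinical success in \[0, 1\].
#' @param cost_success,cost_fail leaf costs (non-negative).
#' @param eff_success,eff_fail leaf effectiveness payoffs (default 1 / 0).
#' @return an object of class `decision_tree`.
#' @export
decision_tree <- function(p, cost_success, cost_fail,
                          eff_success = 1, eff_fail = 0) {
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("success probability must lie in [0, 1]", call. = FALSE)
  if (cost_success < 0 || cost_fail < 0)
    stop("leaf costs must be non-negative", call. = FALSE)
  structure(list(p = p, cost_success = cost_success, cost_fail = cost_fail,
                 eff_success = eff_success, eff_fail = eff_fail),
            class = "decision_tree")
}

#' Roll back a decision-tree arm to expected cost and effectiveness
#'
#' Expected values over the two leaves weighted by path probability:
#' `E[cost] = p * cost_success + (1 - p) * cost_fail` and likewise for
#' effectiveness (with the default payoffs `E[eff] = p`).
#'
#' @param tree a [decision_tree()].
#' @return named numeric vector `c(cost = , eff = )`.
#' @export
#' @examples
#' rollback(decision_tree(0.5, 100, 200)) # cost 150, eff 0.5
rollback <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  c(cost = tree$p * tree$cost_success + (1 - tree$p) * tree$cost_fail,
    eff = tree$p * tree$eff_success + (1 - tree$p) * tree$eff_fail)
}

#' Average cost-effectiveness ratio
#'
#' `ACER = mean cost / mean effectiveness` of a single arm. Zero
#' effectiveness yields `NA` (undefined), not an error.
#'
#' @param cost mean cost.
#' @param effectiveness mean effectiveness (dimensionless, >= 0).
#' @return cost per unit effectiveness, or `NA_real_` when effectiveness
#'   is zero.
#' @export
#' @examples
#' acer(3288.49, 0.55) # 5979.07...
acer <- function(cost, effectiveness) {
  if (any(effectiveness < 0))
    stop("effectiveness must be non-negative", call. = FALSE)
  ifelse(effectiveness == 0, NA_real_, cost / effectiveness)
}

# Vectorized incremental core shared by the base-case engine (icer()) and
# the per-draw Monte Carlo recomputation, so the formula exists exactly once.
incremental <- function(cost_epob, eff_epob, cost_cera, eff_cera) {
  delta_cost <- cost_cera - cost_epob
  delta_eff <- eff_cera - eff_epob
  defined <- delta_eff != 0
  list(delta_cost = delta_cost, delta_eff = delta_eff,
       icer = ifelse(defined, delta_cost / delta_eff, NA_real_),
       icer_defined = defined)
}

# Dominance quadrant of (delta_eff, delta_cost) on the CE plane, with
# boundary points assigned to the adjacent quadrant clockwise (x = delta_eff
# rightwards, y = delta_cost upwards): NE -> SE -> SW -> NW. The origin is
# assigned NE by convention. DOMINANT = SE (cheaper, more effective);
# DOMINATED = NW.
ce_quadrant <- function(delta_eff, delta_cost) {
  out <- character(length(delta_eff))
  out[delta_eff > 0 & delta_cost <= 0] <- "SE"
  out[delta_eff <= 0 & delta_cost < 0] <- "SW"
  out[delta_eff < 0 & delta_cost >= 0] <- "NW"
  out[delta_eff >= 0 & delta_cost > 0] <- "NE"
  out[delta_eff == 0 & delta_cost == 0] <- "NE"
  out
}

quadrant_to_dominance <- function(q) {
  c(SE = "DOMINANT", NW = "DOMINATED",
    NE = "TRADEOFF_NE", SW = "TRADEOFF_SW")[q]
}

#' Incremental cost-effectiveness of CERA versus EpoB
#'
#' Computes the incremental comparison of the new arm (CERA) against the
#' reference arm (EpoB): `delta_cost = cost_cera - cost_epob`,
#' `delta_eff = eff_cera - eff_epob`, `ICER = delta_cost / delta_eff`
#' (sign preserved; `NA` when `delta_eff` is 0), and the dominance status.
#' A negative ICER is ambiguous on its own, so the dominance quadrant is
#' always reported alongside: `DOMINANT` (cheaper and more effective),
#' `DOMINATED` (costlier and less effective), `TRADEOFF_NE` (costlier, more
#' effective) or `TRADEOFF_SW` (cheaper, less effective).
#'
#' @param cost_epob,eff_epob expected cost and effectiveness of the
#'   reference arm.
#' @param cost_cera,eff_cera expected cost and effectiveness of the new arm.
#' @return an object of class `cea_result`: a list with `cost_per_arm`,
#'   `eff_per_arm`, `acer_per_arm`, `delta_cost`, `delta_eff`, `icer`,
#'   `icer_defined`, `dominance`.
#' @export
#' @examples
#' r <- icer(3288.49, 0.55, 3030.19, 0.59)
#' r$icer      # -6457.5
#' r$dominance # "DOMINANT"
icer <- function(cost_epob, eff_epob, cost_cera, eff_cera) {
  stopifnot(is.finite(cost_epob), is.finite(eff_epob),
            is.finite(cost_cera), is.finite(eff_cera))
  inc <- incremental(cost_epob, eff_epob, cost_cera, eff_cera)
  delta_cost <- inc$delta_cost
  delta_eff <- inc$delta_eff
  defined <- inc$icer_defined
  structure(list(
    cost_per_arm = c(EPOB = cost_epob, CERA = cost_cera),
    eff_per_arm = c(EPOB = eff_epob, CERA = eff_cera),
    acer_per_arm = c(EPOB = acer(cost_epob, eff_epob),
                     CERA = acer(cost_cera, eff_cera)),
    delta_cost = delta_cost,
    delta_eff = delta_eff,
    icer = if (defined) delta_cost / delta_eff else NA_real_,
    icer_defined = defined,
    # strict-inequality dominance; boundary cases are trade-offs
    dominance = if (delta_cost < 0 && delta_eff > 0) "DOMINANT"
                else if (delta_cost > 0 && delta_eff < 0) "DOMINATED"
                else if (delta_eff >= 0) "TRADEOFF_NE" else "TRADEOFF_SW"
  ), class = "cea_result")
}

#' Willingness-to-pay threshold decision
#'
#' Decides whether the new arm is cost-effective at the configured
#' willingness-to-pay threshold (default 3x per-capita GDP). The operative
#' rule is non-negative net monetary benefit, `lambda * delta_eff -
#' delta_cost >= 0`, which reduces to the familiar cases: a dominant arm is
#' always cost-effective, a dominated arm never is, a costlier-but-better
#' arm is cost-effective when its ICER is at most the threshold, and a
#' cheaper-but-worse arm when the savings per unit of effectiveness given up
#' (its ICER) are at least the threshold.
#'
#' @param result a `cea_result` from [icer()].
#' @param config a [cea_config()] object supplying the threshold.
#' @return `TRUE`/`FALSE`.
#' @export
threshold_decision <- function(result, config = cea_config()) {
  stopifnot(inherits(result, "cea_result"))
  lambda <- wtp_threshold(config)
  nmb <- lambda * result$delta_eff - result$delta_cost
  unname(nmb >= 0)
}

#' Fit the two-arm cost-effectiveness decision model
#'
#' The single entry point of the analysis. `x` may be either an
#' `arm_summary` table (from [load_table3()] or [summarize_arms()]) or a
#' patient-level cohort data frame (summarized internally). For each arm a
#' two-leaf decision tree is built with success probability = CSR and leaf
#' costs = per-range mean annual costs (falling back to the arm mean annual
#' cost for both leaves when per-range costs are unavailable, in which case
#' rollback returns the arm mean exactly); rollback, ACERs, the incremental
#' comparison, and the threshold decision follow.
#'
#' Effectiveness entering the ratios follows `config$effectiveness_mode`:
#' `"TABLE"` uses the stored `avg_effectiveness` (the published base case),
#' `"CSR"` the success proportion. For cohort-derived summaries the two
#' coincide.
#'
#' @param x an `arm_summary` data frame or a patient-level cohort.
#' @param config a [cea_config()] object.
#' @param ... passed to [summarize_arms()] when `x` is a cohort (e.g.
#'   `currency`).
#' @return an object of class `cea`: list with `arms` (the summary table),
#'   `trees`, `result` (a `cea_result`), `threshold`, `cost_effective`,
#'   `config`.
#' @export
#' @examples
#' fit <- cea(load_table3())
#' fit$result$icer          # -6457.5
#' fit$cost_effective       # TRUE
#' coef(fit)
cea <- function(x, config = cea_config(), ...) {
  arms <- if (inherits(x, "arm_summary")) x else summarize_arms(x, config, ...)
  need <- c("EPOB", "CERA")
  if (!all(need %in% arms$arm))
    stop("both arms (EPOB, CERA) are required; found: ",
         paste(arms$arm, collapse = ", "), call. = FALSE)
  arms <- arms[match(need, arms$arm), ]

  trees <- lapply(seq_len(2), function(i) {
    cs <- arms$cost_success[i]
    cf <- arms$cost_fail[i]
    if (is.na(cs) || is.na(cf)) {
      cs <- cf <- arms$mean_cost_1yr[i]
    } else {
      # per-range costs are stored on the 6-month scale; leaves pay annual
      cs <- annualize(cs)
      cf <- annualize(cf)
    }
    decision_tree(arms$csr[i], cs, cf)
  })
  names(trees) <- need
  rolled <- vapply(trees, rollback, numeric(2))

  eff <- if (config$effectiveness_mode == "TABLE" &&
             all(is.finite(arms$avg_effectiveness))) {
    arms$avg_effectiveness
  } else {
    rolled["eff", ]
  }
  res <- icer(cost_epob = rolled["cost", "EPOB"], eff_epob = eff[1],
              cost_cera = rolled["cost", "CERA"], eff_cera = eff[2])
  structure(list(
    arms = arms,
    trees = trees,
    result = res,
    threshold = wtp_threshold(config),
    cost_effective = threshold_decision(res, config),
    config = config
  ), class = "cea")
}

#' @export
print.cea_result <- function(x, digits = 2, ...) {
  cat(sprintf("  dCost = %.*f $, dEff = %.4g, ICER = %s $/unit eff [%s]\n",
              digits, x$delta_cost, x$delta_eff,
              if (x$icer_defined) sprintf("%.*f", digits, x$icer) else "undefined",
              x$dominance))
  invisible(x)
}

#' @export
print.cea <- function(x, digits = 2, ...) {
  cat("Two-arm cost-effectiveness analysis (CERA vs EpoB)\n\n")
  a <- x$arms
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-4s n = %d, CSR = %s%% (%d/%d), mean 1-yr cost = %.2f $, ACER = %.2f $\n",
                a$arm[i], a$n[i], format(percent(a$csr[i])), a$n_success[i],
                a$n[i], x$result$cost_per_arm[i], x$result$acer_per_arm[i]))
  }
  cat("\nIncremental (CERA - EpoB):\n")
  print(x$result, digits = digits)
  cat(sprintf("  WTP threshold %.0f $: CERA %s cost-effective\n",
              x$threshold, if (x$cost_effective) "IS" else "is NOT"))
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  r <- object$result
  out <- data.frame(
    arm = names(r$cost_per_arm),
    cost = unname(r$cost_per_arm),
    effectiveness = unname(r$eff_per_arm),
    acer = unname(r$acer_per_arm),
    stringsAsFactors = FALSE
  )
  structure(list(arms = out,
                 delta_cost = r$delta_cost, delta_eff = r$delta_eff,
                 icer = r$icer, dominance = r$dominance,
                 threshold = object$threshold,
                 cost_effective = object$cost_effective),
            class = "summary.cea")
}

#' @export
print.summary.cea <- function(x, ...) {
  print(x$arms, row.names = FALSE)
  cat(sprintf("dCost %.2f  dEff %.4g  ICER %.2f  %s; cost-effective at %.0f $: %s\n",
              x$delta_cost, x$delta_eff, x$icer, x$dominance, x$threshold,
              x$cost_effective))
  invisible(x)
}

#' @export
coef.cea <- function(object, ...) {
  r <- object$result
  c(delta_cost = r$delta_cost, delta_eff = r$delta_eff, icer = r$icer)
}

#' Report a fitted model as a JSON run summary
#'
#' Serializes the incremental results of a fitted [cea()] model (and the
#' per-arm summaries) to a JSON file, the machine-readable companion of the
#' printed summary.
#'
#' @param fit a `cea` object.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return `path` (or the JSON string) invisibly.
#' @export
write_cea_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cea"))
  r <- fit$result
  x <- list(
    arms = fit$arms,
    delta_cost = r$delta_cost,
    delta_eff = r$delta_eff,
    icer = if (r$icer_defined) r$icer else NULL,
    icer_defined = r$icer_defined,
    dominance = r$dominance,
    threshold_usd = fit$threshold,
    cost_effective = fit$cost_effective
  )
  if (is.null(path)) {
    return(invisible(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      dataframe = "rows")))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
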