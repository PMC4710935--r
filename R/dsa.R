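# Deterministic sensitivity analysis: one-way and two-way multiplicative
# variation of the four base-case parameters (per-arm annual cost and
# effectiveness), recomputing the full incremental analysis at each bound.

dsa_parameters <- c("cost_epob", "cost_cera", "eff_epob", "eff_cera")

# Extract the four scalar base-case inputs from a fitted model.
cea_base_inputs <- function(fit) {
  stopifnot(inherits(fit, "cea"))
  r <- fit$result
  c(cost_epob = unname(r$cost_per_arm["EPOB"]),
    cost_cera = unname(r$cost_per_arm["CERA"]),
    eff_epob = unname(r$eff_per_arm["EPOB"]),
    eff_cera = unname(r$eff_per_arm["CERA"]))
}

# Recompute the incremental analysis from a (possibly perturbed) input
# vector, clamping effectiveness to [0, 1] (with a warning) as multiplied
# values can leave the probability scale.
cea_from_inputs <- function(inputs, config) {
  eff <- inputs[c("eff_epob", "eff_cera")]
  if (any(eff < 0 | eff > 1)) {
    warning("effectiveness clamped to [0, 1] after multiplication",
            call. = FALSE)
    eff <- pmin(pmax(eff, 0), 1)
  }
  res <- icer(inputs[["cost_epob"]], eff[["eff_epob"]],
              inputs[["cost_cera"]], eff[["eff_cera"]])
  list(result = res, cost_effective = threshold_decision(res, config))
}

#' One-way deterministic sensitivity analysis
#'
#' Varies one base-case parameter multiplicatively (default -10%/+10%),
#' recomputes the full incremental analysis at each bound, and flags whether
#' the willingness-to-pay conclusion changes relative to the base case.
#'
#' @param fit a fitted [cea()] model providing the base case.
#' @param parameter one of `"cost_epob", "cost_cera", "eff_epob",
#'   "eff_cera"`.
#' @param multipliers numeric vector of multipliers applied to the parameter
#'   (default `c(0.9, 1.1)`).
#' @return a `cea_dsa` data frame with one row per multiplier: the perturbed
#'   inputs, `delta_cost`, `delta_eff`, `icer`, `dominance`,
#'   `cost_effective`, `decision_changed`.
#' @export
#' @examples
#' fit <- cea(load_table3())
#' one_way(fit, "cost_cera")
one_way <- function(fit, parameter, multipliers = c(0.9, 1.1)) {
  if (!parameter %in% dsa_parameters)
    stop("unknown parameter '", parameter, "'; expected one of: ",
         paste(dsa_parameters, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(multipliers), length(multipliers) >= 1)
  base <- cea_base_inputs(fit)
  rows <- lapply(multipliers, function(m) {
    inputs <- base
    inputs[parameter] <- inputs[parameter] * m
    out <- cea_from_inputs(inputs, fit$config)
    data.frame(parameter = parameter, multiplier = m,
               value = unname(inputs[parameter]),
               delta_cost = out$result$delta_cost,
               delta_eff = out$result$delta_eff,
               icer = out$result$icer,
               dominance = out$result$dominance,
               cost_effective = out$cost_effective,
               decision_changed = out$cost_effective != fit$cost_effective,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cea_dsa", "data.frame")
  out
}

#' Tornado-style one-way analysis over all base-case parameters
#'
#' Runs [one_way()] for every parameter (per-arm cost and effectiveness)
#' at the given bounds; the standard deterministic sensitivity analysis of
#' the base case.
#'
#' @inheritParams one_way
#' @param parameters parameters to vary (default all four).
#' @return a `cea_dsa` data frame, `length(parameters) *
#'   length(multipliers)` rows.
#' @export
#' @examples
#' fit <- cea(load_table3())
#' d <- dsa(fit)
#' any(d$decision_changed) # FALSE: conclusion robust to +/-10%
dsa <- function(fit, parameters = dsa_parameters, multipliers = c(0.9, 1.1)) {
  out <- do.call(rbind, lapply(parameters, one_way, fit = fit,
                               multipliers = multipliers))
  class(out) <- c("cea_dsa", "data.frame")
  out
}

#' Two-way deterministic sensitivity analysis
#'
#' Full-factorial recomputation over a grid of multipliers for two distinct
#' parameters. The cell at (1, 1) reproduces the base case.
#'
#' @param fit a fitted [cea()] model.
#' @param parameters character vector of two distinct parameter names.
#' @param grid1,grid2 multiplier grids for the first and second parameter
#'   (defaults `c(0.9, 1, 1.1)` each).
#' @return a `cea_dsa` data frame with one row per grid cell, columns
#'   `multiplier1`, `multiplier2` plus the usual result columns.
#' @export
two_way <- function(fit, parameters, grid1 = c(0.9, 1, 1.1),
                    grid2 = c(0.9, 1, 1.1)) {
  if (length(parameters) != 2 || anyDuplicated(parameters) ||
      !all(parameters %in% dsa_parameters))
    stop("parameters must be two distinct names among: ",
         paste(dsa_parameters, collapse = ", "), call. = FALSE)
  base <- cea_base_inputs(fit)
  cells <- expand.grid(m1 = grid1, m2 = grid2, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    inputs <- base
    inputs[parameters[1]] <- inputs[parameters[1]] * cells$m1[k]
    inputs[parameters[2]] <- inputs[parameters[2]] * cells$m2[k]
    out <- cea_from_inputs(inputs, fit$config)
    data.frame(parameter1 = parameters[1], parameter2 = parameters[2],
               multiplier1 = cells$m1[k], multiplier2 = cells$m2[k],
               delta_cost = out$result$delta_cost,
               delta_eff = out$result$delta_eff,
               icer = out$result$icer,
               dominance = out$result$dominance,
               cost_effective = out$cost_effective,
               decision_changed = out$cost_effective != fit$cost_effective,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cea_dsa", "data.frame")
  out
}

#' @export
print.cea_dsa <- function(x, ...) {
  cat("Deterministic sensitivity analysis (", nrow(x), " scenarios)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  if (any(x$decision_changed)) {
    cat("NOTE: the threshold decision flips in",
        sum(x$decision_changed), "scenario(s)\n")
  } else {
    cat("Threshold decision unchanged in all scenarios\n")
  }
  invisible(x)
}
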