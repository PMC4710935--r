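# Probabilistic sensitivity analysis by Monte Carlo simulation.
#
# Parameter uncertainty is propagated by sampling the four base-case inputs
# from configured distribution families and recomputing the incremental
# analysis for each sample: normal distributions for the effectiveness
# (risk) parameters, lognormal for the costing estimates, or FIXED / BETA
# per parameter. Summaries are the CE-plane quadrant shares, the per-draw
# ICER distribution, and the cost-effectiveness acceptability curve.

#' Specify a probabilistic sensitivity analysis
#'
#' Builds the sampling specification for [psa()]. The published analysis
#' states the distribution families (normal for risks, lognormal for costs)
#' but not their parameters; the defaults reconstruct them from the fitted
#' model as sampling uncertainty of the arm means: costs ~
#' LOGNORMAL(mean = arm mean annual cost, sd = annual cost SD / sqrt(n)) and
#' effectiveness ~ NORMAL(CSR or table effectiveness, binomial standard
#' error sqrt(e(1-e)/n)). Every location/scale is overridable.
#'
#' @param fit a fitted [cea()] model supplying base-case means and `n`.
#' @param n_iterations Monte Carlo sample size (default from the model's
#'   config, 50000).
#' @param seed integer RNG seed (default from config; required for
#'   reproducibility).
#' @param cost_epob,cost_cera,eff_epob,eff_cera optional per-parameter
#'   overrides, each a list `list(dist = , mean = , sd = )` with `dist` one
#'   of `"NORMAL", "LOGNORMAL", "BETA", "FIXED"`. For `"BETA"` the mean/sd
#'   are converted to shape parameters by moment matching.
#' @return an object of class `psa_spec`.
#' @export
#' @examples
#' fit <- cea(load_table3())
#' spec <- psa_spec(fit, n_iterations = 1000, seed = 7)
#' spec$params$cost_epob$dist # "LOGNORMAL"
psa_spec <- function(fit, n_iterations = NULL, seed = NULL,
                     cost_epob = NULL, cost_cera = NULL,
                     eff_epob = NULL, eff_cera = NULL) {
  stopifnot(inherits(fit, "cea"))
  a <- fit$arms
  n <- a$n
  base <- cea_base_inputs(fit)
  se_cost <- ifelse(is.finite(a$sd_cost_1yr), a$sd_cost_1yr / sqrt(n), 0)
  eff <- base[c("eff_epob", "eff_cera")]
  se_eff <- sqrt(eff * (1 - eff) / n)
  defaults <- list(
    cost_epob = list(dist = "LOGNORMAL", mean = base[["cost_epob"]], sd = se_cost[1]),
    cost_cera = list(dist = "LOGNORMAL", mean = base[["cost_cera"]], sd = se_cost[2]),
    eff_epob = list(dist = "NORMAL", mean = eff[["eff_epob"]], sd = se_eff[[1]]),
    eff_cera = list(dist = "NORMAL", mean = eff[["eff_cera"]], sd = se_eff[[2]])
  )
  user <- list(cost_epob = cost_epob, cost_cera = cost_cera,
               eff_epob = eff_epob, eff_cera = eff_cera)
  params <- lapply(dsa_parameters, function(p) {
    spec <- defaults[[p]]
    if (!is.null(user[[p]])) spec <- modifyList(spec, user[[p]])
    spec$dist <- match.arg(spec$dist, c("NORMAL", "LOGNORMAL", "BETA", "FIXED"))
    if (spec$dist != "FIXED" && (!is.numeric(spec$sd) || spec$sd < 0))
      stop("sd must be a non-negative number for parameter ", p, call. = FALSE)
    if (spec$dist == "LOGNORMAL" && spec$mean <= 0)
      stop("lognormal parameter ", p,
           " needs a positive arithmetic mean", call. = FALSE)
    spec
  })
  names(params) <- dsa_parameters
  structure(list(
    n_iterations = as.integer(n_iterations %||% fit$config$psa_iterations),
    seed = seed %||% fit$config$rng_seed,
    params = params,
    base = base
  ), class = "psa_spec")
}

sample_param <- function(spec, n) {
  m <- spec$mean
  s <- if (spec$dist == "FIXED") 0 else spec$sd
  if (s == 0) return(rep(m, n))
  switch(spec$dist,
    NORMAL = rnorm(n, m, s),
    LOGNORMAL = rlnorm_ms(n, m, s),
    BETA = {
      if (m <= 0 || m >= 1) stop("beta mean must lie in (0, 1)", call. = FALSE)
      v <- s^2
      k <- m * (1 - m) / v - 1
      if (k <= 0) stop("beta sd too large for its mean", call. = FALSE)
      stats::rbeta(n, m * k, (1 - m) * k)
    }
  )
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_iterations` parameter sets from the specification, recomputes
#' the incremental cost and effectiveness for each draw through the same
#' engine as the base case, and summarizes the CE plane. Effectiveness
#' draws are clamped to \[0, 1\]. A fixed seed makes the whole result
#' reproducible bit-for-bit.
#'
#' @param fit a fitted [cea()] model.
#' @param spec a [psa_spec()]; defaults to `psa_spec(fit)`.
#' @param lambdas willingness-to-pay grid for the acceptability curve
#'   (default 51 points from 0 to twice the configured threshold).
#' @return an object of class `cea_psa`: list with `draws` (data frame
#'   `delta_cost, delta_eff, icer, quadrant`), `quadrant_shares` (named
#'   proportions over SE/NE/SW/NW summing to 1), `icer_quantiles` (2.5, 50,
#'   97.5 percentiles of defined per-draw ICERs), `share_within_10pct`
#'   (proportion of defined ICERs within +/-10% of the base-case ICER),
#'   `n_undefined` (draws with `delta_eff == 0`, excluded from the ICER
#'   distribution), `ceac` (data frame `lambda, probability`), `base`,
#'   `spec`.
#' @export
#' @examples
#' fit <- cea(load_table3())
#' p <- psa(fit, psa_spec(fit, n_iterations = 2000, seed = 1))
#' p$quadrant_shares
psa <- function(fit, spec = psa_spec(fit), lambdas = NULL) {
  stopifnot(inherits(fit, "cea"), inherits(spec, "psa_spec"))
  n <- spec$n_iterations
  if (!is.null(spec$seed)) set.seed(spec$seed)
  draws <- lapply(spec$params, sample_param, n = n)
  eff_epob <- pmin(pmax(draws$eff_epob, 0), 1)
  eff_cera <- pmin(pmax(draws$eff_cera, 0), 1)
  # every draw goes through the same incremental engine as the base case
  inc <- incremental(draws$cost_epob, eff_epob, draws$cost_cera, eff_cera)
  delta_cost <- inc$delta_cost
  delta_eff <- inc$delta_eff
  icer_draw <- inc$icer
  quadrant <- ce_quadrant(delta_eff, delta_cost)

  shares <- vapply(c("SE", "NE", "SW", "NW"),
                   function(q) sum(quadrant == q) / n, numeric(1))
  defined <- !is.na(icer_draw)
  qs <- if (any(defined)) {
    quantile(icer_draw[defined], c(0.025, 0.5, 0.975), names = TRUE)
  } else {
    setNames(rep(NA_real_, 3), c("2.5%", "50%", "97.5%"))
  }
  base_res <- fit$result
  share10 <- if (base_res$icer_defined && any(defined)) {
    b <- sort(base_res$icer * c(0.9, 1.1))
    mean(icer_draw[defined] >= b[1] & icer_draw[defined] <= b[2])
  } else {
    NA_real_
  }
  if (is.null(lambdas))
    lambdas <- seq(0, 2 * fit$threshold, length.out = 51)
  draws_df <- data.frame(delta_cost = delta_cost, delta_eff = delta_eff,
                         icer = icer_draw, quadrant = quadrant,
                         stringsAsFactors = FALSE)
  out <- structure(list(
    draws = draws_df,
    quadrant_shares = shares,
    icer_quantiles = qs,
    share_within_10pct = share10,
    n_undefined = sum(!defined),
    base = base_res,
    spec = spec
  ), class = "cea_psa")
  out$ceac <- ceac(out, lambdas)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the probability (fraction of
#' draws) that the net monetary benefit `lambda * delta_eff - delta_cost`
#' is strictly positive.
#'
#' @param x a `cea_psa` object or a data frame with columns `delta_cost`,
#'   `delta_eff`.
#' @param lambdas numeric grid of willingness-to-pay values.
#' @return a data frame `lambda, probability`.
#' @export
#' @examples
#' d <- data.frame(delta_cost = c(-1, 1), delta_eff = c(0.01, 0.01))
#' ceac(d, lambdas = 100)$probability # 0.5: the NMB = 0 tie is not > 0
ceac <- function(x, lambdas) {
  d <- if (inherits(x, "cea_psa")) x$draws else x
  stopifnot(nrow(d) > 0, is.numeric(lambdas))
  prob <- vapply(lambdas, function(l) {
    mean(l * d$delta_eff - d$delta_cost > 0)
  }, numeric(1))
  data.frame(lambda = lambdas, probability = prob)
}

#' Summary of the per-draw ICER distribution
#'
#' Quantiles of the defined per-draw ICERs plus the proportion lying within
#' +/-10% of a reference ICER (bounds ordered numerically, so a negative
#' reference works). Draws with `delta_eff == 0` have no ICER and are
#' counted separately.
#'
#' @param x a `cea_psa` object or a data frame with columns `delta_cost`,
#'   `delta_eff` (or `icer`).
#' @param base_icer reference ICER; defaults to the base case stored in a
#'   `cea_psa` object.
#' @param probs quantile probabilities (default 2.5/50/97.5%).
#' @return a list `quantiles, share_within_10pct, n_undefined, n_defined`.
#' @export
icer_distribution <- function(x, base_icer = NULL,
                              probs = c(0.025, 0.5, 0.975)) {
  d <- if (inherits(x, "cea_psa")) x$draws else x
  if (is.null(base_icer) && inherits(x, "cea_psa") && x$base$icer_defined)
    base_icer <- x$base$icer
  ic <- if ("icer" %in% names(d)) d$icer else
    ifelse(d$delta_eff == 0, NA_real_, d$delta_cost / d$delta_eff)
  defined <- !is.na(ic)
  qs <- if (any(defined)) quantile(ic[defined], probs, names = TRUE)
        else setNames(rep(NA_real_, length(probs)), paste0(100 * probs, "%"))
  share <- if (!is.null(base_icer) && any(defined)) {
    b <- sort(base_icer * c(0.9, 1.1))
    mean(ic[defined] >= b[1] & ic[defined] <= b[2])
  } else NA_real_
  list(quantiles = qs, share_within_10pct = share,
       n_undefined = sum(!defined), n_defined = sum(defined))
}

#' @export
print.cea_psa <- function(x, ...) {
  n <- nrow(x$draws)
  cat(sprintf("Probabilistic sensitivity analysis: %d Monte Carlo draws\n", n))
  cat("  CE-plane quadrant shares (SE = dominant):\n")
  print(round(x$quadrant_shares, 4))
  cat("  per-draw ICER quantiles:\n")
  print(round(x$icer_quantiles, 2))
  if (!is.na(x$share_within_10pct))
    cat(sprintf("  share of ICERs within +/-10%% of base (%.1f): %.3f\n",
                x$base$icer, x$share_within_10pct))
  if (x$n_undefined > 0)
    cat(sprintf("  draws with undefined ICER (dEff = 0): %d\n", x$n_undefined))
  invisible(x)
}

#' Plot the cost-effectiveness plane or acceptability curve
#'
#' @param x a `cea_psa` object.
#' @param which `"plane"` (scatter of incremental effectiveness versus
#'   incremental cost, with the base case marked) or `"ceac"`.
#' @param max_points subsample size for the scatter (default 5000).
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.cea_psa <- function(x, which = c("plane", "ceac"), max_points = 5000, ...) {
  which <- match.arg(which)
  if (which == "plane") {
    d <- x$draws
    if (nrow(d) > max_points) d <- d[seq_len(max_points), ]
    plot(d$delta_eff, d$delta_cost, pch = 16, cex = 0.4,
         col = "#00000055",
         xlab = "Incremental effectiveness (CERA - EpoB)",
         ylab = "Incremental cost, $ (CERA - EpoB)",
         main = "Cost-effectiveness plane", ...)
    abline(h = 0, v = 0, col = "grey50")
    points(x$base$delta_eff, x$base$delta_cost, pch = 4, col = "red", cex = 1.4)
  } else {
    plot(x$ceac$lambda, x$ceac$probability, type = "l",
         ylim = c(0, 1),
         xlab = "Willingness to pay, $ per unit effectiveness",
         ylab = "P(net monetary benefit > 0)",
         main = "Cost-effectiveness acceptability curve", ...)
  }
  invisible(x)
}

#' Simulate incremental cost-effectiveness draws from a fitted model
#'
#' `simulate()` method wrapping [psa()]: returns `nsim` Monte Carlo draws of
#' incremental cost and effectiveness under the default probabilistic
#' specification.
#'
#' @param object a fitted [cea()] model.
#' @param nsim number of draws (default the configured PSA size).
#' @param seed RNG seed.
#' @param ... ignored.
#' @return the draws data frame of a [psa()] run.
#' @export
simulate.cea <- function(object, nsim = NULL, seed = NULL, ...) {
  spec <- psa_spec(object, n_iterations = nsim, seed = seed)
  psa(object, spec)$draws
}
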