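fit_t3 <- cea(load_table3())

fixed_spec <- function(fit, n, seed = 1) {
  psa_spec(fit, n_iterations = n, seed = seed,
           cost_epob = list(dist = "FIXED"), cost_cera = list(dist = "FIXED"),
           eff_epob = list(dist = "FIXED"), eff_cera = list(dist = "FIXED"))
}

test_that("degenerate all-FIXED PSA reproduces the base case in every draw", {
  p <- psa(fit_t3, fixed_spec(fit_t3, 2000))
  expect_equal(nrow(p$draws), 2000)
  expect_true(all(abs(p$draws$delta_cost - (-258.30)) < 1e-9))
  expect_true(all(abs(p$draws$delta_eff - 0.04) < 1e-9))
  expect_true(all(abs(p$draws$icer - (-6457.5)) < 1e-9))
  # dominant draws all land in the lower-right (SE) quadrant
  expect_equal(unname(p$quadrant_shares["SE"]), 1)
  expect_equal(sum(p$quadrant_shares), 1)
  expect_equal(unname(p$icer_quantiles), rep(-6457.5, 3), tolerance = 1e-9)
  expect_equal(p$share_within_10pct, 1)
  expect_equal(p$n_undefined, 0)
})

test_that("zero-SD distributions degenerate to FIXED", {
  spec0 <- psa_spec(fit_t3, n_iterations = 500, seed = 2,
                    cost_epob = list(dist = "LOGNORMAL", sd = 0),
                    cost_cera = list(dist = "LOGNORMAL", sd = 0),
                    eff_epob = list(dist = "NORMAL", sd = 0),
                    eff_cera = list(dist = "NORMAL", sd = 0))
  p0 <- psa(fit_t3, spec0)
  pf <- psa(fit_t3, fixed_spec(fit_t3, 500, seed = 2))
  expect_equal(p0$draws, pf$draws)
})

test_that("identical spec and seed reproduce the PSA bit for bit", {
  s <- psa_spec(fit_t3, n_iterations = 3000, seed = 99)
  p1 <- psa(fit_t3, s)
  p2 <- psa(fit_t3, s)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$quadrant_shares, p2$quadrant_shares)
  expect_identical(p1$ceac, p2$ceac)
})

test_that("quadrant shares always sum to one and respect the tie rule", {
  s <- psa_spec(fit_t3, n_iterations = 5000, seed = 4)
  p <- psa(fit_t3, s)
  expect_equal(sum(p$quadrant_shares), 1)
  # clockwise tie-breaking on the quadrant boundaries
  expect_equal(esaCEA:::ce_quadrant(0.1, 0), "SE")
  expect_equal(esaCEA:::ce_quadrant(0, -5), "SW")
  expect_equal(esaCEA:::ce_quadrant(-0.1, 0), "NW")
  expect_equal(esaCEA:::ce_quadrant(0, 5), "NE")
  expect_equal(esaCEA:::ce_quadrant(0, 0), "NE")
})

test_that("normal effectiveness draws match the closed-form probability", {
  # independent N(0.59, 0.02) vs N(0.55, 0.02), costs fixed:
  # P(dEff > 0) = pnorm(0.04 / sqrt(2 * 0.02^2))
  p_true <- pnorm(0.04 / sqrt(2 * 0.02^2))
  n <- 20000
  mc_se <- sqrt(p_true * (1 - p_true) / n)
  for (seed in 1:2) {
    spec <- psa_spec(fit_t3, n_iterations = n, seed = seed,
                     cost_epob = list(dist = "FIXED"),
                     cost_cera = list(dist = "FIXED"),
                     eff_epob = list(dist = "NORMAL", mean = 0.55, sd = 0.02),
                     eff_cera = list(dist = "NORMAL", mean = 0.59, sd = 0.02))
    p <- psa(fit_t3, spec)
    share_pos <- mean(p$draws$delta_eff > 0)
    expect_lt(abs(share_pos - p_true), 4 * mc_se)
    # costs fixed and negative dCost: dEff > 0 is exactly the SE share
    expect_equal(unname(p$quadrant_shares["SE"]), share_pos)
  }
})

test_that("acceptability curve counts strictly positive net monetary benefit", {
  d <- data.frame(delta_cost = c(-1, 1), delta_eff = c(0.01, 0.01))
  expect_equal(ceac(d, lambdas = 100)$probability, 0.5) # NMB = 0 tie excluded
  expect_equal(ceac(d, lambdas = 0)$probability, 0.5)   # cost-saving fraction
  dom <- data.frame(delta_cost = rep(-258.3, 10), delta_eff = rep(0.04, 10))
  expect_equal(ceac(dom, lambdas = c(0, 5000, 50000))$probability, rep(1, 3))
})

test_that("the acceptability curve is monotone for all-positive dEff draws", {
  spec <- psa_spec(fit_t3, n_iterations = 5000, seed = 10)
  p <- psa(fit_t3, spec)
  pos <- p$draws$delta_eff > 0
  cv <- ceac(p$draws[pos, ], lambdas = seq(0, 20000, by = 1000))
  expect_true(all(diff(cv$probability) >= 0))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
})

test_that("ICER distribution summaries match analytic normal quantiles", {
  set.seed(31)
  mu <- -6457.5; sig <- 500
  d <- data.frame(delta_cost = rnorm(1000, mu * 0.04, sig * 0.04),
                  delta_eff = rep(0.04, 1000))
  out <- icer_distribution(d, base_icer = mu)
  probs <- c(0.025, 0.5, 0.975)
  se <- sqrt(probs * (1 - probs) / 1000) / dnorm(qnorm(probs)) * sig
  analytic <- qnorm(probs, mu, sig)
  for (i in seq_along(probs))
    expect_lt(abs(out$quantiles[[i]] - analytic[i]), 3 * se[i])
  expect_equal(out$n_undefined, 0)
  # share within +/-10% of mu: P(|X - mu| < 0.1 |mu|)
  p_in <- pnorm(0.1 * abs(mu) / sig) - pnorm(-0.1 * abs(mu) / sig)
  expect_lt(abs(out$share_within_10pct - p_in), 0.05)
})

test_that("zero-dEff draws are excluded from the ICER distribution and counted", {
  d <- data.frame(delta_cost = c(-10, -20, 5), delta_eff = c(0.1, 0, 0))
  out <- icer_distribution(d, base_icer = -100)
  expect_equal(out$n_undefined, 2)
  expect_equal(out$n_defined, 1)
  expect_equal(unname(out$quantiles), rep(-100, 3))
})

test_that("simulate() on a fitted model returns reproducible PSA draws", {
  d1 <- simulate(fit_t3, nsim = 200, seed = 6)
  d2 <- simulate(fit_t3, nsim = 200, seed = 6)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 200)
})

test_that("lognormal cost sampling preserves the arithmetic mean and sd", {
  set.seed(8)
  x <- esaCEA:::rlnorm_ms(2e5, 3288.49, 198.5)
  expect_equal(mean(x), 3288.49, tolerance = 5e-3)
  expect_equal(sd(x), 198.5, tolerance = 5e-2)
  expect_error(psa_spec(fit_t3, cost_epob = list(dist = "LOGNORMAL", mean = -5)),
               "positive arithmetic mean")
})
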