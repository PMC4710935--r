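test_that("rollback returns expected cost and effectiveness of a two-leaf arm", {
  expect_equal(rollback(decision_tree(1, 100, 999)), c(cost = 100, eff = 1))
  expect_equal(rollback(decision_tree(0.5, 100, 200)), c(cost = 150, eff = 0.5))
  expect_error(decision_tree(1.2, 100, 100), "\\[0, 1\\]")
  expect_error(decision_tree(0.5, -1, 100), "non-negative")
})

test_that("rollback equals exhaustive leaf enumeration on random trees", {
  set.seed(101)
  for (i in 1:300) {
    tree <- decision_tree(runif(1), runif(1, 0, 5000), runif(1, 0, 5000))
    expect_equal(rollback(tree), enumerate_tree(tree), tolerance = 1e-12)
  }
})

test_that("ACER divides mean cost by mean effectiveness", {
  expect_equal(acer(3288.49, 0.55), 5979.0727, tolerance = 1e-4)
  expect_equal(acer(100, 1), 100)
  # back-solving the published ACER implies unrounded effectiveness ~ 0.5857
  expect_equal(acer(3030.19, 0.5857), 5173.64, tolerance = 1e-4)
  expect_true(is.na(acer(100, 0)))
  expect_error(acer(100, -0.1), "non-negative")
})

test_that("the incremental comparison reproduces the published base case", {
  r <- icer(3288.49, 0.55, 3030.19, 0.59)
  expect_equal(r$delta_cost, -258.30, tolerance = 1e-9)
  expect_equal(r$delta_eff, 0.04, tolerance = 1e-9)
  expect_equal(r$icer, -6457.5, tolerance = 1e-9)
  expect_equal(r$dominance, "DOMINANT")
})

test_that("degenerate and trade-off comparisons are classified correctly", {
  tie <- icer(100, 0.5, 100, 0.5)
  expect_equal(tie$delta_cost, 0)
  expect_false(tie$icer_defined)
  expect_true(is.na(tie$icer))

  ne <- icer(100, 0.5, 120, 0.6)
  expect_equal(ne$icer, 200)
  expect_equal(ne$dominance, "TRADEOFF_NE")

  dominated <- icer(100, 0.6, 120, 0.5)
  expect_equal(dominated$dominance, "DOMINATED")

  sw <- icer(120, 0.6, 100, 0.5)
  expect_equal(sw$dominance, "TRADEOFF_SW")
})

test_that("incremental comparison is antisymmetric and scale-equivariant", {
  set.seed(77)
  for (i in 1:50) {
    ce <- runif(2, 500, 5000); ee <- runif(2, 0.05, 0.95)
    ab <- icer(ce[1], ee[1], ce[2], ee[2])
    ba <- icer(ce[2], ee[2], ce[1], ee[1])
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_eff, -ba$delta_eff)
    if (ab$icer_defined) expect_equal(ab$icer, ba$icer)
    k <- runif(1, 0.1, 10)
    sc <- icer(k * ce[1], ee[1], k * ce[2], ee[2])
    expect_equal(sc$acer_per_arm, k * ab$acer_per_arm)
    if (ab$icer_defined) expect_equal(sc$icer, k * ab$icer)
  }
})

test_that("threshold decision implements the WTP rule in every quadrant", {
  cfg <- cea_config() # threshold 3 x 3092 = 9276
  base <- icer(3288.49, 0.55, 3030.19, 0.59)
  expect_true(threshold_decision(base, cfg)) # dominant

  over <- icer(1000, 0.55, 1400, 0.59) # ICER 10000 > 9276
  expect_equal(over$icer, 10000, tolerance = 1e-9)
  expect_false(threshold_decision(over, cfg))

  under <- icer(1000, 0.55, 1200, 0.59) # ICER 5000 < 9276
  expect_true(threshold_decision(under, cfg))

  dominated <- icer(1000, 0.56, 1001, 0.55)
  expect_false(threshold_decision(dominated, cfg))

  # cheaper-but-less-effective: cost-effective only when savings per unit
  # effectiveness lost are at least the threshold
  sw_good <- icer(1500, 0.59, 1000, 0.55) # saves 12500 per unit lost
  expect_true(threshold_decision(sw_good, cfg))
  sw_bad <- icer(1100, 0.59, 1000, 0.55) # saves only 2500 per unit lost
  expect_false(threshold_decision(sw_bad, cfg))

  # literal override replaces the 3 x GDP rule
  cfg2 <- cea_config(threshold_override = 9186)
  expect_false(threshold_decision(icer(1000, 0.55, 1372, 0.59), cfg2)) # 9300
  expect_true(threshold_decision(icer(1000, 0.55, 1366, 0.59), cfg2))  # 9150
})

test_that("the fitted model replays the published inputs end to end", {
  fit <- cea(load_table3())
  expect_s3_class(fit, "cea")
  expect_equal(unname(coef(fit)),
               c(-258.30, 0.04, -6457.5), tolerance = 1e-9)
  expect_equal(fit$result$dominance, "DOMINANT")
  expect_true(fit$cost_effective)
  expect_equal(fit$threshold, 9276)
  # published effectiveness mode vs computed CSR mode
  expect_equal(unname(fit$result$eff_per_arm), c(0.55, 0.59))
  fit_csr <- cea(load_table3(), cea_config(effectiveness_mode = "CSR"))
  expect_equal(unname(fit_csr$result$eff_per_arm), c(49, 53) / 75)
  expect_equal(fit_csr$result$dominance, "DOMINANT")
})

test_that("fitting a cohort rolls per-range leaf costs back to the arm mean", {
  co <- two_arm_cohort(3, 4, 2, 4, cost_epob = 270, cost_cera = 250)
  fit <- cea(co, cea_config(effectiveness_mode = "CSR"))
  s <- summarize_arms(co, cea_config(effectiveness_mode = "CSR"))
  # with success/fail leaf costs, rollback reproduces the weighted mean
  expect_equal(unname(fit$result$cost_per_arm),
               s$csr * 2 * s$cost_success + (1 - s$csr) * 2 * s$cost_fail)
  expect_equal(unname(fit$result$eff_per_arm), s$csr)
  expect_error(cea(toy_cohort(11)), "both arms")
})

test_that("model summaries and JSON export carry the key quantities", {
  fit <- cea(load_table3())
  sm <- summary(fit)
  expect_equal(sm$icer, -6457.5, tolerance = 1e-9)
  expect_equal(sm$dominance, "DOMINANT")
  js <- jsonlite::fromJSON(write_cea_json(fit))
  expect_equal(js$icer, -6457.5, tolerance = 1e-9)
  expect_true(js$cost_effective)
})
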