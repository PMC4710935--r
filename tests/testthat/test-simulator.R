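test_that("EpoB-to-CERA conversion follows the dose tiers with closed middle range", {
  expect_equal(convert_epob_to_cera(6000), 120)
  expect_equal(convert_epob_to_cera(7999.9), 120)
  expect_equal(convert_epob_to_cera(8000), 200)
  expect_equal(convert_epob_to_cera(16000), 200)
  expect_equal(convert_epob_to_cera(16000.1), 360)
  expect_equal(convert_epob_to_cera(20000), 360)
  expect_error(convert_epob_to_cera(0), "positive")
  expect_error(convert_epob_to_cera(-100), "positive")
})

test_that("monthly titration adjusts by 25% only on >1 g/dL swings", {
  expect_equal(titrate_dose(8000, 11.0, 12.3), 6000)   # rise > 1: -25%
  expect_equal(titrate_dose(8000, 11.0, 11.5), 8000)   # within band
  expect_equal(titrate_dose(120, 11.5, 10.2), 150)     # fall > 1: +25%
  expect_equal(titrate_dose(100, 11.0, 12.0), 100)     # exactly +1: no change
  expect_equal(titrate_dose(100, 12.0, 11.0), 100)     # exactly -1: no change
})

test_that("iron start/stop triggers follow thresholds with stop precedence", {
  expect_true(iron_rule(90, 25, FALSE))    # ferritin < 100 starts
  expect_false(iron_rule(850, 30, TRUE))   # ferritin > 800 stops
  expect_true(iron_rule(300, 30, TRUE))    # no trigger: unchanged
  expect_false(iron_rule(300, 30, FALSE))
  expect_true(iron_rule(300, 15, FALSE))   # TSAT < 20 starts
  expect_false(iron_rule(300, 55, TRUE))   # TSAT > 50 stops
  # contradictory triggers: stop wins
  expect_false(iron_rule(90, 55, TRUE))
})

test_that("identical parameters and seed give bit-identical cohorts", {
  p <- sim_params(n_patients = 15, seed = 42)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  p2 <- sim_params(n_patients = 15, seed = 43)
  expect_false(identical(simulate_cohort(p), simulate_cohort(p2)))
})

test_that("patient trajectories do not depend on cohort size or ordering", {
  big <- simulate_cohort(sim_params(n_patients = 20, seed = 5))
  small <- simulate_cohort(sim_params(n_patients = 10, seed = 5))
  shared <- small$patient_id
  expect_identical(small$hb_3,
                   big$hb_3[match(paste(shared, small$arm),
                                  paste(big$patient_id, big$arm))])
})

test_that("a noiseless in-range cohort has CSR 1 and constant doses", {
  p <- sim_params(n_patients = 10, seed = 1,
                  target_hb_mean = c(EPOB = 11.2, CERA = 11.2),
                  target_hb_sd = c(EPOB = 0, CERA = 0),
                  hb_month_sd = 0,
                  dose_response_epob = 0, dose_response_cera = 0)
  co <- simulate_cohort(p)
  cls <- classify_phases(co)
  expect_true(all(cls$mean_hb == 11.2))
  expect_true(all(cls$category == "IN_RANGE"))
  # titration safety: constant Hb never changes the dose
  d <- as.matrix(co[paste0("dose_", 1:6)])
  expect_true(all(d == d[, 1]))
})

test_that("monthly costs equal dose times unit price under the costing rule", {
  p <- sim_params(n_patients = 6, seed = 9)
  co <- simulate_cohort(p)
  d <- as.matrix(co[paste0("dose_", 1:6)])
  cost <- as.matrix(co[paste0("cost_", 1:6)])
  epob <- co$arm == "EPOB"
  expect_equal(unname(cost[epob, ]),
               unname(d[epob, ] * p$weeks_per_month / 1000 * p$epob_unit_price),
               tolerance = 1e-12)
  expect_equal(unname(cost[!epob, ]), unname(d[!epob, ] * p$cera_unit_price),
               tolerance = 1e-12)
})

test_that("conversion dose mode starts CERA from the tiered conversion table", {
  p <- sim_params(n_patients = 30, seed = 2, cera_dose_mode = "conversion")
  co <- simulate_cohort(p)
  expect_true(all(co$dose_1[co$arm == "CERA"] %in% c(120, 200, 360)))
})

test_that("default cohort reproduces the published phase conditions", {
  co <- simulate_cohort(sim_params(seed = 1))
  cfg <- cea_config(effectiveness_mode = "CSR")
  s <- summarize_arms(co, cfg)
  cls <- classify_phases(co, cfg)
  # CSR within the exact binomial 95% interval around the published rates
  ci_e <- stats::binom.test(49, 75)$conf.int
  ci_c <- stats::binom.test(53, 75)$conf.int
  expect_gte(s$csr[s$arm == "EPOB"], ci_e[1])
  expect_lte(s$csr[s$arm == "EPOB"], ci_e[2])
  expect_gte(s$csr[s$arm == "CERA"], ci_c[1])
  expect_lte(s$csr[s$arm == "CERA"], ci_c[2])
  # 6-month EpoB drug cost within 10% of the published mean
  expect_lt(abs(s$mean_cost_6mo[s$arm == "EPOB"] - 1644.2) / 1644.2, 0.10)
  # phase-mean Hb close to the published phase means
  m_e <- mean(cls$mean_hb[cls$arm == "EPOB"])
  m_c <- mean(cls$mean_hb[cls$arm == "CERA"])
  expect_lt(abs(m_e - 11.25), 0.3)
  expect_lt(abs(m_c - 11.42), 0.3)
})

test_that("unit prices back-solved from published doses recover published costs", {
  p <- sim_params()
  expect_equal(6104 * 26 / 1000 * p$epob_unit_price, 1644.2, tolerance = 1e-9)
  expect_equal(106.4 * 6 * p$cera_unit_price, 1515.5, tolerance = 1e-9)
})
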