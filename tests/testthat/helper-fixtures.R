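# Small hand-built cohorts used across tests.

# n patient-phases with constant monthly values per row.
toy_cohort <- function(hb_means, arms = rep("EPOB", length(hb_means)),
                       dose = 6000, cost = 250) {
  n <- length(hb_means)
  cohort(
    patient_id = sprintf("p%02d", seq_len(n)),
    arm = arms,
    hb = matrix(rep(hb_means, 6), nrow = n),
    dose = matrix(dose, n, 6),
    cost = matrix(cost, n, 6)
  )
}

# Two-arm cohort with per-arm in-range counts and distinct flat costs.
two_arm_cohort <- function(n_in_epob, n_epob, n_in_cera, n_cera,
                           cost_epob = 270, cost_cera = 250) {
  hb_e <- c(rep(11, n_in_epob), rep(9.5, n_epob - n_in_epob))
  hb_c <- c(rep(11, n_in_cera), rep(13, n_cera - n_in_cera))
  co_e <- toy_cohort(hb_e, rep("EPOB", n_epob), cost = cost_epob)
  co_c <- toy_cohort(hb_c, rep("CERA", n_cera), cost = cost_cera)
  co_c$patient_id <- sprintf("c%02d", seq_len(n_cera))
  rbind(co_e, co_c)
}

# Independent brute-force oracle for decision-tree rollback: enumerate the
# leaves and weight each payoff by its path probability.
enumerate_tree <- function(tree) {
  leaves <- list(
    list(prob = tree$p, cost = tree$cost_success, eff = tree$eff_success),
    list(prob = 1 - tree$p, cost = tree$cost_fail, eff = tree$eff_fail)
  )
  cost <- 0; eff <- 0
  for (lf in leaves) {
    cost <- cost + lf$prob * lf$cost
    eff <- eff + lf$prob * lf$eff
  }
  c(cost = cost, eff = eff)
}
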