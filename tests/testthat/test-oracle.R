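# Closed-form derivations and exact CME cross-checks of the engines.

single_subunit_system <- function() {
  sys <- chain_system()
  sys$flags <- sys$flags[1, , drop = FALSE]
  sys$kinase_map <- sys$kinase_map[0, ]
  sys
}

# rate table restricted to a subsystem (all other rates zero)
only_rates <- function(...) {
  zero <- list(k_dock = 0, k_undock = 0, k_activate = 0, k_inactivate = 0,
               k_on_CaM = 0, k_off_CaM_ini = 0, k_ini_to_full = 0,
               k_full_to_ini = 0, k_autophos = 0, k_phos_T306 = 0,
               k_on_PP = 0, k_off_PP = 0, k_cat_PP = 0)
  keep <- list(...)
  zero[names(keep)] <- keep
  do.call(rate_table, zero)
}

test_that("derived parameters reproduce the printed constants and the rate table", {
  d <- derive_parameters()
  expect_equal(d$K_docking, 0.018)
  expect_equal(d$k_undock, 0.63)
  expect_equal(d$k_off_CaM_ini, 590)
  expect_equal(d$initial_full_occupancy_ratio, 1.1e-5, tolerance = 0.05)
  expect_equal(d$K_M_PP, 8.3e-7, tolerance = 0.01)
  expect_equal(d$p_act, 0.002, tolerance = 0.002)
  # the rate table is not free to drift from the derivations
  r <- rate_table()
  expect_equal(d$k_undock, r$k_undock)
  expect_equal(d$k_off_CaM_ini, r$k_off_CaM_ini)
  expect_equal(d$p_act, activation_probability(r))
  expect_equal(d$K_M_PP, (r$k_off_PP + r$k_cat_PP) / r$k_on_PP)
})

test_that("activation-only CME has the textbook two-state generator", {
  sys <- single_subunit_system()
  cme <- enumerate_cme(sys, pools(), rule_table(only_rates(
    k_activate = 2e4, k_inactivate = 1e7)))
  expect_equal(cme$n, 2)
  Q <- as.matrix(cme$Q)
  expect_equal(Q, matrix(c(-2e4, 1e7, 2e4, -1e7), 2, 2),
               ignore_attr = TRUE)
  stat <- solve_cme(cme, t = 0, stationary = TRUE)
  expect_equal(stat[2], 2e4 / (2e4 + 1e7), tolerance = 1e-10)  # ~0.002
})

test_that("docking-only CME recovers the docking equilibrium", {
  sys <- single_subunit_system()
  cme <- enumerate_cme(sys, pools(), rule_table(only_rates(
    k_dock = 35, k_undock = 0.63)))
  expect_equal(cme$n, 2)
  stat <- solve_cme(cme, t = 0, stationary = TRUE)
  expect_equal(stat[2], 0.018 / 1.018, tolerance = 1e-10)      # ~0.0177
  # docking + activation only: 4 states
  cme4 <- enumerate_cme(sys, pools(), rule_table(only_rates(
    k_dock = 35, k_undock = 0.63, k_activate = 2e4, k_inactivate = 1e7)))
  expect_equal(cme4$n, 4)
})

test_that("CME contract checks", {
  sys <- single_subunit_system()
  rules <- rule_table(rate_table())
  cme <- enumerate_cme(sys, pools(free_CaM4 = 5, free_PP = 1), rules)
  # generator rows sum to zero, off-diagonals non-negative
  expect_true(all(abs(Matrix::rowSums(cme$Q)) < 1e-8))
  offdiag <- cme$Q - Matrix::Diagonal(cme$n, Matrix::diag(cme$Q))
  expect_true(all(offdiag@x >= 0))
  # t = 0 returns the initial distribution; normalisation preserved
  expect_equal(solve_cme(cme, 0)[1], 1)
  expect_equal(sum(solve_cme(cme, 0.1)), 1, tolerance = 1e-9)
  # cap errors name the count
  expect_error(enumerate_cme(sys, pools(free_CaM4 = 5, free_PP = 1), rules,
                             max_states = 5), "cap")
})

test_that("SSA matches the CME transient for 1 subunit with all flags (3 SE)", {
  sys <- single_subunit_system()
  p <- pools(free_CaM4 = 5, free_PP = 1)
  cme <- enumerate_cme(sys, p, rule_table(rate_table()))
  pr <- solve_cme(cme, t = 0.05)
  m <- cme_marginals(cme, pr)
  ens <- run_replicates(sys, p, rate_table(),
    engine_config(scheme = "ssa", t_end = 0.05, record_interval = 0.05,
                  seed = 4000, n_replicates = 1500),
    stimulus_protocol("continuous_bolus"))
  finals <- sapply(ens$final_flags, function(f) f[1, ])
  n <- ncol(finals)
  check <- function(obs_p, cme_p) {
    se <- sqrt(max(cme_p * (1 - cme_p), 1e-6) / n)
    expect_lt(abs(obs_p - cme_p), 3 * se)
  }
  check(mean(finals["docking", ] == 1), m$docking[["undocked"]])
  check(mean(finals["cam", ] == 1), m$cam[["initial"]])
  check(mean(finals["cam", ] == 2), m$cam[["full"]])
})

test_that("SSA matches the CME for the 2-subunit autophosphorylation chain (3 SE)", {
  # chain starts CaM-loaded so the neighbor-gated rule is exercised;
  # flicker slowed 1000-fold (p_act unchanged) to keep both routes cheap
  rates <- slow_flicker_rates(exclusivity = "non_exclusive")
  chain <- chain_system()
  chain$flags[, "docking"] <- 1L
  chain$flags[, "cam"] <- 2L
  chain$flags[, "conformation"] <- 1L
  p <- pools(free_CaM4 = 0, free_PP = 1)
  cme <- enumerate_cme(chain, p, rule_table(rates))
  pr <- solve_cme(cme, t = 2)
  m1 <- cme_marginals(cme, pr, subunit = 1)
  ens <- run_replicates(chain, p, rates,
    engine_config(scheme = "ssa", t_end = 2, record_interval = 2,
                  seed = 300, n_replicates = 1500),
    stimulus_protocol("continuous_bolus"))
  f1 <- sapply(ens$final_flags, function(f) f[1, "t286"])
  n <- length(f1)
  for (v in 0:2) {
    cme_p <- m1$t286[[v + 1]]
    se <- sqrt(max(cme_p * (1 - cme_p), 1e-6) / n)
    expect_lt(abs(mean(f1 == v) - cme_p), 3 * se)
  }
  # directionality: subunit 2 has no kinase, so it is never phosphorylated
  f2 <- sapply(ens$final_flags, function(f) f[2, "t286"])
  expect_true(all(f2 == 0))
  expect_equal(cme_marginals(cme, pr, 2)$t286[["pT286"]], 0)
})

test_that("SSA stationary occupancies recover P(active) ~ 0.002 and P(undocked) ~ 0.0177", {
  sys <- single_subunit_system()
  ens <- run_replicates(sys, pools(), rate_table(),
    engine_config(scheme = "ssa", t_end = 10, record_interval = 0.001,
                  seed = 77, n_replicates = 5),
    stimulus_protocol("none"))
  act <- observable_matrix(ens, "active")
  und <- observable_matrix(ens, "undocked")
  burn <- ceiling(nrow(act) / 4)
  expect_equal(mean(act[-seq_len(burn), ]), 0.002, tolerance = 0.25)
  expect_equal(mean(und[-seq_len(burn), ]), 0.0177, tolerance = 0.25)
})
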