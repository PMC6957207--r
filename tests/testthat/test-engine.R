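# Engine behavior: determinism, the fixed-step probability cap, empty
# systems, and cross-scheme equivalence.

test_that("identical configuration and seed give bit-identical ensembles", {
  run <- function() simulate_camkii(n_holo = 2, n_CaM = 30, n_PP = 2,
    engine = engine_config(scheme = "qssa", t_end = 2, seed = 5,
                           n_replicates = 3),
    protocol = stimulus_protocol("continuous_bolus"))
  a <- run(); b <- run()
  expect_identical(a$obs, b$obs)
  expect_identical(a$final_flags, b$final_flags)
  # replicate seeds are base + r - 1
  expect_equal(a$seeds, 5:7)
  # different seed differs
  c <- simulate_camkii(n_holo = 2, n_CaM = 30, n_PP = 2,
    engine = engine_config(scheme = "qssa", t_end = 2, seed = 99,
                           n_replicates = 3))
  expect_false(identical(a$obs, c$obs))
})

test_that("fixed-step refuses a timestep that violates the p <= 0.1 cap", {
  # with the conformational flicker at 1e7 s^-1, dt = 1e-7 gives p ~ 0.63
  expect_error(
    simulate_camkii(n_holo = 1, n_CaM = 0, n_PP = 0,
      engine = engine_config(scheme = "fixed_step", dt = 1e-7, t_end = 1e-4,
                             seed = 1, n_replicates = 1)),
    "exceeds 0.1")
  # per-step probability arithmetic: 1 - exp(-k dt)
  expect_equal(1 - exp(-590 * 1e-7), 5.9e-5, tolerance = 1e-2)
  expect_equal(1 - exp(-1e7 * 1e-7), 0.632, tolerance = 1e-2)
})

test_that("a system with no eligible transitions stays in its initial state", {
  zero <- rate_table(k_dock = 0, k_undock = 0, k_activate = 0,
                     k_inactivate = 0, k_on_CaM = 0, k_off_CaM_ini = 0,
                     k_ini_to_full = 0, k_full_to_ini = 0, k_autophos = 0,
                     k_phos_T306 = 0, k_on_PP = 0, k_off_PP = 0, k_cat_PP = 0)
  ens <- simulate_camkii(n_holo = 1, n_CaM = 10, n_PP = 1, rates = zero,
    engine = engine_config(scheme = "ssa", t_end = 1, seed = 1,
                           n_replicates = 1))
  final <- ens$final_flags[[1]]
  expect_true(all(final[, c("docking", "conformation", "cam", "t286")] == 0L))
  expect_true(all(observable_matrix(ens, "pT286") == 0))
})

test_that("fixed_step, ssa and qssa agree on mean flag counts (3 SE)", {
  # 1 holoenzyme, 10 CaM, 1 PP, continuous bolus. The flicker is slowed
  # 1000-fold (same p_act) so the exact schemes resolve it affordably;
  # fixed_step runs at dt = 1e-5 (p_max ~ 0.095 under the slowed flicker,
  # the same margin the full-rate model has at dt = 1e-8).
  rates <- slow_flicker_rates()
  sys <- small_system()
  p <- pools(free_CaM4 = 10, free_PP = 1)
  prot <- stimulus_protocol("continuous_bolus")
  n_rep <- 200
  run <- function(scheme, dt = 1e-5, seed) {
    run_replicates(sys, p, rates,
                   engine_config(scheme = scheme, dt = dt, t_end = 0.5,
                                 record_interval = 0.5, seed = seed,
                                 n_replicates = n_rep), prot)
  }
  ssa <- run("ssa", seed = 1000)
  qssa <- run("qssa", seed = 3000)
  fixed <- run("fixed_step", seed = 5000)
  for (obsname in c("cam_initial", "cam_full", "undocked")) {
    vals <- lapply(list(ssa, qssa, fixed), function(e) {
      m <- observable_matrix(e, obsname)
      m[nrow(m), ]
    })
    means <- vapply(vals, mean, numeric(1))
    sems <- vapply(vals, function(v) stats::sd(v) / sqrt(length(v)),
                   numeric(1))
    for (i in 1:2) for (j in (i + 1):3) {
      se <- sqrt(sems[i]^2 + sems[j]^2)
      expect_lt(abs(means[i] - means[j]), 3 * max(se, 1e-3))
    }
  }
})

test_that("QSSA expected active count tracks the SSA time-averaged count", {
  # unstimulated holoenzyme: active subunits only via the flicker
  rates <- slow_flicker_rates()
  sys <- small_system()
  ssa <- run_replicates(sys, pools(), rates,
    engine_config(scheme = "ssa", t_end = 5, record_interval = 0.01,
                  seed = 11, n_replicates = 20), stimulus_protocol("none"))
  qssa <- run_replicates(sys, pools(), rates,
    engine_config(scheme = "qssa", t_end = 5, record_interval = 0.01,
                  seed = 11, n_replicates = 1), stimulus_protocol("none"))
  ssa_mean <- mean(observable_matrix(ssa, "active"))
  qssa_mean <- mean(observable_matrix(qssa, "active"))
  expect_equal(qssa_mean, 12 * activation_probability(rates),
               tolerance = 1e-9)  # deterministic expected value here
  n <- length(observable_matrix(ssa, "active"))
  expect_lt(abs(ssa_mean - qssa_mean), 3 * 0.05)  # generous MC band
})

test_that("ensembles carry config fingerprint and frames within bounds", {
  ens <- simulate_camkii(n_holo = 1, n_CaM = 10, n_PP = 1,
    engine = engine_config(scheme = "qssa", t_end = 1, seed = 2,
                           n_replicates = 2))
  expect_equal(length(ens$times), 101)
  expect_true(all(diff(ens$times) > 0))
  for (m in ens$obs) {
    expect_true(all(m[, "pT286"] >= 0 & m[, "pT286"] <= 12))
    expect_true(all(m[, "free_CaM4"] >= 0))
  }
  expect_s3_class(ens$config$rates, "camkii_rates")
  df <- as.data.frame(ens)
  expect_equal(nrow(df), 202)
  expect_true(all(c("replicate", "time", "pT286") %in% names(df)))
})
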