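# Property suite: conservation laws, state invariants on every recorded
# frame, phosphate monotonicity under inhibitors, and degenerate inputs.

test_that("CaM and PP totals are conserved on every frame, all engines", {
  for (scheme in c("qssa", "ssa")) {
    ens <- simulate_camkii(n_holo = 2, n_CaM = 30, n_PP = 3,
      engine = engine_config(scheme = scheme, t_end = 1,
                             record_interval = 0.05, seed = 31,
                             n_replicates = 3),
      protocol = stimulus_protocol("pulse_train", frequency = 5))
    check_cam_conservation(ens, 30)
    check_pp_conservation(ens, 3)
  }
  # fixed_step with the slowed flicker
  ens <- simulate_camkii(n_holo = 1, n_CaM = 10, n_PP = 2,
    rates = slow_flicker_rates(),
    engine = engine_config(scheme = "fixed_step", dt = 1e-5, t_end = 0.2,
                           record_interval = 0.01, seed = 32,
                           n_replicates = 3))
  check_cam_conservation(ens, 10)
  check_pp_conservation(ens, 2)
})

test_that("subunit state invariants hold on every snapshot, every variant", {
  for (mode in c("exclusive", "non_exclusive")) {
    ens <- simulate_camkii(n_holo = 2, n_CaM = 30, n_PP = 3,
      rates = rate_table(exclusivity = mode),
      engine = engine_config(scheme = "qssa", t_end = 5,
                             record_interval = 0.1, seed = 33,
                             n_replicates = 2, snapshot_interval = 0.5),
      protocol = stimulus_protocol("finite_bolus", bolus_duration = 2))
    for (r in seq_along(ens$snapshots))
      for (snap in ens$snapshots[[r]])
        check_state_invariants(snap, exclusive = mode == "exclusive")
    for (f in ens$final_flags)
      check_state_invariants(f, exclusive = mode == "exclusive")
  }
})

test_that("cumulative phosphate count is non-decreasing when catalysis is off", {
  ens <- simulate_camkii(n_holo = 2, n_CaM = 30, n_PP = 3,
    rates = rate_table(k_cat_PP = 0),
    engine = engine_config(scheme = "qssa", t_end = 5, record_interval = 0.05,
                           seed = 34, n_replicates = 3))
  for (m in ens$obs) {
    phosphate <- m[, "pT286"] + m[, "pp_bound"]
    expect_true(all(diff(phosphate) >= 0))
  }
})

test_that("kinase inhibition makes the phosphate count non-increasing after the event", {
  prot <- stimulus_protocol("finite_bolus", bolus_duration = 2,
    events = data.frame(time = 5, kind = "kinase_inhibitor"))
  ens <- simulate_camkii(n_holo = 3, n_CaM = 45, n_PP = 3,
    engine = engine_config(scheme = "qssa", t_end = 15,
                           record_interval = 0.1, seed = 35,
                           n_replicates = 3),
    protocol = prot)
  for (m in ens$obs) {
    after <- m[, "time"] > 5
    phosphate <- m[after, "pT286"] + m[after, "pp_bound"]
    expect_true(all(diff(phosphate) <= 0))
    # the cumulative counter freezes: no new autophosphorylation
    expect_true(all(diff(m[after, "cum_phos"]) == 0))
  }
})

test_that("phosphatase inhibition makes the phosphate count non-decreasing after the event", {
  prot <- stimulus_protocol("continuous_bolus",
    events = data.frame(time = 2, kind = "phosphatase_inhibitor"))
  ens <- simulate_camkii(n_holo = 3, n_CaM = 45, n_PP = 3,
    engine = engine_config(scheme = "qssa", t_end = 10,
                           record_interval = 0.1, seed = 36,
                           n_replicates = 3),
    protocol = prot)
  for (m in ens$obs) {
    after <- m[, "time"] > 2
    phosphate <- m[after, "pT286"] + m[after, "pp_bound"]
    expect_true(all(diff(phosphate) >= 0))
  }
})

test_that("without CaM, unassisted autophosphorylation is effectively absent", {
  # guard chain requires two simultaneous spontaneous activations
  ens <- simulate_camkii(n_holo = 5, n_CaM = 0, n_PP = 0,
    engine = engine_config(scheme = "qssa", t_end = 20,
                           record_interval = 0.5, seed = 37,
                           n_replicates = 3),
    protocol = stimulus_protocol("none"))
  for (r in seq_along(ens$obs)) {
    ever <- ens$obs[[r]][nrow(ens$obs[[r]]), "cum_phos"]
    expect_lt(ever / 60, 0.01)   # < 1% of subunits over 20 s
  }
})

test_that("K252a event blocks autophosphorylation but not dephosphorylation", {
  # start phosphorylated with PP present and CaM absent: with the kinase
  # inhibitor in place from t = 0, pT286 can only decline
  sys <- build_holoenzyme(1)
  sys$flags[, "t286"] <- 1L
  sys$flags[, "inhibitor"] <- 1L
  ens <- run_replicates(sys, pools(free_PP = 5), rate_table(),
    engine_config(scheme = "qssa", t_end = 10, record_interval = 0.1,
                  seed = 38, n_replicates = 3),
    stimulus_protocol("none"))
  final <- endpoint(ens, "pT286")
  expect_lt(final["mean"], 12)
  for (m in ens$obs) expect_true(all(diff(m[, "pT286"] + m[, "pp_bound"]) <= 0))
})
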