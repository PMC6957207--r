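# Shared fixtures: small systems and rate variants used across tests.

# standard compartment constants
VOL <- 0.0328e-15

small_system <- function(n_holo = 1, dof = 1) build_holoenzyme(n_holo, dof)

# rate table with the conformational flicker slowed 1000x but the same
# activation probability p_act = 0.002; used where the exact SSA or the
# CME transient must resolve the flicker affordably
slow_flicker_rates <- function(...) {
  rate_table(k_activate = 20, k_inactivate = 1e4, ...)
}

# ensemble mean and SEM of an observable at the final frame
endpoint <- function(ens, observable) {
  m <- observable_matrix(ens, observable)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(ens$obs))
  x <- m[nrow(m), ]
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
}

# CaM conservation check from recorded observables: free CaM pools plus
# subunit-bound CaM must equal the total at every frame
check_cam_conservation <- function(ens, total) {
  for (m in ens$obs) {
    tot <- m[, "free_CaM4"] + m[, "free_apo_CaM"] +
      m[, "cam_initial"] + m[, "cam_full"]
    expect_true(all(tot == total))
  }
}

check_pp_conservation <- function(ens, total) {
  for (m in ens$obs) {
    expect_true(all(m[, "free_PP"] + m[, "pp_bound"] == total))
  }
}

# per-subunit invariant check on a flag snapshot matrix
check_state_invariants <- function(flags, exclusive = TRUE) {
  expect_true(all(flags[flags[, "docking"] == 0L, "cam"] == 0L))
  expect_true(all(flags[flags[, "t306"] == 1L, "cam"] == 0L))
  expect_true(all(flags[flags[, "cam"] == 2L, "conformation"] == 1L))
  if (exclusive)
    expect_true(all(flags[flags[, "t286"] == 2L, "cam"] == 0L))
}
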