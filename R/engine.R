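# Engine configuration and seeded replicate management.

#' Engine configuration
#'
#' @param scheme `"qssa"` (default production engine; marginalises the
#'   1e7 s^-1 conformational flicker), `"ssa"` (exact trajectories of the
#'   full rule system) or `"fixed_step"` (MCell-like per-step Bernoulli
#'   sampling; requires `dt` small enough that every per-step firing
#'   probability stays below 0.1 — with the flicker active this means
#'   dt <= ~1e-8 s).
#' @param dt fixed-step timestep in seconds (fixed_step only)
#' @param t_end simulated duration in seconds (> 0)
#' @param record_interval observable recording interval in seconds
#' @param seed base RNG seed; replicate r runs with seed `seed + r - 1`
#' @param n_replicates number of replicates
#' @param snapshot_interval if > 0, full per-subunit flag snapshots are
#'   recorded every `snapshot_interval` seconds (memory permitting)
#' @return object of class `engine_config`
#' @export
engine_config <- function(scheme = c("qssa", "ssa", "fixed_step"),
                          dt = 1e-7, t_end = 20, record_interval = 0.01,
                          seed = 1L, n_replicates = 50L,
                          snapshot_interval = 0) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= 0) stop("t_end must be > 0")
  if (record_interval <= 0) stop("record_interval must be > 0")
  if (scheme == "fixed_step" && record_interval < dt)
    stop("record_interval must be >= dt for fixed_step")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(scheme = scheme, dt = dt, t_end = t_end,
                 record_interval = record_interval, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 snapshot_interval = snapshot_interval),
            class = "engine_config")
}

scheme_code <- function(scheme)
  match(scheme, c("ssa", "qssa", "fixed_step")) - 1L

# Assemble the parameter list handed to the C++ engine: macroscopic
# association constants become per-pair propensities for the compartment.
engine_params <- function(rates, volume) {
  list(
    k_dock = rates$k_dock, k_undock = rates$k_undock,
    k_activate = rates$k_activate, k_inactivate = rates$k_inactivate,
    kon_cam_pair = bimolecular_propensity(rates$k_on_CaM, volume),
    k_off_cam_ini = rates$k_off_CaM_ini,
    k_ini_to_full = rates$k_ini_to_full,
    k_full_to_ini = rates$k_full_to_ini,
    k_autophos = rates$k_autophos, k_phos_t306 = rates$k_phos_T306,
    kon_pp_pair = bimolecular_propensity(rates$k_on_PP * rates$kon_PP_scale,
                                         volume),
    k_off_pp = rates$k_off_PP, k_cat_pp = rates$k_cat_PP,
    p_act = activation_probability(rates),
    exclusive = identical(rates$exclusivity, "exclusive"),
    pp_bound_counts_as_phospho = rates$pp_bound_counts_as_phospho,
    dock_requires_inactive = rates$dock_requires_inactive,
    k252a_blocks_kinase_role = rates$k252a_blocks_kinase_role,
    stochastic_forcing = rates$stochastic_forcing
  )
}

# kinase_map data.frame -> N x 3 matrix of 0-based kinase indices
kinase_index_matrix <- function(sys) {
  n <- nrow(sys$flags)
  m <- matrix(-1L, nrow = n, ncol = 3)
  km <- sys$kinase_map
  if (!is.null(km) && nrow(km)) {
    slot <- integer(n)
    for (r in seq_len(nrow(km))) {
      s <- km$substrate[r]
      slot[s] <- slot[s] + 1L
      if (slot[s] > 3L) stop("more than 3 kinase edges for one substrate")
      m[s, slot[s]] <- km$kinase[r] - 1L
    }
  }
  m
}

run_one_replicate <- function(sys, p, rates, engine, protocol, rep_seed) {
  sched <- phase_schedule(protocol, engine$t_end)
  ev <- protocol$events
  if (!is.null(ev) && nrow(ev)) {
    if (any(ev$kind == "chelate_Ca")) {
      warning("chelate_Ca is a no-op in the 2-state model; ignoring")
      ev <- ev[ev$kind != "chelate_Ca", , drop = FALSE]
    }
    ev_t <- ev$time
    ev_k <- match(ev$kind, c("kinase_inhibitor", "phosphatase_inhibitor")) - 1L
  } else {
    ev_t <- numeric(0); ev_k <- integer(0)
  }
  set.seed(rep_seed)
  .sim_run_cpp(sys$flags, kinase_index_matrix(sys),
               p$free_apo_CaM, p$free_CaM4, p$free_PP,
               engine_params(rates, p$volume),
               scheme_code(engine$scheme), engine$dt,
               engine$t_end, engine$record_interval,
               sched$time, sched$activating,
               ev_t, ev_k, engine$snapshot_interval)
}

#' Run a seeded replicate ensemble of the 2-state-2-step model
#'
#' Replicate r is run with RNG seed `engine$seed + r - 1`, so an ensemble
#' is bit-reproducible given its configuration.
#'
#' @param sys a [build_holoenzyme()] system (or any subunit flag matrix +
#'   kinase map wrapped as a `camkii_system`)
#' @param p initial free pools, see [pools()]
#' @param rates a [rate_table()]
#' @param engine an [engine_config()]
#' @param protocol a [stimulus_protocol()]
#' @return object of class `trajectory_ensemble`: recorded times, one
#'   observable matrix per replicate (counts of each flag; the QSSA
#'   engine reports the expected active count
#'   `#stabilised + p_act * #unstabilised`), final subunit states, seeds
#'   and the full configuration
#' @examples
#' sys <- build_holoenzyme(1)
#' ens <- run_replicates(sys, pools(free_CaM4 = 10, free_PP = 1),
#'                       rate_table(), engine_config(t_end = 0.5,
#'                       n_replicates = 2, seed = 7),
#'                       stimulus_protocol("continuous_bolus"))
#' ensemble_stats(ens, "pT286")
#' @export
run_replicates <- function(sys, p, rates = rate_table(),
                           engine = engine_config(),
                           protocol = stimulus_protocol("continuous_bolus")) {
  stopifnot(inherits(sys, "camkii_system"), inherits(p, "camkii_pools"),
            inherits(rates, "camkii_rates"), inherits(engine, "engine_config"),
            inherits(protocol, "stimulus_protocol"))
  seeds <- engine$seed + seq_len(engine$n_replicates) - 1L
  reps <- vector("list", engine$n_replicates)
  for (r in seq_len(engine$n_replicates))
    reps[[r]] <- run_one_replicate(sys, p, rates, engine, protocol, seeds[r])
  structure(list(
    times = reps[[1]]$obs[, "time"],
    obs = lapply(reps, `[[`, "obs"),
    final_flags = lapply(reps, `[[`, "final_flags"),
    snapshots = lapply(reps, `[[`, "snapshots"),
    snapshot_times = reps[[1]]$snapshot_times,
    free_pools = lapply(reps, `[[`, "free_pools"),
    seeds = seeds,
    n_subunits = nrow(sys$flags),
    volume = p$volume,
    config = list(rates = rates, engine = engine, protocol = protocol,
                  pools = p, n_holo = sys$n_holo, dof = sys$dof)
  ), class = "trajectory_ensemble")
}

#' Convenience front end: simulate a standard compartment
#'
#' Builds the holoenzymes and pools from counts and runs the ensemble.
#'
#' @param n_holo holoenzyme count (default 30)
#' @param n_CaM calmodulin count (default 450), instantiated as apo-CaM
#' @param n_PP phosphatase count (default 17)
#' @param volume compartment volume in liters
#' @param rates a [rate_table()]
#' @param engine an [engine_config()]
#' @param protocol a [stimulus_protocol()]
#' @return a `trajectory_ensemble`
#' @export
simulate_camkii <- function(n_holo = 30L, n_CaM = 450L, n_PP = 17L,
                            volume = DEFAULT_VOLUME,
                            rates = rate_table(),
                            engine = engine_config(),
                            protocol = stimulus_protocol("continuous_bolus")) {
  sys <- build_holoenzyme(n_holo, dof = rates$dof)
  p <- pools(free_apo_CaM = n_CaM, free_PP = n_PP, volume = volume)
  run_replicates(sys, p, rates, engine, protocol)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("Trajectory ensemble:", length(x$obs), "replicate(s),",
      length(x$times), "frames,", x$n_subunits, "subunits (",
      x$config$engine$scheme, "engine )\n")
  invisible(x)
}

#' Flatten an ensemble to a long data.frame
#'
#' @param x a `trajectory_ensemble`
#' @param row.names,optional,... ignored (S3 signature)
#' @return data.frame with columns `replicate`, `time` and one column per
#'   observable
#' @export
as.data.frame.trajectory_ensemble <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  out <- do.call(rbind, lapply(seq_along(x$obs), function(r) {
    df <- as.data.frame(x$obs[[r]])
    df$replicate <- r
    df
  }))
  out[, c("replicate", setdiff(names(out), "replicate"))]
}
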