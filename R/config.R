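# Configuration schema, YAML loading, experiment presets, and run output.

#' Default full configuration
#'
#' The default is the standard compartment (30 holoenzymes / 360
#' subunits, 450 CaM, 17 PP in 0.0328 fL) under a continuous CaM4 bolus,
#' 20 s, QSSA engine, 50 replicates — the canonical validation run.
#'
#' @return nested named list (model / engine / stimulus sections)
#' @export
default_config <- function() {
  list(
    model = list(
      n_holo = 30L, n_CaM = 450L, n_PP = 17L, volume = DEFAULT_VOLUME,
      rates = list(
        k_dock = 35, k_undock = 0.63, k_activate = 2e4, k_inactivate = 1e7,
        k_on_CaM = 1e8, k_off_CaM_ini = 590, k_ini_to_full = 350,
        k_full_to_ini = 4e-3, k_autophos = 1, k_phos_T306 = 0.02,
        k_on_PP = 3e6, k_off_PP = 0.5, k_cat_PP = 2
      ),
      exclusivity = "exclusive", dof = 1L, kon_PP_scale = 1,
      pp_bound_counts_as_phospho = FALSE, dock_requires_inactive = FALSE,
      k252a_blocks_kinase_role = TRUE, stochastic_forcing = FALSE
    ),
    engine = list(scheme = "qssa", dt = 1e-7, t_end = 20,
                  record_interval = 0.01, seed = 1L, n_replicates = 50L,
                  snapshot_interval = 0),
    stimulus = list(mode = "continuous_bolus", frequency = NULL,
                    pulse_width = 0.01, bolus_duration = NULL,
                    events = list())
  )
}

check_unknown_keys <- function(x, template, path = "") {
  if (!is.list(x)) return(invisible(NULL))
  unknown <- setdiff(names(x), names(template))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(x))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      check_unknown_keys(x[[k]], template[[k]], paste0(path, k, "."))
  invisible(NULL)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && !is.null(names(override[[k]])) &&
        is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

validate_config <- function(cfg) {
  check_unknown_keys(cfg, default_config())
  full <- merge_config(default_config(), cfg)
  bad <- vapply(full$model$rates, function(v) !is.numeric(v) || v < 0,
                logical(1))
  if (any(bad))
    stop("negative or non-numeric rate(s): ",
         paste(names(full$model$rates)[bad], collapse = ", "))
  if (full$model$n_holo < 1) stop("n_holo must be >= 1")
  full
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, fills every omitted
#' value from [default_config()] (an empty file therefore resolves to the
#' continuous-bolus validation preset), and validates ranges.
#'
#' @param path YAML file path
#' @return validated full configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

# Materialise the R objects for a resolved configuration
config_objects <- function(cfg) {
  m <- cfg$model
  rates <- do.call(rate_table, c(m$rates, list(
    exclusivity = m$exclusivity, dof = m$dof, kon_PP_scale = m$kon_PP_scale,
    pp_bound_counts_as_phospho = m$pp_bound_counts_as_phospho,
    dock_requires_inactive = m$dock_requires_inactive,
    k252a_blocks_kinase_role = m$k252a_blocks_kinase_role,
    stochastic_forcing = m$stochastic_forcing)))
  ev <- cfg$stimulus$events
  events <- if (length(ev))
    do.call(rbind, lapply(ev, function(e)
      data.frame(time = e$time, kind = e$kind)))
  else NULL
  protocol <- stimulus_protocol(cfg$stimulus$mode,
                                frequency = cfg$stimulus$frequency,
                                pulse_width = cfg$stimulus$pulse_width,
                                bolus_duration = cfg$stimulus$bolus_duration,
                                events = events)
  engine <- do.call(engine_config, cfg$engine)
  list(rates = rates, protocol = protocol, engine = engine,
       n_holo = m$n_holo, n_CaM = m$n_CaM, n_PP = m$n_PP,
       volume = m$volume)
}

#' Run a resolved configuration
#'
#' @param cfg a configuration list (see [default_config()]); partial
#'   configurations are completed and validated first
#' @return a `trajectory_ensemble`
#' @export
run_config <- function(cfg) {
  cfg <- validate_config(cfg)
  ob <- config_objects(cfg)
  simulate_camkii(n_holo = ob$n_holo, n_CaM = ob$n_CaM, n_PP = ob$n_PP,
                  volume = ob$volume, rates = ob$rates, engine = ob$engine,
                  protocol = ob$protocol)
}

# ---- presets --------------------------------------------------------------

preset_arms <- function(name) {
  base <- default_config()
  arm <- function(...) merge_config(base, list(...))
  switch(name,
    fig3a_bolus = list(
      bolus = arm(stimulus = list(mode = "continuous_bolus"))),
    fig3bc_5hz_50hz = list(
      hz5 = arm(stimulus = list(mode = "pulse_train", frequency = 5)),
      hz50 = arm(stimulus = list(mode = "pulse_train", frequency = 50))),
    fig3d_freq_sweep = {
      freqs <- c(1, 5, 10, 20, 35, 50)
      arms <- lapply(freqs, function(f)
        arm(stimulus = list(mode = "pulse_train", frequency = f)))
      names(arms) <- paste0("hz", freqs)
      arms
    },
    fig4_pulse_durations = {
      durs <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
      arms <- lapply(durs, function(d)
        arm(stimulus = list(mode = "finite_bolus", bolus_duration = d),
            engine = list(t_end = 120)))
      names(arms) <- paste0("pulse_", durs, "s")
      arms
    },
    fig5_inhibitors = {
      ev <- function(kind) list(list(time = 30, kind = kind))
      list(
        control = arm(stimulus = list(mode = "finite_bolus",
                                      bolus_duration = 2),
                      engine = list(t_end = 120)),
        kinase_inhibitor = arm(
          stimulus = list(mode = "finite_bolus", bolus_duration = 2,
                          events = ev("kinase_inhibitor")),
          engine = list(t_end = 120)),
        phosphatase_inhibitor = arm(
          stimulus = list(mode = "finite_bolus", bolus_duration = 2,
                          events = ev("phosphatase_inhibitor")),
          engine = list(t_end = 120)))
    },
    fig6_exclusivity = {
      arms <- list()
      for (ex in c("exclusive", "non_exclusive"))
        for (sc in c(0.1, 10))
          arms[[paste0(ex, "_kon", sc, "x")]] <-
            arm(model = list(exclusivity = ex, kon_PP_scale = sc),
                stimulus = list(mode = "finite_bolus", bolus_duration = 2),
                engine = list(t_end = 120))
      arms
    },
    fig6e_nonexclusive_inhibitors = {
      ev <- function(kind) list(list(time = 30, kind = kind))
      nonex <- function(...) arm(model = list(exclusivity = "non_exclusive"),
                                 ...)
      list(
        control = nonex(stimulus = list(mode = "finite_bolus",
                                        bolus_duration = 2),
                        engine = list(t_end = 120)),
        kinase_inhibitor = nonex(
          stimulus = list(mode = "finite_bolus", bolus_duration = 2,
                          events = ev("kinase_inhibitor")),
          engine = list(t_end = 120)),
        phosphatase_inhibitor = nonex(
          stimulus = list(mode = "finite_bolus", bolus_duration = 2,
                          events = ev("phosphatase_inhibitor")),
          engine = list(t_end = 120)))
    },
    supp_dof_comparison = {
      arms <- lapply(1:3, function(d)
        arm(model = list(dof = d),
            stimulus = list(mode = "finite_bolus", bolus_duration = 2),
            engine = list(t_end = 20, snapshot_interval = 1)))
      names(arms) <- paste0("dof", 1:3)
      arms
    },
    fig7_nine_state = list(
      nine_state = list(nine_state = TRUE, n_holo = 30L, n_CaM = 450L,
                        n_Ca = 2000L, n_PP = 17L, t_end = 120,
                        chelate_time = 2, n_replicates = 20L,
                        exclusion = "exclusive")),
    stop("unknown preset '", name, "'; available: ",
         paste(available_presets(), collapse = ", "))
  )
}

#' Names of the shipped experiment presets
#' @return character vector
#' @export
available_presets <- function() {
  c("fig3a_bolus", "fig3bc_5hz_50hz", "fig3d_freq_sweep",
    "fig4_pulse_durations", "fig5_inhibitors", "fig6_exclusivity",
    "fig6e_nonexclusive_inhibitors", "fig7_nine_state",
    "supp_dof_comparison")
}

#' Retrieve the resolved configuration(s) of a preset
#'
#' @param name preset name (see [available_presets()])
#' @return named list of full configurations, one per experimental arm
#' @export
experiment_preset <- function(name) preset_arms(name)

#' Run an experiment preset and write its artifacts
#'
#' Runs every arm of the preset with the given base seed and writes to
#' `out_dir`: `trajectories.csv` (arm, replicate, time, observables),
#' `summary.json` (per-arm endpoint statistics), `config_echo.yaml` (the
#' fully resolved configurations; re-running from the echo reproduces the
#' trajectories), and `log.txt`.
#'
#' @param name preset name
#' @param seed base RNG seed (replicate r of an arm uses seed + r - 1)
#' @param overrides configuration fragment merged into every arm (e.g.
#'   `list(engine = list(n_replicates = 5))` to scale down)
#' @param out_dir output directory (created if needed)
#' @return named list of `trajectory_ensemble`s (or 9-state results),
#'   invisibly
#' @export
run_experiment <- function(name, seed = 1L, overrides = list(),
                           out_dir = tempfile("camkii_run_")) {
  arms <- preset_arms(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  traj <- list()
  summaries <- list()
  log <- c(sprintf("preset: %s", name), sprintf("base seed: %d", seed),
           sprintf("started: %s", format(Sys.time())))
  for (an in names(arms)) {
    cfg <- arms[[an]]
    if (isTRUE(cfg$nine_state)) {
      cfg <- merge_config(cfg, overrides)
      res <- simulate_nine_state(
        n_holo = cfg$n_holo, n_CaM = cfg$n_CaM, n_Ca = cfg$n_Ca,
        n_PP = cfg$n_PP, exclusion = cfg$exclusion, t_end = cfg$t_end,
        chelate_time = cfg$chelate_time, seed = seed)
      results[[an]] <- res
      df <- as.data.frame(res$obs)
      df$replicate <- 1L; df$arm <- an
      traj[[an]] <- df
      summaries[[an]] <- list(final_active = unname(res$obs[nrow(res$obs),
                                                            "active"]),
                              final_pT286 = unname(res$obs[nrow(res$obs),
                                                           "pT286"]))
      log <- c(log, sprintf("arm %s: 9-state, seed %d", an, seed))
      next
    }
    cfg <- merge_config(cfg, overrides)
    cfg$engine$seed <- seed
    cfg <- validate_config(cfg)
    arms[[an]] <- cfg
    ens <- run_config(cfg)
    results[[an]] <- ens
    df <- as.data.frame(ens)
    df$arm <- an
    traj[[an]] <- df
    st <- ensemble_stats(ens, "pT286")
    last <- nrow(st)
    summaries[[an]] <- list(
      endpoint_pT286_mean = st$mean[last],
      endpoint_pT286_sem = st$sem[last],
      endpoint_pT286_fraction = st$mean[last] / ens$n_subunits,
      seeds = ens$seeds)
    log <- c(log, sprintf("arm %s: %d replicates, seeds %s", an,
                          cfg$engine$n_replicates,
                          paste(range(ens$seeds), collapse = "-")))
  }
  utils::write.csv(do.call(rbind, traj), file.path(out_dir,
                                                   "trajectories.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(arms, file.path(out_dir, "config_echo.yaml"))
  log <- c(log, sprintf("finished: %s", format(Sys.time())))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(results)
}

#' Write ensemble mean/SEM tables for the standard observables
#'
#' @param ens a `trajectory_ensemble`
#' @param path CSV output path
#' @return the path, invisibly
#' @export
write_ensemble_csv <- function(ens, path) {
  obs <- c("active", "cam_initial", "cam_full", "pT286", "pp_bound")
  out <- data.frame(time = ens$times)
  for (o in obs) {
    st <- ensemble_stats(ens, o)
    out[[paste0(o, "_mean")]] <- st$mean
    out[[paste0(o, "_sem")]] <- st$sem
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
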