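# 9-state-1-step CaM-CaMKII model: explicit per-lobe Ca2+ binding to CaM,
# one-step CaM binding to CaMKII with state-specific kinetics and CaM
# trapping on pT286 subunits. The docking and activation flags are
# removed; "active" means CaM-bound.

NINE_STATES <- expand.grid(c_lobe = 0:2, n_lobe = 0:2)[, c("n_lobe", "c_lobe")]
nine_state_index <- function(n_lobe, c_lobe) n_lobe * 3L + c_lobe + 1L
nine_state_label <- function(idx) {
  paste0(NINE_STATES$n_lobe[idx], ".", NINE_STATES$c_lobe[idx])
}

#' Load or construct the 9-state CaM rate set
#'
#' Without arguments, reads the rate file shipped with the package
#' (`inst/extdata/ninestate_rates.yaml`), which carries the printed
#' anchor affinities (apo-CaM K_D 1.45 mM, CaM_2C K_D 7.4 uM, 1000-fold
#' CaM trapping) plus synthetic placeholder values for the per-lobe Ca2+
#' kinetics, tagged in the file with their intended literature source.
#'
#' @param path optional path to a YAML rate file with the same schema
#' @return object of class `nine_state_rates`
#' @export
nine_state_rates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ninestate_rates.yaml",
                        package = "camkiisim")
  raw <- yaml::read_yaml(path)
  required <- c("ca_lobe", "camkii_binding", "trapping_factor")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("9-state rate file is missing entries: ",
         paste(missing, collapse = ", "))
  labels <- vapply(1:9, nine_state_label, character(1))
  miss_b <- setdiff(labels, names(raw$camkii_binding))
  if (length(miss_b))
    stop("camkii_binding is missing CaM state(s): ",
         paste(miss_b, collapse = ", "))
  kon <- vapply(labels, function(l) raw$camkii_binding[[l]]$kon, numeric(1))
  koff <- vapply(labels, function(l) raw$camkii_binding[[l]]$koff, numeric(1))
  if (any(!is.finite(kon)) || any(!is.finite(koff)) ||
      any(kon < 0) || any(koff < 0))
    stop("camkii_binding rates must be non-negative numbers")
  structure(list(
    ca_on_N_free = as.numeric(raw$ca_lobe$N$free$kon),
    ca_off_N_free = as.numeric(raw$ca_lobe$N$free$koff),
    ca_on_C_free = as.numeric(raw$ca_lobe$C$free$kon),
    ca_off_C_free = as.numeric(raw$ca_lobe$C$free$koff),
    ca_on_N_bound = as.numeric(raw$ca_lobe$N$bound$kon),
    ca_off_N_bound = as.numeric(raw$ca_lobe$N$bound$koff),
    ca_on_C_bound = as.numeric(raw$ca_lobe$C$bound$kon),
    ca_off_C_bound = as.numeric(raw$ca_lobe$C$bound$koff),
    camkii_kon = unname(kon), camkii_koff = unname(koff),
    trapping_factor = raw$trapping_factor,
    trap_sub_saturated = isTRUE(raw$trap_sub_saturated),
    autophos_rate = if (is.null(raw$autophos_rate)) 1 else raw$autophos_rate
  ), class = "nine_state_rates")
}

#' Effective CaM unbinding rate from a subunit
#'
#' koff of the CaM state divided by the trapping factor when the subunit
#' is pT286 (for sub-saturated states only if `trap_sub_saturated`).
#'
#' @param rates9 a [nine_state_rates()]
#' @param state CaM state index 1-9
#' @param pT286 is the subunit phosphorylated at Thr-286
#' @return rate in s^-1
#' @export
nine_state_koff <- function(rates9, state, pT286 = FALSE) {
  k <- rates9$camkii_koff[state]
  if (pT286 && (rates9$trap_sub_saturated || state == 9L))
    k <- k / rates9$trapping_factor
  k
}

#' Assemble the 9-state-1-step rule system
#'
#' Returns the serializable rule list and the initial state template.
#' Subunit flags reduce to `cam9` (0 = unbound, 1-9 = bound CaM state),
#' `t286` and `t306`; activation is defined as CaM binding, so the
#' 2-state docking/activation rules (and the QSSA reduction) do not
#' apply. Thr-306 is carried but has no transition rule: its 2-state
#' guard (active while CaM-unbound) is unsatisfiable here.
#'
#' @param rates9 a [nine_state_rates()]
#' @param exclusion `"exclusive"` (any bound CaM state blocks PP),
#'   `"cam4_only"` (only fully saturated CaM4 excludes PP) or
#'   `"non_exclusive"`
#' @param pp_rates phosphatase rates shared with the 2-state model (a
#'   [rate_table()])
#' @return list with `rules` (data.frame) and `rates`
#' @export
build_nine_state_model <- function(rates9 = nine_state_rates(),
                                   exclusion = c("exclusive", "cam4_only",
                                                 "non_exclusive"),
                                   pp_rates = rate_table()) {
  stopifnot(inherits(rates9, "nine_state_rates"))
  exclusion <- match.arg(exclusion)
  pp_guard <- switch(exclusion,
    exclusive = "t286 == pT286 & cam9 == unbound",
    cam4_only = "t286 == pT286 & cam9 != CaM4",
    non_exclusive = "t286 == pT286")
  rules <- rbind(
    data.frame(name = "ca_on_lobe", guard = "free or bound CaM, lobe < 2",
               rate = "ca_on (per lobe, per site)",
               effect = "lobe occupancy + 1; free_Ca - 1"),
    data.frame(name = "ca_off_lobe", guard = "free or bound CaM, lobe > 0",
               rate = "ca_off (per lobe, per site)",
               effect = "lobe occupancy - 1; free_Ca + 1"),
    data.frame(name = "cam_bind", guard = "cam9 == unbound & t306 == uT306",
               rate = "camkii_kon[state]",
               effect = "cam9 <- state; free CaM[state] - 1"),
    data.frame(name = "cam_unbind", guard = "cam9 == bound",
               rate = "camkii_koff[state] (/1000 if pT286)",
               effect = "cam9 <- unbound; free CaM[state] + 1"),
    data.frame(name = "autophos",
               guard = "t286 == uT286 & cam9 bound & kinase cam9 bound & !inhibitor",
               rate = "autophos_rate", effect = "t286 <- pT286"),
    data.frame(name = "pp_bind", guard = pp_guard, rate = "k_on_PP",
               effect = "t286 <- PP_bound; free_PP - 1"),
    data.frame(name = "pp_release", guard = "t286 == PP_bound",
               rate = "k_off_PP", effect = "t286 <- pT286; free_PP + 1"),
    data.frame(name = "pp_catalysis", guard = "t286 == PP_bound",
               rate = "k_cat_PP", effect = "t286 <- uT286; free_PP + 1")
  )
  list(rules = rules, rates = rates9, exclusion = exclusion,
       pp_rates = pp_rates)
}

# per-state Ca2+ on/off rates for a CaM molecule (free or bound).
# Returns list of matrices [state, ] -> rates for N-on, N-off, C-on, C-off.
lobe_rate_vectors <- function(rates9, bound, kon_pair_scale) {
  on_N <- if (bound) rates9$ca_on_N_bound else rates9$ca_on_N_free
  off_N <- if (bound) rates9$ca_off_N_bound else rates9$ca_off_N_free
  on_C <- if (bound) rates9$ca_on_C_bound else rates9$ca_on_C_free
  off_C <- if (bound) rates9$ca_off_C_bound else rates9$ca_off_C_free
  n <- NINE_STATES$n_lobe; c <- NINE_STATES$c_lobe
  list(
    n_on  = ifelse(n < 2, on_N[pmin(n + 1L, 2L)] * kon_pair_scale, 0),
    n_off = ifelse(n > 0, off_N[pmax(n, 1L)], 0),
    c_on  = ifelse(c < 2, on_C[pmin(c + 1L, 2L)] * kon_pair_scale, 0),
    c_off = ifelse(c > 0, off_C[pmax(c, 1L)], 0)
  )
}

#' Simulate the 9-state-1-step model (exact SSA)
#'
#' Stimulation follows the published protocol for this variant: a pool of
#' free Ca2+ ions present from t = 0, optionally fully chelated at a
#' given time (`chelate_time`). Written in R; intended for desk-scale
#' systems (tens of CaM, hundreds of Ca2+, a few holoenzymes).
#'
#' @param n_holo,n_CaM,n_Ca,n_PP particle counts
#' @param rates9 a [nine_state_rates()]
#' @param exclusion see [build_nine_state_model()]
#' @param pp_rates a [rate_table()] supplying the PP and autophos rates
#' @param dof autophosphorylation degrees of freedom
#' @param volume compartment volume in liters
#' @param t_end simulated seconds
#' @param record_interval recording interval in seconds
#' @param chelate_time time of full Ca2+ chelation (NULL = never)
#' @param seed RNG seed
#' @param max_events safety cap on the number of SSA events
#' @return list with `times`, `obs` (matrix of counts: CaM-bound/active
#'   subunits, pT286, PP-bound, free Ca, total Ca, per-state bound
#'   counts), `final` (subunit state list)
#' @export
simulate_nine_state <- function(n_holo = 1L, n_CaM = 30L, n_Ca = 120L,
                                n_PP = 2L, rates9 = nine_state_rates(),
                                exclusion = "exclusive",
                                pp_rates = rate_table(), dof = 1L,
                                volume = DEFAULT_VOLUME,
                                t_end = 5, record_interval = 0.05,
                                chelate_time = NULL, seed = 1L,
                                max_events = 5e6) {
  set.seed(seed)
  exclusion <- match.arg(exclusion, c("exclusive", "cam4_only",
                                      "non_exclusive"))
  sys <- build_holoenzyme(n_holo, dof = dof)
  n_sub <- nrow(sys$flags)
  kin <- kinase_index_matrix(sys) + 1L  # 1-based, 0 = absent

  # state
  free_cam <- integer(9); free_cam[1] <- n_CaM  # all apo at t = 0
  free_ca <- as.integer(n_Ca)
  free_pp <- as.integer(n_PP)
  cam9 <- integer(n_sub)   # 0 unbound, 1..9 bound state
  t286 <- integer(n_sub)   # 0/1/2
  t306 <- integer(n_sub)

  pair <- function(k) bimolecular_propensity(k, volume)
  lob_free <- lobe_rate_vectors(rates9, bound = FALSE, kon_pair_scale = pair(1))
  lob_bound <- lobe_rate_vectors(rates9, bound = TRUE, kon_pair_scale = pair(1))
  kon9_pair <- pair(rates9$camkii_kon)
  konpp_pair <- pair(pp_rates$k_on_PP * pp_rates$kon_PP_scale)
  k_cat <- pp_rates$k_cat_PP

  koff_sub <- function(i) nine_state_koff(rates9, cam9[i], t286[i] == 1L)
  pp_excluded <- function(i) {
    switch(exclusion,
           exclusive = cam9[i] != 0L,
           cam4_only = cam9[i] == 9L,
           non_exclusive = FALSE)
  }

  n_frames <- floor(t_end / record_interval + 1e-9) + 1
  obs <- matrix(0, nrow = n_frames, ncol = 7 + 9,
                dimnames = list(NULL, c("time", "active", "pT286", "pp_bound",
                                        "free_Ca", "total_Ca", "free_PP",
                                        paste0("bound_", vapply(1:9,
                                          nine_state_label, character(1))))))
  frame <- 1L
  total_ca <- function() {
    free_ca + sum(free_cam * (NINE_STATES$n_lobe + NINE_STATES$c_lobe)) +
      sum(ifelse(cam9 > 0,
                 NINE_STATES$n_lobe[pmax(cam9, 1)] +
                   NINE_STATES$c_lobe[pmax(cam9, 1)], 0))
  }
  record <- function(at) {
    bound_counts <- tabulate(cam9[cam9 > 0], nbins = 9)
    obs[frame, ] <<- c(at, sum(cam9 > 0), sum(t286 == 1L), sum(t286 == 2L),
                       free_ca, total_ca(), free_pp, bound_counts)
    frame <<- frame + 1L
  }

  t <- 0; next_record <- 0
  chel <- if (is.null(chelate_time)) Inf else chelate_time
  chel_done <- FALSE
  ev <- 0L
  repeat {
    # ---- propensities -------------------------------------------------
    # free CaM lobe transitions (aggregated over molecules per state)
    a_free_non <- lob_free$n_on * free_cam * free_ca
    a_free_noff <- lob_free$n_off * free_cam
    a_free_con <- lob_free$c_on * free_cam * free_ca
    a_free_coff <- lob_free$c_off * free_cam
    # bound CaM lobe transitions (per subunit)
    bnd <- which(cam9 > 0L)
    a_b_non <- if (length(bnd)) lob_bound$n_on[cam9[bnd]] * free_ca else numeric(0)
    a_b_noff <- if (length(bnd)) lob_bound$n_off[cam9[bnd]] else numeric(0)
    a_b_con <- if (length(bnd)) lob_bound$c_on[cam9[bnd]] * free_ca else numeric(0)
    a_b_coff <- if (length(bnd)) lob_bound$c_off[cam9[bnd]] else numeric(0)
    # CaM-CaMKII binding (per state, uniform over eligible subunits)
    elig <- which(cam9 == 0L & t306 == 0L)
    a_bind <- kon9_pair * free_cam * length(elig)
    # unbinding per bound subunit
    a_unbind <- if (length(bnd)) vapply(bnd, koff_sub, numeric(1)) else numeric(0)
    # autophosphorylation per eligible edge
    sub_ok <- t286 == 0L & cam9 > 0L
    edge_sub <- integer(0)
    if (any(sub_ok)) {
      for (e in 1:3) {
        k <- kin[, e]
        ok <- sub_ok & k > 0L
        ok[ok] <- cam9[k[ok]] > 0L
        edge_sub <- c(edge_sub, which(ok))
      }
    }
    a_auto <- rates9$autophos_rate * length(edge_sub)
    # PP
    pp_targets <- which(t286 == 1L & !vapply(seq_len(n_sub), pp_excluded,
                                             logical(1)))
    a_ppbind <- konpp_pair * free_pp * length(pp_targets)
    ppb <- which(t286 == 2L)
    a_ppoff <- pp_rates$k_off_PP * length(ppb)
    a_ppcat <- k_cat * length(ppb)

    tot <- sum(a_free_non, a_free_noff, a_free_con, a_free_coff,
               a_b_non, a_b_noff, a_b_con, a_b_coff,
               a_bind, a_unbind, a_auto, a_ppbind, a_ppoff, a_ppcat)

    t_next <- if (tot > 0) t + stats::rexp(1, tot) else Inf
    barrier <- min(if (!chel_done) chel else Inf, t_end)
    if (t_next >= barrier) {
      while (next_record <= barrier + 1e-9 && frame <= n_frames) {
        record(next_record); next_record <- next_record + record_interval
      }
      t <- barrier
      if (!chel_done && barrier == chel) { free_ca <- 0L; chel_done <- TRUE; next }
      break
    }
    while (next_record <= t_next + 1e-9 && frame <= n_frames) {
      record(next_record); next_record <- next_record + record_interval
    }
    t <- t_next
    ev <- ev + 1L
    if (ev > max_events) stop("9-state SSA exceeded max_events (", max_events,
                              "); reduce system size or duration")

    # ---- select and apply --------------------------------------------
    r <- stats::runif(1) * tot
    pick <- function(v) { # returns index into v if r falls in it, else NA
      s <- sum(v)
      if (r <= s && s > 0) {
        i <- which(r <= cumsum(v))[1]
        r <<- -1  # consumed
        i
      } else { r <<- r - s; NA_integer_ }
    }
    i <- pick(a_free_non)
    if (!is.na(i)) {
      free_cam[i] <- free_cam[i] - 1L
      j <- nine_state_index(NINE_STATES$n_lobe[i] + 1L, NINE_STATES$c_lobe[i])
      free_cam[j] <- free_cam[j] + 1L; free_ca <- free_ca - 1L; next
    }
    i <- pick(a_free_noff)
    if (!is.na(i)) {
      free_cam[i] <- free_cam[i] - 1L
      j <- nine_state_index(NINE_STATES$n_lobe[i] - 1L, NINE_STATES$c_lobe[i])
      free_cam[j] <- free_cam[j] + 1L; free_ca <- free_ca + 1L; next
    }
    i <- pick(a_free_con)
    if (!is.na(i)) {
      free_cam[i] <- free_cam[i] - 1L
      j <- nine_state_index(NINE_STATES$n_lobe[i], NINE_STATES$c_lobe[i] + 1L)
      free_cam[j] <- free_cam[j] + 1L; free_ca <- free_ca - 1L; next
    }
    i <- pick(a_free_coff)
    if (!is.na(i)) {
      free_cam[i] <- free_cam[i] - 1L
      j <- nine_state_index(NINE_STATES$n_lobe[i], NINE_STATES$c_lobe[i] - 1L)
      free_cam[j] <- free_cam[j] + 1L; free_ca <- free_ca + 1L; next
    }
    i <- pick(a_b_non)
    if (!is.na(i)) {
      s <- bnd[i]
      cam9[s] <- nine_state_index(NINE_STATES$n_lobe[cam9[s]] + 1L,
                                  NINE_STATES$c_lobe[cam9[s]])
      free_ca <- free_ca - 1L; next
    }
    i <- pick(a_b_noff)
    if (!is.na(i)) {
      s <- bnd[i]
      cam9[s] <- nine_state_index(NINE_STATES$n_lobe[cam9[s]] - 1L,
                                  NINE_STATES$c_lobe[cam9[s]])
      free_ca <- free_ca + 1L; next
    }
    i <- pick(a_b_con)
    if (!is.na(i)) {
      s <- bnd[i]
      cam9[s] <- nine_state_index(NINE_STATES$n_lobe[cam9[s]],
                                  NINE_STATES$c_lobe[cam9[s]] + 1L)
      free_ca <- free_ca - 1L; next
    }
    i <- pick(a_b_coff)
    if (!is.na(i)) {
      s <- bnd[i]
      cam9[s] <- nine_state_index(NINE_STATES$n_lobe[cam9[s]],
                                  NINE_STATES$c_lobe[cam9[s]] - 1L)
      free_ca <- free_ca + 1L; next
    }
    i <- pick(a_bind)
    if (!is.na(i)) {
      s <- elig[sample.int(length(elig), 1L)]
      cam9[s] <- i; free_cam[i] <- free_cam[i] - 1L; next
    }
    i <- pick(a_unbind)
    if (!is.na(i)) {
      s <- bnd[i]
      free_cam[cam9[s]] <- free_cam[cam9[s]] + 1L; cam9[s] <- 0L; next
    }
    if (r <= a_auto && a_auto > 0) {
      s <- edge_sub[sample.int(length(edge_sub), 1L)]
      t286[s] <- 1L; next
    }
    r <- r - a_auto
    if (r <= a_ppbind && a_ppbind > 0) {
      s <- pp_targets[sample.int(length(pp_targets), 1L)]
      t286[s] <- 2L; free_pp <- free_pp - 1L; next
    }
    r <- r - a_ppbind
    if (r <= a_ppoff && a_ppoff > 0) {
      s <- ppb[sample.int(length(ppb), 1L)]
      t286[s] <- 1L; free_pp <- free_pp + 1L; next
    }
    # catalysis (remaining mass)
    if (length(ppb)) {
      s <- ppb[sample.int(length(ppb), 1L)]
      t286[s] <- 0L; free_pp <- free_pp + 1L
    }
  }
  while (frame <= n_frames) {
    record(next_record); next_record <- next_record + record_interval
  }
  list(times = obs[, "time"], obs = obs,
       final = list(cam9 = cam9, t286 = t286, t306 = t306,
                    free_cam = free_cam, free_ca = free_ca, free_pp = free_pp))
}

#' Simulated CaM dwell times on a subunit
#'
#' Draws unbinding waiting times from the model's CaM-release channel for
#' a subunit of given phosphorylation status (used for the trapping
#' order-of-magnitude check: pT286 dwell ~1000x the uT286 dwell).
#'
#' @param rates9 a [nine_state_rates()]
#' @param state bound CaM state index 1-9
#' @param pT286 phosphorylation status
#' @param n number of draws
#' @return numeric vector of dwell times in seconds
#' @export
sample_cam_dwell <- function(rates9, state = 9L, pT286 = FALSE, n = 1000L) {
  stats::rexp(n, rate = nine_state_koff(rates9, state, pT286))
}
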