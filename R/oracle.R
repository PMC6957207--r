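# Independent verification route: closed-form parameter derivations and
# exact chemical-master-equation solutions for small instances. The CME
# is built from the R rule table (guards + effects), entirely apart from
# the C++ engine it validates.

#' Derived kinetic constants from their source measurements
#'
#' Recomputes every derived parameter of the model from the primary
#' measured quantities, independently of [rate_table()]:
#' the docking equilibrium constant (ratio of the CaM on-rate to peptide
#' and to full-length CaMKII), the undocking rate, the initial-CaM
#' dissociation rate (K_D x k_on), the initially-bound vs fully-bound
#' occupancy ratio, the phosphatase Michaelis constant, and the
#' activation probability.
#'
#' @return named list: `K_docking` (0.018), `k_undock` (0.63 s^-1),
#'   `k_off_CaM_ini` (590 s^-1), `initial_full_occupancy_ratio`
#'   (~1.1e-5), `K_M_PP` (8.3e-7 M), `p_act` (~0.002)
#' @export
derive_parameters <- function() {
  K_docking <- 1.8e6 / 1e8           # kon full-length / kon peptide
  list(
    K_docking = K_docking,
    k_undock = 35 * K_docking,
    k_off_CaM_ini = 5.9e-6 * 1e8,    # K_D (low-affinity peptide) x kon
    initial_full_occupancy_ratio = 4e-3 / 350,
    K_M_PP = (0.5 + 2) / 3e6,
    p_act = 2e4 / (2e4 + 1e7)
  )
}

state_key <- function(flags, pl) {
  paste(c(t(flags), pl), collapse = ",")
}

#' Enumerate the exact CME of a small rule system
#'
#' Breadth-first enumeration of all states reachable from the initial
#' state of `sys` under the rule table, with the free pools part of the
#' global state (the oracle is exact, not mean-field). Bimolecular rules
#' use per-pair propensities times the current pool count.
#'
#' @param sys a [build_holoenzyme()] system, or any `camkii_system` with
#'   1-3 subunits (use [chain_system()] for the 2-subunit
#'   autophosphorylation fragment)
#' @param p initial pools ([pools()]); only `free_CaM4` and `free_PP`
#'   participate (the oracle assumes a constant activating phase)
#' @param rules a [rule_table()]
#' @param max_states enumeration cap (default 1e6)
#' @return object of class `cme_system`: states, sparse generator `Q`
#'   (rows sum to zero, `Q[i, j]` = rate i -> j), the initial index, and
#'   bookkeeping
#' @export
enumerate_cme <- function(sys, p, rules, max_states = 1e6) {
  stopifnot(inherits(sys, "camkii_system"), inherits(p, "camkii_pools"),
            inherits(rules, "camkii_rules"))
  n_sub <- nrow(sys$flags)
  if (n_sub < 1) stop("CME enumeration requires at least 1 subunit")
  if (n_sub > 3) stop("CME oracle supports at most 3 subunits")
  km <- sys$kinase_map

  pair_rate <- function(rule) {
    if (rule$participants == "bimolecular_subunit_pool")
      bimolecular_propensity(rule$rate, p$volume)
    else rule$rate
  }
  rates_pp <- vapply(rules, pair_rate, numeric(1))

  # transitions from one global state: list of (key, new_state, rate)
  transitions <- function(st) {
    out <- list()
    add <- function(flags, pl, rate) {
      if (rate <= 0) return(invisible(NULL))  # zero-rate rules open no states
      out[[length(out) + 1L]] <<- list(flags = flags, pools = pl, rate = rate)
    }
    for (ri in seq_along(rules)) {
      rule <- rules[[ri]]
      base_rate <- rates_pp[ri]
      if (rule$participants == "neighbor_gated") {
        if (is.null(km) || !nrow(km)) next
        for (e in seq_len(nrow(km))) {
          s_i <- km$substrate[e]; k_i <- km$kinase[e]
          sub <- st$flags[s_i, ]; nb <- st$flags[k_i, ]
          if (isTRUE(rule$guard(sub, nb))) {
            res <- rule$effect(sub, st$pools)
            fl <- st$flags; fl[s_i, ] <- res$s
            add(fl, res$pools, base_rate)
          }
        }
      } else {
        mult <- 1
        if (rule$participants == "bimolecular_subunit_pool") {
          cnt <- st$pools[[rule$pool]]
          if (cnt <= 0) next
          mult <- cnt
        }
        for (i in seq_len(n_sub)) {
          sub <- st$flags[i, ]
          if (isTRUE(rule$guard(sub, NULL))) {
            res <- rule$effect(sub, st$pools)
            fl <- st$flags; fl[i, ] <- res$s
            add(fl, res$pools, base_rate * mult)
          }
        }
      }
    }
    out
  }

  pools0 <- list(free_CaM4 = p$free_CaM4, free_PP = p$free_PP)
  init <- list(flags = sys$flags, pools = pools0)
  index <- new.env(hash = TRUE, parent = emptyenv())
  states <- list(init)
  assign(state_key(init$flags, unlist(init$pools)), 1L, envir = index)
  queue <- 1L
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)

  while (length(queue)) {
    si <- queue[1]; queue <- queue[-1]
    st <- states[[si]]
    for (tr in transitions(st)) {
      key <- state_key(tr$flags, unlist(tr$pools))
      j <- index[[key]]
      if (is.null(j)) {
        states[[length(states) + 1L]] <- list(flags = tr$flags,
                                              pools = tr$pools)
        j <- length(states)
        if (j > max_states)
          stop("CME state count exceeds cap (", max_states, " states)")
        assign(key, j, envir = index)
        queue <- c(queue, j)
      }
      trip_i <- c(trip_i, si); trip_j <- c(trip_j, j); trip_x <- c(trip_x, tr$rate)
    }
  }

  n <- length(states)
  Q <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  structure(list(states = states, Q = Q, n = n, initial = 1L,
                 n_subunits = n_sub),
            class = "cme_system")
}

#' Solve a CME system
#'
#' Transient: stiff integration of the forward equation
#' `dp/dt = Q^T p` from the initial distribution (deSolve, `lsoda`, with
#' the analytic Jacobian). Stationary: direct solve of `Q^T p = 0` with
#' the normalisation constraint.
#'
#' @param system a [enumerate_cme()] result
#' @param t time in seconds (ignored for `stationary = TRUE`)
#' @param stationary solve for the stationary distribution instead
#' @param atol,rtol integrator tolerances
#' @return numeric vector of state probabilities (sums to 1)
#' @export
solve_cme <- function(system, t, stationary = FALSE,
                      atol = 1e-12, rtol = 1e-8) {
  stopifnot(inherits(system, "cme_system"))
  n <- system$n
  QT <- Matrix::t(system$Q)
  if (stationary) {
    A <- as.matrix(QT)
    A[1, ] <- 1
    b <- c(1, rep(0, n - 1))
    pr <- solve(A, b)
    pr[pr < 0 & pr > -1e-12] <- 0
    return(pr / sum(pr))
  }
  if (t < 0) stop("t must be >= 0")
  p0 <- numeric(n); p0[system$initial] <- 1
  if (t == 0) return(p0)
  QTd <- as.matrix(QT)
  deriv <- function(tt, y, parms) list(as.vector(QTd %*% y))
  jac <- function(tt, y, parms) QTd
  sol <- deSolve::lsoda(y = p0, times = c(0, t), func = deriv,
                        jacfunc = jac, jactype = "fullusr",
                        atol = atol, rtol = rtol, parms = NULL)
  if (attr(sol, "istate")[1] < 0)
    stop("CME integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  pr <- sol[2, -1]
  tot <- sum(pr)
  if (abs(tot - 1) > 1e-6)
    stop("CME normalisation drifted: sum(p) = ", format(tot))
  unname(pr / tot)
}

#' Marginal flag probabilities of a CME distribution
#'
#' @param system a `cme_system`
#' @param pr probability vector from [solve_cme()]
#' @param subunit which subunit (default 1)
#' @return named list of marginal distributions per flag
#' @export
cme_marginals <- function(system, pr, subunit = 1L) {
  flags <- c("docking", "conformation", "cam", "t286", "t306")
  vals <- list(docking = 0:1, conformation = 0:1, cam = 0:2, t286 = 0:2,
               t306 = 0:1)
  out <- list()
  for (f in flags) {
    codes <- vapply(system$states, function(st) st$flags[subunit, f],
                    integer(1))
    out[[f]] <- vapply(vals[[f]], function(v) sum(pr[codes == v]), numeric(1))
    names(out[[f]]) <- FLAG_LEVELS[[f]][vals[[f]] + 1L]
  }
  out
}

#' Two-subunit open-chain system for oracle checks
#'
#' Subunit 2 is the (only) kinase of subunit 1 — the minimal fragment
#' exercising the neighbor-gated autophosphorylation rule.
#'
#' @return a `camkii_system` with 2 subunits and one kinase edge
#' @export
chain_system <- function() {
  sys <- build_holoenzyme(1)
  sys$flags <- sys$flags[1:2, , drop = FALSE]
  sys$holo <- c(1L, 1L); sys$ring <- c(1L, 1L); sys$pos <- c(0L, 1L)
  sys$kinase_map <- data.frame(substrate = 1L, kinase = 2L,
                               trans_ring = FALSE)
  sys
}
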