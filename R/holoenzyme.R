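# Holoenzyme topology, subunit states, and the state-space census.

# Integer encodings shared with the C++ engine:
#   docking      0 = docked,   1 = undocked
#   conformation 0 = inactive, 1 = active
#   cam          0 = unbound,  1 = initial, 2 = full
#   t286         0 = uT286,    1 = pT286,   2 = PP_bound
#   t306         0 = uT306,    1 = pT306
#   inhibitor    0 = free,     1 = K252a-bound
FLAG_LEVELS <- list(
  docking      = c("docked", "undocked"),
  conformation = c("inactive", "active"),
  cam          = c("unbound", "initial", "full"),
  t286         = c("uT286", "pT286", "PP_bound"),
  t306         = c("uT306", "pT306"),
  inhibitor    = c("FALSE", "TRUE")
)

#' Construct a single CaMKII subunit state
#'
#' @param docking `"docked"` or `"undocked"`
#' @param conformation `"inactive"` or `"active"`
#' @param cam CaM-binding flag: `"unbound"`, `"initial"` or `"full"`
#' @param t286 `"uT286"`, `"pT286"` or `"PP_bound"`
#' @param t306 `"uT306"` or `"pT306"`
#' @param inhibitor_bound logical, K252a overlay
#' @param check validate the state invariants (default `TRUE`)
#' @return named integer vector of length 6 (class `camkii_subunit`)
#' @export
subunit_state <- function(docking = "docked", conformation = "inactive",
                          cam = "unbound", t286 = "uT286", t306 = "uT306",
                          inhibitor_bound = FALSE, check = TRUE) {
  code <- function(flag, value) {
    i <- match(value, FLAG_LEVELS[[flag]])
    if (is.na(i)) stop("invalid ", flag, " value: ", value)
    i - 1L
  }
  s <- c(docking = code("docking", docking),
         conformation = code("conformation", conformation),
         cam = code("cam", cam),
         t286 = code("t286", t286),
         t306 = code("t306", t306),
         inhibitor = as.integer(isTRUE(inhibitor_bound)))
  class(s) <- "camkii_subunit"
  if (check) validate_subunit(s)
  s
}

#' Check the subunit state invariants
#'
#' Invariants: a docked subunit is CaM-unbound; a pT306 subunit is
#' CaM-unbound; a fully CaM-bound subunit is active; under the exclusive
#' variant a PP-bound subunit is CaM-unbound.
#'
#' @param s a subunit state (named integer vector)
#' @param exclusivity `"exclusive"` or `"non_exclusive"`; governs the
#'   fourth invariant
#' @return `TRUE` invisibly, or an error describing the violated invariant
#' @export
validate_subunit <- function(s, exclusivity = "exclusive") {
  if (s[["docking"]] == 0L && s[["cam"]] != 0L)
    stop("invariant violated: docked subunit must be CaM-unbound")
  if (s[["t306"]] == 1L && s[["cam"]] != 0L)
    stop("invariant violated: pT306 subunit must be CaM-unbound")
  if (s[["cam"]] == 2L && s[["conformation"]] != 1L)
    stop("invariant violated: fully CaM-bound subunit must be active")
  if (identical(exclusivity, "exclusive") && s[["t286"]] == 2L && s[["cam"]] != 0L)
    stop("invariant violated: PP-bound subunit must be CaM-unbound (exclusive model)")
  invisible(TRUE)
}

#' Directed kinase -> substrate adjacency of the holoenzyme
#'
#' Positions 0-5 are ordered counter-clockwise within each hexamer ring.
#' The kinase of substrate position i is (i+1) mod 6 in the same ring for
#' DOF 1; DOF 2 adds (i-1) mod 6; DOF 3 adds the directly apposed subunit
#' (same position index, other ring), in both directions.
#'
#' @param dof degrees of freedom (1, 2 or 3)
#' @param n_holo number of holoenzymes (edges replicated per holoenzyme)
#' @return data.frame with columns `substrate`, `kinase` (1-based global
#'   subunit indices) and `trans_ring` (logical)
#' @export
kinase_map <- function(dof = 1L, n_holo = 1L) {
  if (!dof %in% 1:3) stop("dof must be 1, 2 or 3")
  edges <- NULL
  for (ring in 0:1) {
    base <- ring * 6L
    i <- 0:5
    edges <- rbind(edges,
                   data.frame(substrate = base + i, kinase = base + (i + 1L) %% 6L,
                              trans_ring = FALSE))
    if (dof >= 2)
      edges <- rbind(edges,
                     data.frame(substrate = base + i, kinase = base + (i - 1L) %% 6L,
                                trans_ring = FALSE))
  }
  if (dof >= 3) {
    i <- 0:5
    edges <- rbind(edges,
                   data.frame(substrate = i, kinase = i + 6L, trans_ring = TRUE),
                   data.frame(substrate = i + 6L, kinase = i, trans_ring = TRUE))
  }
  out <- NULL
  for (h in seq_len(n_holo) - 1L) {
    e <- edges
    e$substrate <- e$substrate + h * 12L + 1L
    e$kinase <- e$kinase + h * 12L + 1L
    out <- rbind(out, e)
  }
  rownames(out) <- NULL
  out
}

#' Build a collection of CaMKII holoenzymes in the initial state
#'
#' All subunits start docked, inactive, CaM-unbound, uT286, uT306 and
#' inhibitor-free.
#'
#' @param n_holo number of holoenzymes (>= 1)
#' @param dof autophosphorylation degrees of freedom (1, 2 or 3)
#' @return object of class `camkii_system`: a list with the subunit flag
#'   matrix (`flags`, one row per subunit), holoenzyme/ring/position
#'   indices, and the directed `kinase_map`
#' @examples
#' sys <- build_holoenzyme(30, dof = 1)
#' nrow(sys$flags)          # 360 subunits
#' nrow(sys$kinase_map)     # 360 directed kinase edges (12 per holoenzyme)
#' @export
build_holoenzyme <- function(n_holo, dof = 1L) {
  if (!is.numeric(n_holo) || length(n_holo) != 1 || n_holo < 1 ||
      n_holo != round(n_holo))
    stop("n_holo must be a positive integer")
  if (!dof %in% 1:3) stop("invalid dof: must be 1, 2 or 3")
  n_holo <- as.integer(n_holo)
  n <- n_holo * 12L
  flags <- matrix(0L, nrow = n, ncol = 6,
                  dimnames = list(NULL, c("docking", "conformation", "cam",
                                          "t286", "t306", "inhibitor")))
  sys <- list(
    n_holo = n_holo,
    dof = as.integer(dof),
    flags = flags,
    holo = rep(seq_len(n_holo), each = 12L),
    ring = rep(rep(1:2, each = 6L), times = n_holo),
    pos  = rep(rep(0:5, times = 2L), times = n_holo),
    kinase_map = kinase_map(dof, n_holo)
  )
  class(sys) <- "camkii_system"
  sys
}

#' Rebuild the kinase adjacency of a system for a new DOF setting
#'
#' @param sys a `camkii_system`
#' @param dof 1, 2 or 3
#' @return the system with `dof` and `kinase_map` replaced
#' @export
set_dof <- function(sys, dof) {
  stopifnot(inherits(sys, "camkii_system"))
  if (!dof %in% 1:3) stop("invalid dof: must be 1, 2 or 3")
  sys$dof <- as.integer(dof)
  sys$kinase_map <- kinase_map(dof, sys$n_holo)
  sys
}

#' Enumerate all subunit flag combinations
#'
#' @param constrained if `TRUE`, keep only combinations satisfying the
#'   structural invariants (docked => CaM-unbound, pT306 => CaM-unbound,
#'   fully bound => active); the K252a overlay is not included.
#' @return data.frame of flag codes, one row per state
#' @export
enumerate_subunit_states <- function(constrained = FALSE) {
  g <- expand.grid(docking = 0:1, conformation = 0:1, cam = 0:2,
                   t286 = 0:2, t306 = 0:1)
  if (constrained) {
    keep <- !(g$docking == 0L & g$cam != 0L) &
            !(g$t306 == 1L & g$cam != 0L) &
            !(g$cam == 2L & g$conformation != 1L)
    g <- g[keep, , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

#' Size of the per-subunit state space
#'
#' Unconstrained: the product of the flag cardinalities (2 x 2 x 3 x 3 x 2
#' = 72). Constrained: exhaustive enumeration filtered by the structural
#' invariants (33 states).
#'
#' @param constrained apply the state invariants
#' @return integer count
#' @export
per_subunit_state_count <- function(constrained = FALSE) {
  nrow(enumerate_subunit_states(constrained))
}

#' @export
print.camkii_system <- function(x, ...) {
  cat("CaMKII system:", x$n_holo, "holoenzyme(s),", nrow(x$flags),
      "subunits, DOF", x$dof, "(", nrow(x$kinase_map), "kinase edges )\n")
  invisible(x)
}
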