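# The rule table: guarded state transitions of the 2-state-2-step model.
#
# Each rule is a pure predicate over one subunit's flags (plus, for the
# autophosphorylation rule, the kinase neighbor's flags) together with an
# effect on the subunit and the free pools. The same table drives the CME
# oracle; the C++ engine implements the identical semantics and is
# validated against the oracle in the test suite.

new_rule <- function(name, participants, rate_name, rate, guard_desc, guard,
                     effect_desc, effect, pool = NA_character_,
                     neighbor_guard_desc = character()) {
  structure(list(name = name, participants = participants,
                 rate_name = rate_name, rate = rate,
                 guard_desc = guard_desc, guard = guard,
                 effect_desc = effect_desc, effect = effect,
                 pool = pool, neighbor_guard_desc = neighbor_guard_desc),
            class = "camkii_rule")
}

#' Build the rule table for a rate table
#'
#' Emits the complete set of guarded transitions: docking/undocking, the
#' conformational flicker, two-step CaM binding, neighbor-gated
#' autophosphorylation at Thr-286, phosphatase binding/release/catalysis,
#' and Thr-306 phosphorylation (irreversible). The `exclusivity` switch in
#' `rates` adds or removes exactly two guard clauses: bound CaM blocking PP
#' binding, and bound PP blocking CaM binding.
#'
#' @param rates a [rate_table()]
#' @return object of class `camkii_rules`: list of rules with the rate
#'   table attached as attribute `rates`
#' @export
rule_table <- function(rates = rate_table()) {
  stopifnot(inherits(rates, "camkii_rates"))
  exclusive <- identical(rates$exclusivity, "exclusive")

  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r

  add(new_rule("undock", "unimolecular_subunit", "k_undock", rates$k_undock,
    "docking == docked",
    function(s, n = NULL) s[["docking"]] == 0L,
    "docking <- undocked",
    function(s, pools) { s[["docking"]] <- 1L; list(s = s, pools = pools) }))

  dock_guard <- c("docking == undocked", "cam == unbound", "t306 == uT306")
  if (rates$dock_requires_inactive)
    dock_guard <- c(dock_guard, "conformation == inactive")
  add(new_rule("dock", "unimolecular_subunit", "k_dock", rates$k_dock,
    dock_guard,
    function(s, n = NULL) {
      ok <- s[["docking"]] == 1L && s[["cam"]] == 0L && s[["t306"]] == 0L
      if (rates$dock_requires_inactive) ok <- ok && s[["conformation"]] == 0L
      ok
    },
    "docking <- docked",
    function(s, pools) { s[["docking"]] <- 0L; list(s = s, pools = pools) }))

  add(new_rule("activate", "unimolecular_subunit", "k_activate", rates$k_activate,
    "conformation == inactive",
    function(s, n = NULL) s[["conformation"]] == 0L,
    "conformation <- active",
    function(s, pools) { s[["conformation"]] <- 1L; list(s = s, pools = pools) }))

  inact_guard <- c("conformation == active", "cam != full", "t286 != pT286")
  if (rates$pp_bound_counts_as_phospho)
    inact_guard <- c(inact_guard, "t286 != PP_bound")
  add(new_rule("inactivate", "unimolecular_subunit", "k_inactivate",
    rates$k_inactivate,
    inact_guard,
    function(s, n = NULL) {
      ok <- s[["conformation"]] == 1L && s[["cam"]] != 2L && s[["t286"]] != 1L
      if (rates$pp_bound_counts_as_phospho) ok <- ok && s[["t286"]] != 2L
      ok
    },
    "conformation <- inactive",
    function(s, pools) { s[["conformation"]] <- 0L; list(s = s, pools = pools) }))

  cam_guard <- c("cam == unbound", "docking == undocked", "t306 == uT306")
  if (exclusive) cam_guard <- c(cam_guard, "t286 != PP_bound")
  add(new_rule("cam_bind", "bimolecular_subunit_pool", "k_on_CaM", rates$k_on_CaM,
    cam_guard,
    function(s, n = NULL) {
      ok <- s[["cam"]] == 0L && s[["docking"]] == 1L && s[["t306"]] == 0L
      if (exclusive) ok <- ok && s[["t286"]] != 2L
      ok
    },
    "cam <- initial; free_CaM4 - 1",
    function(s, pools) {
      s[["cam"]] <- 1L
      pools[["free_CaM4"]] <- pools[["free_CaM4"]] - 1L
      list(s = s, pools = pools)
    },
    pool = "free_CaM4"))

  add(new_rule("cam_release", "unimolecular_subunit", "k_off_CaM_ini",
    rates$k_off_CaM_ini,
    "cam == initial",
    function(s, n = NULL) s[["cam"]] == 1L,
    "cam <- unbound; free_CaM4 + 1",
    function(s, pools) {
      s[["cam"]] <- 0L
      pools[["free_CaM4"]] <- pools[["free_CaM4"]] + 1L
      list(s = s, pools = pools)
    }))

  add(new_rule("cam_full", "unimolecular_subunit", "k_ini_to_full",
    rates$k_ini_to_full,
    c("cam == initial", "conformation == active"),
    function(s, n = NULL) s[["cam"]] == 1L && s[["conformation"]] == 1L,
    "cam <- full",
    function(s, pools) { s[["cam"]] <- 2L; list(s = s, pools = pools) }))

  add(new_rule("cam_decompact", "unimolecular_subunit", "k_full_to_ini",
    rates$k_full_to_ini,
    "cam == full",
    function(s, n = NULL) s[["cam"]] == 2L,
    "cam <- initial",
    function(s, pools) { s[["cam"]] <- 1L; list(s = s, pools = pools) }))

  kin_guard <- c("kinase conformation == active", "kinase docking == undocked")
  if (rates$k252a_blocks_kinase_role)
    kin_guard <- c(kin_guard, "kinase inhibitor_bound == FALSE")
  add(new_rule("autophos", "neighbor_gated", "k_autophos", rates$k_autophos,
    c("t286 == uT286", "docking == undocked", "conformation == active",
      "inhibitor_bound == FALSE"),
    function(s, n) {
      if (is.null(n)) stop("neighbor_gated rule requires a neighbor state")
      ok <- s[["t286"]] == 0L && s[["docking"]] == 1L &&
        s[["conformation"]] == 1L && s[["inhibitor"]] == 0L &&
        n[["conformation"]] == 1L && n[["docking"]] == 1L
      if (rates$k252a_blocks_kinase_role) ok <- ok && n[["inhibitor"]] == 0L
      ok
    },
    "t286 <- pT286",
    function(s, pools) { s[["t286"]] <- 1L; list(s = s, pools = pools) },
    neighbor_guard_desc = kin_guard))

  pp_guard <- "t286 == pT286"
  if (exclusive) pp_guard <- c(pp_guard, "cam == unbound")
  add(new_rule("pp_bind", "bimolecular_subunit_pool", "k_on_PP",
    rates$k_on_PP * rates$kon_PP_scale,
    pp_guard,
    function(s, n = NULL) {
      ok <- s[["t286"]] == 1L
      if (exclusive) ok <- ok && s[["cam"]] == 0L
      ok
    },
    "t286 <- PP_bound; free_PP - 1",
    function(s, pools) {
      s[["t286"]] <- 2L
      pools[["free_PP"]] <- pools[["free_PP"]] - 1L
      list(s = s, pools = pools)
    },
    pool = "free_PP"))

  add(new_rule("pp_release", "unimolecular_subunit", "k_off_PP", rates$k_off_PP,
    "t286 == PP_bound",
    function(s, n = NULL) s[["t286"]] == 2L,
    "t286 <- pT286; free_PP + 1",
    function(s, pools) {
      s[["t286"]] <- 1L
      pools[["free_PP"]] <- pools[["free_PP"]] + 1L
      list(s = s, pools = pools)
    }))

  add(new_rule("pp_catalysis", "unimolecular_subunit", "k_cat_PP", rates$k_cat_PP,
    "t286 == PP_bound",
    function(s, n = NULL) s[["t286"]] == 2L,
    "t286 <- uT286; free_PP + 1",
    function(s, pools) {
      s[["t286"]] <- 0L
      pools[["free_PP"]] <- pools[["free_PP"]] + 1L
      list(s = s, pools = pools)
    }))

  add(new_rule("t306_phos", "unimolecular_subunit", "k_phos_T306",
    rates$k_phos_T306,
    c("t306 == uT306", "conformation == active", "cam == unbound"),
    function(s, n = NULL) s[["t306"]] == 0L && s[["conformation"]] == 1L &&
      s[["cam"]] == 0L,
    "t306 <- pT306",
    function(s, pools) { s[["t306"]] <- 1L; list(s = s, pools = pools) }))

  names(rules) <- vapply(rules, `[[`, character(1), "name")
  structure(rules, class = "camkii_rules", rates = rates)
}

#' Evaluate a rule guard against a subunit (and neighbor) state
#'
#' @param rule a rule from [rule_table()]
#' @param subunit a subunit state (named integer vector, see
#'   [subunit_state()])
#' @param neighbor the kinase neighbor's state; required exactly when the
#'   rule is neighbor-gated, disallowed otherwise
#' @return `TRUE` iff every guard clause holds
#' @export
guard_eval <- function(rule, subunit, neighbor = NULL) {
  stopifnot(inherits(rule, "camkii_rule"))
  if (rule$participants == "neighbor_gated") {
    if (is.null(neighbor))
      stop("neighbor_gated rule '", rule$name, "' requires a neighbor state")
  } else if (!is.null(neighbor)) {
    stop("rule '", rule$name, "' takes no neighbor state")
  }
  isTRUE(rule$guard(subunit, neighbor))
}

#' Switch the CaM/PP binding exclusivity of a rule set
#'
#' Rebuilds the rule table with the exclusivity switch changed; exactly
#' two guard clauses differ between the two variants (the `cam == unbound`
#' clause of PP binding and the `t286 != PP_bound` clause of CaM binding).
#' The variant is fixed for the lifetime of a simulation.
#'
#' @param rules a `camkii_rules` object
#' @param mode `"exclusive"` or `"non_exclusive"`
#' @return a new `camkii_rules` object
#' @export
set_exclusivity <- function(rules, mode = c("exclusive", "non_exclusive")) {
  stopifnot(inherits(rules, "camkii_rules"))
  mode <- match.arg(mode)
  rates <- attr(rules, "rates")
  rates$exclusivity <- mode
  rule_table(rates)
}

#' Serialize a rule table to a plain data.frame
#'
#' One record per rule: name, participant kind, guard clauses (joined by
#' " & "), rate symbol and value, pool, and effect. Suitable for audit,
#' diffing model variants, and text export.
#'
#' @param rules a `camkii_rules` object
#' @return data.frame
#' @export
serialize_rules <- function(rules) {
  stopifnot(inherits(rules, "camkii_rules"))
  data.frame(
    name = vapply(rules, `[[`, character(1), "name"),
    participants = vapply(rules, `[[`, character(1), "participants"),
    guard = vapply(rules, function(r)
      paste(c(r$guard_desc, r$neighbor_guard_desc), collapse = " & "),
      character(1)),
    rate_name = vapply(rules, `[[`, character(1), "rate_name"),
    rate = vapply(rules, `[[`, numeric(1), "rate"),
    pool = vapply(rules, `[[`, character(1), "pool"),
    effect = vapply(rules, `[[`, character(1), "effect_desc"),
    row.names = NULL
  )
}

#' Write a rule table to a tab-separated text file
#'
#' @param rules a `camkii_rules` object
#' @param path output file path
#' @return the path, invisibly
#' @export
write_rules <- function(rules, path) {
  utils::write.table(serialize_rules(rules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.camkii_rules <- function(x, ...) {
  df <- serialize_rules(x)
  cat("CaMKII rule table (", attr(x, "rates")$exclusivity, "), ",
      nrow(df), " rules\n", sep = "")
  print(df[, c("name", "rate_name", "rate", "guard")], right = FALSE)
  invisible(x)
}
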