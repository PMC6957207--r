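# Kinetic constants and variant switches for the 2-state-2-step model.

#' Kinetic rate table for the CaMKII holoenzyme model
#'
#' Builds the full set of kinetic constants and variant switches used by
#' [rule_table()] and the simulation engines. Defaults are the published
#' parameterisation of the 2-state-2-step model:
#'
#' * `k_dock` 35 s^-1 (undocked -> docked), `k_undock` 0.63 s^-1
#'   (docked -> undocked); their ratio is the docking equilibrium
#'   constant K_docking = 0.018, so a free subunit is undocked ~1.8% of
#'   the time and the effective CaM on-rate for holoenzyme subunits is
#'   1e8 x 0.018 ~ 1.8e6 M^-1 s^-1, the full-length CaMKII measurement.
#' * `k_activate` 2e4 s^-1, `k_inactivate` 1e7 s^-1: the conformational
#'   flicker, giving an activation probability of
#'   2e4/(2e4 + 1e7) ~ 0.002 for unstabilised subunits.
#' * two-step CaM binding: `k_on_CaM` 1e8 M^-1 s^-1 to the initially
#'   bound state, `k_off_CaM_ini` 590 s^-1 (K_D 5.9 uM), compaction
#'   `k_ini_to_full` 350 s^-1 (requires the subunit open/active),
#'   de-compaction `k_full_to_ini` 4e-3 s^-1.
#' * `k_autophos` 1 s^-1 per eligible kinase-substrate pair;
#'   `k_phos_T306` 0.02 s^-1 (50-fold slower).
#' * phosphatase: `k_on_PP` 3e6 M^-1 s^-1, `k_off_PP` 0.5 s^-1,
#'   `k_cat_PP` 2 s^-1 (Michaelis constant 8.3e-7 M).
#'
#' @param ... named overrides of any default listed above.
#' @param exclusivity `"exclusive"` (bound CaM and bound PP sterically
#'   exclude one another) or `"non_exclusive"`.
#' @param dof autophosphorylation degrees of freedom: 1 (counter-clockwise
#'   intra-ring only), 2 (both intra-ring directions) or 3 (adds the
#'   directly apposed trans-ring subunit).
#' @param kon_PP_scale multiplier on `k_on_PP` (0.1 or 10 reproduce the
#'   phosphatase-association sensitivity experiments).
#' @param pp_bound_counts_as_phospho if `TRUE`, a PP-occupied Thr-286 also
#'   blocks conformational inactivation (default `FALSE`: the inactivation
#'   guard reads the flag literally).
#' @param dock_requires_inactive if `TRUE`, docking additionally requires
#'   the inactive conformation.
#' @param k252a_blocks_kinase_role if `TRUE` (default) a K252a-bound
#'   subunit can neither be phosphorylated nor act as the kinase neighbor.
#' @param stochastic_forcing if `TRUE` the square-wave CaM forcing is
#'   sampled as 1e8 s^-1 exponential conversions of individual CaM
#'   molecules instead of deterministic batch conversion at phase edges.
#' @return an object of class `camkii_rates` (named list).
#' @examples
#' r <- rate_table()
#' r$k_undock / r$k_dock          # K_docking = 0.018
#' rate_table(kon_PP_scale = 10, exclusivity = "non_exclusive")
#' @export
rate_table <- function(...,
                       exclusivity = c("exclusive", "non_exclusive"),
                       dof = 1L,
                       kon_PP_scale = 1,
                       pp_bound_counts_as_phospho = FALSE,
                       dock_requires_inactive = FALSE,
                       k252a_blocks_kinase_role = TRUE,
                       stochastic_forcing = FALSE) {
  exclusivity <- match.arg(exclusivity)
  defaults <- list(
    k_dock        = 35,
    k_undock      = 0.63,
    k_activate    = 2e4,
    k_inactivate  = 1e7,
    k_on_CaM      = 1e8,
    k_off_CaM_ini = 590,
    k_ini_to_full = 350,
    k_full_to_ini = 4e-3,
    k_autophos    = 1,
    k_phos_T306   = 0.02,
    k_on_PP       = 3e6,
    k_off_PP      = 0.5,
    k_cat_PP      = 2
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("rate overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown rate name(s): ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  bad <- vapply(defaults, function(x) !is.numeric(x) || length(x) != 1 || is.na(x) || x < 0,
                logical(1))
  if (any(bad))
    stop("rates must be single non-negative numbers: ",
         paste(names(defaults)[bad], collapse = ", "))
  if (!dof %in% 1:3) stop("dof must be 1, 2 or 3")
  if (!is.numeric(kon_PP_scale) || kon_PP_scale <= 0)
    stop("kon_PP_scale must be a positive number")

  rates <- c(defaults, list(
    exclusivity = exclusivity,
    dof = as.integer(dof),
    kon_PP_scale = kon_PP_scale,
    pp_bound_counts_as_phospho = isTRUE(pp_bound_counts_as_phospho),
    dock_requires_inactive = isTRUE(dock_requires_inactive),
    k252a_blocks_kinase_role = isTRUE(k252a_blocks_kinase_role),
    stochastic_forcing = isTRUE(stochastic_forcing)
  ))
  class(rates) <- "camkii_rates"
  rates
}

#' Activation probability of an unstabilised subunit
#'
#' Closed form `k_activate / (k_activate + k_inactivate)`; used by the
#' QSSA engine to marginalise the conformational flicker.
#'
#' @param rates a [rate_table()]
#' @return probability (~0.002 at defaults)
#' @export
activation_probability <- function(rates = rate_table()) {
  rates$k_activate / (rates$k_activate + rates$k_inactivate)
}

#' @export
print.camkii_rates <- function(x, ...) {
  cat("CaMKII rate table (", x$exclusivity, ", DOF ", x$dof, ")\n", sep = "")
  nums <- names(x)[vapply(x, is.numeric, logical(1))]
  for (n in setdiff(nums, "dof"))
    cat(sprintf("  %-14s %g\n", n, x[[n]]))
  invisible(x)
}
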