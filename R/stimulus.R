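# Ca2+/CaM forcing protocols, boluses, pulse trains and timed events.
#
# Free CaM is driven between apo-CaM and fully saturated CaM4 by a pair
# of square-wave forcing functions acting as a proxy for Ca2+ flux. The
# nominal conversion rate (1e8 s^-1) exceeds every other rate in the
# model by >= 5 orders of magnitude, so by default the conversion is
# applied deterministically at phase boundaries; CaM bound to subunits is
# untouched until it dissociates.

#' Construct a stimulus protocol
#'
#' @param mode `"continuous_bolus"` (CaM4 available for the whole run),
#'   `"pulse_train"` (square pulses at `frequency` Hz, first onset at
#'   t = 0), `"finite_bolus"` (activating for `bolus_duration` seconds,
#'   then inactivating) or `"none"` (never activating).
#' @param frequency pulse-train frequency in Hz
#' @param pulse_width pulse width in seconds (default 0.01; must not
#'   exceed the pulse period)
#' @param bolus_duration duration of a finite bolus in seconds
#' @param events data.frame with columns `time` (seconds) and `kind`
#'   (`"kinase_inhibitor"`, `"phosphatase_inhibitor"` or `"chelate_Ca"`),
#'   or NULL
#' @return object of class `stimulus_protocol`
#' @examples
#' stimulus_protocol("pulse_train", frequency = 10)
#' stimulus_protocol("finite_bolus", bolus_duration = 2,
#'                   events = data.frame(time = 30, kind = "kinase_inhibitor"))
#' @export
stimulus_protocol <- function(mode = c("continuous_bolus", "pulse_train",
                                       "finite_bolus", "none"),
                              frequency = NULL, pulse_width = 0.01,
                              bolus_duration = NULL, events = NULL) {
  mode <- match.arg(mode)
  if (mode == "pulse_train") {
    if (is.null(frequency) || !is.numeric(frequency) || frequency <= 0)
      stop("pulse_train requires frequency > 0")
    if (pulse_width <= 0 || pulse_width > 1 / frequency)
      stop("pulse_width must lie in (0, 1/frequency]")
  }
  if (mode == "finite_bolus") {
    if (is.null(bolus_duration) || bolus_duration <= 0)
      stop("finite_bolus requires bolus_duration > 0")
  }
  if (!is.null(events)) {
    stopifnot(is.data.frame(events), all(c("time", "kind") %in% names(events)))
    bad <- setdiff(events$kind,
                   c("kinase_inhibitor", "phosphatase_inhibitor", "chelate_Ca"))
    if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
    if (any(events$time < 0)) stop("event times must be >= 0")
    events <- events[order(events$time), , drop = FALSE]
  }
  structure(list(mode = mode, frequency = frequency,
                 pulse_width = pulse_width, bolus_duration = bolus_duration,
                 events = events),
            class = "stimulus_protocol")
}

#' Forcing phase at a time point
#'
#' `"activating"` drives all free CaM to CaM4; `"inactivating"` drives it
#' to apo-CaM. For a pulse train the activating windows are
#' `[k/f, k/f + pulse_width)`, k = 0, 1, 2, ...
#'
#' @param t time(s) in seconds (>= 0); vectorised
#' @param protocol a [stimulus_protocol()]
#' @return character vector, `"activating"` or `"inactivating"`
#' @export
forcing_phase <- function(t, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0)) stop("t must be >= 0")
  act <- switch(protocol$mode,
    continuous_bolus = rep(TRUE, length(t)),
    none = rep(FALSE, length(t)),
    finite_bolus = t < protocol$bolus_duration,
    pulse_train = (t - floor(t * protocol$frequency) / protocol$frequency) <
      protocol$pulse_width
  )
  ifelse(act, "activating", "inactivating")
}

#' Free-pool state of the compartment
#'
#' @param free_apo_CaM count of Ca2+-free calmodulin
#' @param free_CaM4 count of fully saturated Ca2+/CaM
#' @param free_PP count of free protein phosphatase
#' @param free_K252a count of free kinase inhibitor
#' @param volume compartment volume in liters
#' @return object of class `camkii_pools` (named list)
#' @export
pools <- function(free_apo_CaM = 0L, free_CaM4 = 0L, free_PP = 0L,
                  free_K252a = 0L, volume = DEFAULT_VOLUME) {
  counts <- c(free_apo_CaM, free_CaM4, free_PP, free_K252a)
  if (any(counts < 0)) stop("pool counts must be non-negative")
  if (volume <= 0) stop("volume must be positive")
  structure(list(free_apo_CaM = as.integer(free_apo_CaM),
                 free_CaM4 = as.integer(free_CaM4),
                 free_PP = as.integer(free_PP),
                 free_K252a = as.integer(free_K252a),
                 volume = volume),
            class = "camkii_pools")
}

#' Apply a forcing phase to the free CaM pools
#'
#' Deterministic batch conversion: an activating phase converts all free
#' apo-CaM to CaM4; an inactivating phase converts all free CaM4 to
#' apo-CaM. Subunit-bound CaM is untouched.
#'
#' @param p a [pools()] object
#' @param phase `"activating"` or `"inactivating"`
#' @return the updated pools
#' @export
apply_forcing <- function(p, phase = c("activating", "inactivating")) {
  stopifnot(inherits(p, "camkii_pools"))
  phase <- match.arg(phase)
  if (phase == "activating") {
    p$free_CaM4 <- p$free_CaM4 + p$free_apo_CaM
    p$free_apo_CaM <- 0L
  } else {
    p$free_apo_CaM <- p$free_apo_CaM + p$free_CaM4
    p$free_CaM4 <- 0L
  }
  p
}

#' Apply a timed intervention to a simulation state
#'
#' * `kinase_inhibitor`: saturating K252a; sets `inhibitor` on every
#'   subunit, blocking autophosphorylation (dephosphorylation continues).
#' * `phosphatase_inhibitor`: sets the PP catalytic rate to zero from the
#'   event time on; PP binding/unbinding dynamics are preserved.
#' * `chelate_Ca`: removes all free Ca2+ (9-state model only; a warning
#'   no-op in the 2-state model, which has no explicit Ca2+ pool).
#'
#' @param state list with elements `flags` (subunit flag matrix), `rates`,
#'   and optionally `free_Ca`
#' @param kind event kind
#' @return the updated state
#' @export
apply_event <- function(state, kind = c("kinase_inhibitor",
                                        "phosphatase_inhibitor",
                                        "chelate_Ca")) {
  kind <- match.arg(kind)
  if (kind == "kinase_inhibitor") {
    state$flags[, "inhibitor"] <- 1L
  } else if (kind == "phosphatase_inhibitor") {
    state$rates$k_cat_PP <- 0
  } else {
    if (is.null(state$free_Ca)) {
      warning("chelate_Ca is a no-op in the 2-state model (no explicit Ca2+ pool)")
    } else {
      state$free_Ca <- 0L
    }
  }
  state
}

# Internal: piecewise-constant phase schedule on [0, t_end].
# Returns data.frame(time, activating) of phase-change points, starting
# at t = 0, suitable for the engines' hard time barriers.
phase_schedule <- function(protocol, t_end) {
  stopifnot(inherits(protocol, "stimulus_protocol"), t_end > 0)
  if (protocol$mode == "continuous_bolus")
    return(data.frame(time = 0, activating = TRUE))
  if (protocol$mode == "none")
    return(data.frame(time = 0, activating = FALSE))
  if (protocol$mode == "finite_bolus") {
    if (protocol$bolus_duration >= t_end)
      return(data.frame(time = 0, activating = TRUE))
    return(data.frame(time = c(0, protocol$bolus_duration),
                      activating = c(TRUE, FALSE)))
  }
  # pulse train: onsets at k/f, offsets at k/f + width
  f <- protocol$frequency; w <- protocol$pulse_width
  onsets <- seq(0, t_end, by = 1 / f)
  times <- sort(unique(c(rbind(onsets, onsets + w))))
  times <- times[times < t_end]
  df <- data.frame(time = times,
                   activating = rep(c(TRUE, FALSE),
                                    length.out = length(times)))
  # duty cycle 1 (width == period): offsets coincide with next onsets
  if (abs(w - 1 / f) < 1e-12) df <- df[df$activating, , drop = FALSE]
  df
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol:", x$mode)
  if (x$mode == "pulse_train")
    cat(sprintf(" (%g Hz, width %g s)", x$frequency, x$pulse_width))
  if (x$mode == "finite_bolus")
    cat(sprintf(" (%g s)", x$bolus_duration))
  cat("\n")
  if (!is.null(x$events) && nrow(x$events)) {
    cat("Events:\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}
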