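# Ensemble observables: flag censuses, mean/SEM time courses, decay
# constants, frequency-response fits, and consecutive-pT286 run lengths.

#' Census of subunit flags
#'
#' @param flags subunit flag matrix (rows = subunits, columns `docking`,
#'   `conformation`, `cam`, `t286`, `t306`, `inhibitor`), e.g. an element
#'   of `ensemble$final_flags` or a snapshot
#' @param volume if non-NULL, concentrations (mol/L) are attached as
#'   attribute `"concentration"`
#' @param count_pp_bound_as_pT286 include phosphatase-occupied Thr-286 in
#'   the pT286 census (default `FALSE`: the flag is read literally)
#' @return named integer vector: `n_active`, `n_cam_initial`,
#'   `n_cam_full`, `n_pT286`, `n_PP_bound`, `n_pT306`, `n_docked`
#' @export
count_flags <- function(flags, volume = NULL, count_pp_bound_as_pT286 = FALSE) {
  stopifnot(is.matrix(flags))
  n_p <- sum(flags[, "t286"] == 1L)
  if (count_pp_bound_as_pT286) n_p <- n_p + sum(flags[, "t286"] == 2L)
  out <- c(n_active = sum(flags[, "conformation"] == 1L),
           n_cam_initial = sum(flags[, "cam"] == 1L),
           n_cam_full = sum(flags[, "cam"] == 2L),
           n_pT286 = n_p,
           n_PP_bound = sum(flags[, "t286"] == 2L),
           n_pT306 = sum(flags[, "t306"] == 1L),
           n_docked = sum(flags[, "docking"] == 0L))
  if (!is.null(volume))
    attr(out, "concentration") <- out / (AVOGADRO * volume)
  out
}

#' Extract one observable across replicates
#'
#' @param ens a `trajectory_ensemble`
#' @param observable column name of the recorded observables (e.g.
#'   `"pT286"`, `"active"`, `"cam_full"`)
#' @return matrix frames x replicates
#' @export
observable_matrix <- function(ens, observable) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (!observable %in% colnames(ens$obs[[1]]))
    stop("unknown observable: ", observable)
  sapply(ens$obs, function(m) m[, observable])
}

#' Pointwise ensemble mean and SEM of an observable
#'
#' SEM is the sample standard deviation over replicates divided by
#' sqrt(N); with a single replicate it is reported as `NA`.
#'
#' @param ens a `trajectory_ensemble`
#' @param observable observable name (see [observable_matrix()])
#' @return data.frame with `time`, `mean`, `sem`
#' @export
ensemble_stats <- function(ens, observable = "pT286") {
  m <- observable_matrix(ens, observable)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(ens$obs))
  n <- ncol(m)
  data.frame(
    time = ens$times,
    mean = rowMeans(m),
    sem = if (n >= 2) apply(m, 1, stats::sd) / sqrt(n) else NA_real_
  )
}

#' Exponential decay constant of a time course
#'
#' Least-squares slope of `ln(value)` versus time over a window (signed;
#' a decaying trace gives a negative constant, units s^-1). The trace
#' must be strictly positive on the window, which should start after the
#' peak.
#'
#' @param time time points in seconds
#' @param value trace values (counts or concentrations; the fitted
#'   constant is invariant to uniform scaling)
#' @param window two-element numeric, fit window `[t0, t1]` (default
#'   `c(5, 120)`)
#' @return fitted decay constant in s^-1
#' @examples
#' t <- seq(0, 120, 0.1)
#' fit_decay_constant(t, 3 * exp(-0.006 * t), window = c(5, 120))  # -0.006
#' @export
fit_decay_constant <- function(time, value, window = c(5, 120)) {
  stopifnot(length(time) == length(value), length(window) == 2,
            window[2] > window[1])
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 2) stop("fewer than 2 points in the fit window")
  if (any(value[sel] <= 0))
    stop("trace must be strictly positive on the window (fit after the peak)")
  unname(stats::coef(stats::lm(log(value[sel]) ~ time[sel]))[2])
}

#' Linear frequency-response fit
#'
#' Ordinary least squares of endpoint response versus stimulation
#' frequency. With fewer than 3 frequencies the fit is refused; if all
#' responses are equal the slope is 0 and R^2 is reported as 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param frequency frequencies in Hz
#' @param response endpoint responses (e.g. concentration at t = 20 s)
#' @return list with `slope`, `intercept`, `r_squared`, `degenerate`
#' @export
frequency_response <- function(frequency, response) {
  stopifnot(length(frequency) == length(response))
  if (length(frequency) < 3)
    stop("frequency_response requires at least 3 frequencies")
  if (stats::var(response) == 0)
    return(list(slope = 0, intercept = response[1], r_squared = 0,
                degenerate = TRUE))
  fit <- stats::lm(response ~ frequency)
  # summary.lm warns on exactly collinear (noise-free) input; a perfect
  # fit is a legitimate case here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       degenerate = FALSE)
}

# maximal runs of TRUE on a cyclic vector; full circle reported as length(x)
cyclic_runs <- function(x) {
  n <- length(x)
  if (!any(x)) return(integer(0))
  if (all(x)) return(n)
  # rotate so position 1 is FALSE, then ordinary run-length encoding
  start <- which(!x)[1]
  x <- x[c(start:n, seq_len(start - 1L))]
  r <- rle(x)
  as.integer(r$lengths[r$values])
}

#' Consecutive-pT286 run lengths per hexamer ring
#'
#' For each ring, the maximal cyclic runs of subunits phosphorylated at
#' Thr-286 (`pT286` or `PP_bound` both count as carrying the phosphate).
#' A fully phosphorylated ring is one run of length 6.
#'
#' @param flags subunit flag matrix of a `camkii_system` layout (rings of
#'   6 in consecutive rows)
#' @return integer vector of run lengths pooled over all rings (empty if
#'   nothing is phosphorylated)
#' @examples
#' sys <- build_holoenzyme(1)
#' sys$flags[c(1, 2, 4), "t286"] <- 1L   # ring pattern P,P,u,P,u,u
#' pT286_run_lengths(sys$flags)          # runs 2 and 1
#' @export
pT286_run_lengths <- function(flags) {
  stopifnot(is.matrix(flags), nrow(flags) %% 6 == 0)
  phos <- flags[, "t286"] %in% c(1L, 2L)
  n_rings <- nrow(flags) / 6L
  out <- integer(0)
  for (r in seq_len(n_rings)) {
    idx <- ((r - 1L) * 6L + 1L):(r * 6L)
    out <- c(out, cyclic_runs(phos[idx]))
  }
  out
}
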