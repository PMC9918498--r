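#' Fractional residual activity under the tight-binding equilibrium
#'
#' Computes the fraction of enzyme activity remaining, `v_i/v_0`, for a
#' reversible inhibitor whose affinity is high enough that depletion of free
#' inhibitor by the enzyme cannot be neglected (a tight-binding inhibitor).
#' The free/bound species follow the mass-balance quadratic popularised by
#' Morrison, so
#' \deqn{a = 1 - \frac{(E + I + K) - \sqrt{(E + I + K)^2 - 4 E I}}{2E}}
#' where \eqn{E} and \eqn{I} are total enzyme and inhibitor concentrations and
#' \eqn{K} the dissociation constant of the complex, all in the same units.
#'
#' The limit `kd = 0` reduces to the stoichiometric titration line
#' `a = 1 - min(I, E)/E`.
#'
#' @param enzyme_total total enzyme concentration (nM), a single value > 0.
#' @param inhibitor_total total inhibitor concentration (nM), vectorised,
#'   values >= 0.
#' @param kd dissociation constant of the enzyme-inhibitor complex (nM), >= 0.
#' @return numeric vector of activity fractions in `[0, 1]`.
#' @examples
#' morrison_activity(515, c(0, 250, 515), 30.25)
#' @export
morrison_activity <- function(enzyme_total, inhibitor_total, kd) {
  stopifnot(length(enzyme_total) == 1L, length(kd) == 1L)
  if (!is.finite(enzyme_total) || enzyme_total <= 0) {
    stop("`enzyme_total` must be a single positive concentration", call. = FALSE)
  }
  if (kd < 0) stop("`kd` must be >= 0", call. = FALSE)
  if (any(!is.finite(inhibitor_total)) || any(inhibitor_total < 0)) {
    stop("`inhibitor_total` must be finite and >= 0", call. = FALSE)
  }
  s <- enzyme_total + inhibitor_total + kd
  disc <- pmax(s^2 - 4 * enzyme_total * inhibitor_total, 0)
  bound <- (s - sqrt(disc)) / (2 * enzyme_total)
  a <- 1 - bound
  pmin(pmax(a, 0), 1)
}

#' Percent inhibition from paired rate measurements
#'
#' The uninhibited (positive control) rate defines 100% enzyme activity;
#' inhibition is `100 * (1 - test/control)`, clipped to `[0, 100]` so that
#' slightly super-control test rates report 0% inhibition.
#'
#' @param test_rate reaction rate with inhibitor present, >= 0 (vectorised).
#' @param control_rate reaction rate of the uninhibited control, > 0.
#' @return percent inhibition in `[0, 100]`.
#' @examples
#' percent_inhibition(30, 100) # 70
#' @export
percent_inhibition <- function(test_rate, control_rate) {
  if (length(control_rate) != 1L || !is.finite(control_rate) ||
      control_rate <= 0) {
    stop("`control_rate` must be a single rate > 0", call. = FALSE)
  }
  if (any(test_rate < 0)) stop("rates must be >= 0", call. = FALSE)
  pmin(pmax(100 * (1 - test_rate / control_rate), 0), 100)
}

#' Pre-incubation time needed for full inhibition
#'
#' Slow, tight-binding inhibitors need a pre-incubation period before
#' residual activity stabilises.  Given a time course of residual activity,
#' this returns the earliest time from which the series has plateaued: every
#' later consecutive change, and every later deviation from the final value,
#' is smaller than `tol`.
#'
#' @param series a [progress_series()] or a data frame with columns `time`
#'   (minutes) and `activity_fraction`.
#' @param tol plateau tolerance on the activity fraction (default 0.02).
#' @return plateau onset time in the units of `time`, or `NA` if the series
#'   never settles (still drifting at its end).
#' @export
preincubation_plateau <- function(series, tol = 0.02) {
  series <- as_progress_series(series)
  t <- series$time
  a <- series$activity_fraction
  n <- length(t)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  # the plateau must contain at least one settled step, so the last point
  # alone never qualifies: a series still drifting at its end "never
  # plateaus"
  for (i in seq_len(n - 1L)) {
    steps <- abs(diff(a[i:n]))
    if (all(steps < tol) && all(abs(a[i:n] - a[n]) < tol)) {
      return(t[i])
    }
  }
  NA_real_
}

#' Time course of residual activity
#'
#' @param time sampling times (minutes), non-negative and increasing.
#' @param activity_fraction residual activity fractions.
#' @return a `progress_series` data frame.
#' @export
progress_series <- function(time, activity_fraction) {
  if (length(time) != length(activity_fraction)) {
    stop("`time` and `activity_fraction` must have equal length", call. = FALSE)
  }
  if (any(time < 0) || is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be non-negative and strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time, activity_fraction = activity_fraction),
            class = c("progress_series", "data.frame"))
}

as_progress_series <- function(x) {
  if (inherits(x, "progress_series")) return(x)
  if (is.data.frame(x) && all(c("time", "activity_fraction") %in% names(x))) {
    return(progress_series(x$time, x$activity_fraction))
  }
  stop("cannot interpret input as a progress series", call. = FALSE)
}

#' Unpaired two-sample comparison of assay groups
#'
#' Classical unpaired, equal-variance Student t-test, as used to compare
#' inhibition between chromatographic fractions and controls.
#'
#' @param a,b numeric vectors of at least 2 values each.
#' @return list with elements `t`, `p` (two-sided), and `df`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate groups: zero variance in both samples", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Enzyme molarity from a mass concentration
#'
#' Converts an assay's mass concentration (ng/uL) into molarity (nM) given
#' the enzyme's molecular weight; e.g. bovine trypsin at 12 ng/uL and
#' 23,300 Da is 515 nM.
#'
#' @param ng_per_ul mass concentration in ng per microlitre.
#' @param mw molecular weight in Da (default 23300, bovine trypsin).
#' @return molar concentration in nM.
#' @export
enzyme_molarity_nM <- function(ng_per_ul, mw = 23300) {
  if (ng_per_ul < 0 || mw <= 0) stop("invalid concentration or MW", call. = FALSE)
  ng_per_ul / mw * 1e6
}
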