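# Firing-power regularisation and alarm generation.
#
# fp[n] is the fraction of the tau most recent 10-s slots classified
# preictal. Slots falling in temporal gaps left by preprocessing contribute
# 0, so the firing power decays towards zero across a gap and reaches it
# once the gap spans tau slots; missing history before the stream start
# counts as zeros under the same rule.

#' Per-window prediction series
#'
#' Pairs per-window classifier outputs with their timestamps on the 10-s
#' grid of the originating window set.
#'
#' @param o integer vector of per-window classes in `{0, 1}`.
#' @param timestamps window start times in seconds (strictly increasing,
#'   multiples of `window_s` on a common grid).
#' @param window_s window length in seconds.
#' @return A `prediction_series` object.
#' @export
prediction_series <- function(o, timestamps, window_s = 10) {
  stopifnot(length(o) == length(timestamps), all(o %in% c(0L, 1L)),
            !is.unsorted(timestamps, strictly = TRUE))
  structure(list(o = as.integer(o), timestamps = as.numeric(timestamps),
                 window_s = window_s),
            class = "prediction_series")
}

#' Gap-aware firing power
#'
#' `fp[n]` is the mean of the classifier output over the `tau` most recent
#' 10-s slots ending at window `n`; slots missing from the series (gaps left
#' by dropped windows, or history before the first window) count as zeros.
#' At the default SOP of 30 minutes, `tau = 180` slots.
#'
#' @param preds a [prediction_series()].
#' @param tau moving-window length in slots.
#' @return A `firing_power_series`: `fp` values in `[0, 1]` aligned with
#'   `preds$timestamps`.
#' @export
firing_power <- function(preds, tau = 180) {
  stopifnot(inherits(preds, "prediction_series"), tau >= 1)
  w <- preds$window_s
  slots <- round(preds$timestamps / w)
  if (length(slots) == 0) {
    fp <- numeric(0)
  } else {
    offs <- slots - slots[1] + 1L
    full <- numeric(offs[length(offs)])
    full[offs] <- preds$o
    cs <- cumsum(full)
    lo <- offs - tau
    fp <- (cs[offs] - ifelse(lo >= 1, cs[pmax(lo, 1)], 0)) / tau
  }
  structure(list(fp = fp, timestamps = preds$timestamps, tau = tau,
                 window_s = w),
            class = "firing_power_series")
}

#' Raise alarms from a firing-power series
#'
#' An alarm fires at the first window whose firing power strictly exceeds
#' the threshold; for `refractory_s` seconds afterwards (SPH + SOP = 40 min
#' at defaults) no further alarm may fire, and eligibility resumes
#' unconditionally once the refractory period ends.
#'
#' @param fps a `firing_power_series` from [firing_power()].
#' @param threshold alarm threshold on the firing power.
#' @param refractory_s refractory period in seconds.
#' @return An `alarm_record`: `alarm_times` in seconds plus the parameters.
#' @export
raise_alarms <- function(fps, threshold = 0.5, refractory_s = 2400) {
  stopifnot(inherits(fps, "firing_power_series"))
  alarm_times <- numeric(0)
  last <- -Inf
  for (i in seq_along(fps$fp)) {
    t <- fps$timestamps[i]
    if (fps$fp[i] > threshold && t >= last + refractory_s) {
      alarm_times <- c(alarm_times, t)
      last <- t
    }
  }
  structure(list(alarm_times = alarm_times, threshold = threshold,
                 refractory_s = refractory_s),
            class = "alarm_record")
}
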