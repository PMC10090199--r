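# Shared fixtures: tiny deterministic records and brute-force oracles used
# across test files. Everything is generated in code; no stored data.

# A short multichannel record built from named per-channel generator
# functions of time (seconds).
make_record <- function(duration, fs = 256, channels = list(function(t) sin(2 * pi * 10 * t)),
                        onsets = numeric(0)) {
  t <- (seq_len(duration * fs) - 1) / fs
  sig <- vapply(channels, function(f) f(t), numeric(length(t)))
  eeg_record(sig, fs, onsets = onsets)
}

rms <- function(x) sqrt(mean(x^2))

# Runs of TRUE, as data.frame(start, length), for mask assertions.
true_runs_test <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  keep <- r$values
  data.frame(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

# Brute-force firing power: for each emitted window, walk the tau most
# recent 10-s slots one by one, scoring 0 for any slot without a window.
fp_oracle <- function(o, timestamps, tau, window_s = 10) {
  slots <- round(timestamps / window_s)
  vapply(seq_along(o), function(i) {
    acc <- 0
    for (k in (slots[i] - tau + 1):slots[i]) {
      j <- match(k, slots)
      if (!is.na(j)) acc <- acc + o[j]
    }
    acc / tau
  }, 0)
}

# Brute-force alarm generation with refractory suppression.
alarm_oracle <- function(fp, timestamps, threshold = 0.5, refractory_s = 2400) {
  out <- numeric(0)
  last <- -Inf
  for (i in seq_along(fp)) {
    if (fp[i] > threshold && timestamps[i] >= last + refractory_s) {
      out <- c(out, timestamps[i])
      last <- timestamps[i]
    }
  }
  out
}

# Event-by-event alarm classification: every alarm checked against every
# onset; one true alarm per onset, earliest first.
classify_oracle <- function(alarms, onsets, sop_s = 1800, sph_s = 600) {
  used_alarm <- logical(length(alarms))
  n_true <- 0L
  for (o in onsets) {
    for (i in order(alarms)) {
      if (!used_alarm[i] && alarms[i] + sph_s <= o && o < alarms[i] + sph_s + sop_s) {
        used_alarm[i] <- TRUE
        n_true <- n_true + 1L
        break
      }
    }
  }
  list(n_true = n_true, n_false = length(alarms) - n_true)
}

# A random prediction series with random gaps, on the 10-s grid.
random_prediction_series <- function(n_slots, keep_prob = 0.8, p_one = 0.4) {
  keep <- runif(n_slots) < keep_prob
  if (!any(keep)) keep[1] <- TRUE
  ts <- (which(keep) - 1) * 10
  prediction_series(as.integer(runif(length(ts)) < p_one), ts)
}
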