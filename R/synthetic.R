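#' Configuration for the synthetic EEG generator
#'
#' Defines the study conditions a generated patient emulates: long-term
#' multichannel scalp EEG at 256 Hz with annotated lead seizures separated by
#' at least 4 h 30 min, a 1/f-like background with a posterior-rhythm alpha
#' component, a parametric preictal signature (relative theta power raised,
#' relative alpha power lowered) confined to the 30-min window ending 10 min
#' before each onset, Poisson-injected artefacts, and optional slow concept
#' drift of the background alpha amplitude.
#'
#' @param duration recording length in seconds.
#' @param seizure_onsets seizure-onset times in seconds, strictly increasing,
#'   consecutive onsets at least 16200 s (4 h 30 min) apart.
#' @param n_channels number of EEG channels (19 in the emulated montage).
#' @param fs sampling rate in Hz.
#' @param preictal_len length of the planted preictal signature in seconds
#'   (the seizure occurrence period; 1800 s).
#' @param preictal_effect dimensionless amplitude of the planted band-power
#'   shift: theta-band amplitude is multiplied by `1 + preictal_effect` and
#'   alpha-band amplitude divided by it inside the preictal window. 0 plants
#'   no signature.
#' @param artefact_rates named list of event rates per hour for types
#'   `blink`, `muscle`, `flatline`, `saturation`.
#' @param drift_rate fractional change of the background alpha amplitude per
#'   hour (0 = stationary background).
#' @param rail converter rail in microvolts; saturation artefacts clip here.
#' @param seed integer seed; every stochastic choice of the generator is a
#'   deterministic function of it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(duration,
                         seizure_onsets,
                         n_channels = 19,
                         fs = 256,
                         preictal_len = 1800,
                         preictal_effect = 0,
                         artefact_rates = list(blink = 0, muscle = 0,
                                               flatline = 0, saturation = 0),
                         drift_rate = 0,
                         rail = 500,
                         seed = 1) {
  onsets <- as.numeric(seizure_onsets)
  if (length(onsets) && is.unsorted(onsets, strictly = TRUE)) {
    stopf("seizure onsets must be strictly increasing")
  }
  if (length(onsets) >= 2) {
    gap <- min(diff(onsets))
    if (gap < 16200) {
      stopf("consecutive onsets must be >= 16200 s (4 h 30 min) apart; got %g s", gap)
    }
    if (preictal_len + 600 > gap) {
      stopf("preictal_len + SPH (600 s) must fit the minimum inter-onset gap")
    }
  }
  if (length(onsets) && max(onsets) > duration) {
    stopf("onsets must lie within the recording duration")
  }
  defaults <- list(blink = 0, muscle = 0, flatline = 0, saturation = 0)
  defaults[names(artefact_rates)] <- artefact_rates
  stopifnot(preictal_effect >= 0, drift_rate >= 0, n_channels >= 1, fs > 0)
  structure(list(duration = duration, seizure_onsets = onsets,
                 n_channels = n_channels, fs = fs,
                 preictal_len = preictal_len,
                 preictal_effect = preictal_effect,
                 artefact_rates = defaults, drift_rate = drift_rate,
                 rail = rail, seed = seed),
            class = "synth_config")
}

# Causal band-limited noise with unit standard deviation.
band_noise <- function(n, fs, band, order = 2) {
  b <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- iir_filter(b, stats::rnorm(n))
  x / stats::sd(x)
}

# White noise through a two-pole resonator centred at f0 with approximate
# bandwidth bw, normalised to unit standard deviation: a cheap rhythmic
# component for multi-hour backgrounds.
resonator_noise <- function(n, fs, f0, bw) {
  r <- 1 - pi * bw / fs
  co <- c(2 * r * cos(2 * pi * f0 / fs), -r^2)
  x <- as.numeric(stats::filter(stats::rnorm(n), co, method = "recursive"))
  x / stats::sd(x)
}

# Per-sample logical preictal mask: TRUE on [onset - SPH - SOP, onset - SPH).
preictal_sample_mask <- function(n, fs, onsets, sop_s = 1800, sph_s = 600) {
  mask <- logical(n)
  for (on in onsets) {
    lo <- max(0, on - sph_s - sop_s)
    hi <- max(0, on - sph_s)
    if (hi > lo) mask[(floor(lo * fs) + 1):min(n, ceiling(hi * fs))] <- TRUE
  }
  if (length(onsets)) {
    for (on in onsets) {
      hi <- min(n, ceiling((on - sph_s) * fs))
      if (hi >= 1) mask[hi] <- mask[hi] && ((on - sph_s) * fs > hi - 1)
    }
  }
  mask
}

#' Generate a ground-truthed synthetic EEG recording
#'
#' The background of each channel is the sum of a 1/f-like AR(1) process, a
#' band-limited alpha rhythm (8-13 Hz), a weaker theta component (4-8 Hz) and
#' broadband noise. Inside each preictal window the theta amplitude is scaled
#' by `1 + preictal_effect` and the alpha amplitude by
#' `1 / (1 + preictal_effect)`, planting a recoverable relative band-power
#' shift while leaving total morphology realistic. Output is bit-identical
#' for a fixed seed.
#'
#' @param config a [synth_config()].
#' @return A list with elements `record` (an [eeg_record()]) and `truth`
#'   (ground truth: `clean_signal`, per-sample `preictal_mask`, per-sample
#'   per-channel `artefact_mask`, and an `events` table, empty until
#'   [inject_artefacts()] is applied).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration * fs)
  nc <- config$n_channels
  pre_mask <- preictal_sample_mask(n, fs, config$seizure_onsets)
  planted <- config$preictal_effect > 0 && any(pre_mask)
  if (planted) {
    theta_gain <- 1 + config$preictal_effect * pre_mask
    alpha_gain <- 1 / theta_gain
  }
  sig <- matrix(0, n, nc)
  local_seed(derive_seed(config$seed, 0), {
    for (ch in seq_len(nc)) {
      pink <- as.numeric(stats::filter(stats::rnorm(n, sd = 6), 0.95,
                                       method = "recursive"))
      alpha <- 7 * resonator_noise(n, fs, 10.5, 4)
      theta <- 11 * resonator_noise(n, fs, 6, 3)
      broad <- stats::rnorm(n, sd = 2)
      sig[, ch] <- if (planted) {
        pink + alpha * alpha_gain + theta * theta_gain + broad
      } else {
        pink + alpha + theta + broad
      }
    }
  })
  record <- eeg_record(sig, fs, paste0("ch", seq_len(nc)),
                       onsets = config$seizure_onsets)
  truth <- structure(
    list(clean_signal = sig,
         preictal_mask = pre_mask,
         artefact_mask = matrix(FALSE, n, nc),
         events = data.frame(type = character(0), time = numeric(0),
                             duration = numeric(0))),
    class = "eeg_ground_truth")
  list(record = record, truth = truth)
}

artefact_template_blink <- function(fs, amp = 150) {
  t <- seq(0, 0.4, by = 1 / fs)
  amp * (exp(-((t - 0.12) / 0.05)^2) - 0.4 * exp(-((t - 0.26) / 0.09)^2))
}

#' Inject artefacts and experimental errors into a synthetic recording
#'
#' Adds eye-blink transients (frontally weighted low-frequency biphasic
#' waves), muscle bursts (20-90 Hz band-limited noise on a random channel
#' subset), flatlines (held constant values on all channels) and saturation
#' (samples clipped at the converter rail) at Poisson event times with the
#' configured per-hour rates. Each artefact type draws from its own seed
#' stream, so toggling one type leaves the others' event times unchanged.
#' The ground truth's `clean_signal` is untouched; `artefact_mask` and the
#' `events` table record every injected event.
#'
#' @param record an [eeg_record()] produced by [generate_recording()].
#' @param truth the matching ground truth.
#' @param config the [synth_config()] used to generate the recording.
#' @return A list with updated `record` and `truth`.
#' @export
inject_artefacts <- function(record, truth, config) {
  fs <- record$fs
  n <- n_samples(record)
  nc <- n_channels(record)
  dur_h <- n / fs / 3600
  sig <- record$signal
  mask <- truth$artefact_mask
  events <- truth$events
  frontal <- seq_len(min(4, nc))
  weights <- rep(0.15, nc)
  weights[frontal] <- 1

  add_events <- function(type, stream, max_len, body) {
    local_seed(derive_seed(config$seed, stream), {
      rate <- config$artefact_rates[[type]]
      k <- if (rate > 0) stats::rpois(1, rate * dur_h) else 0L
      if (k > 0) {
        times <- sort(stats::runif(k, 0, max(0, n / fs - max_len)))
        for (tt in times) {
          len <- body(tt)
          events <<- rbind(events, data.frame(type = type, time = tt,
                                              duration = len))
        }
      }
    })
  }

  add_events("blink", 1, 0.5, function(tt) {
    tpl <- artefact_template_blink(fs)
    idx <- floor(tt * fs) + seq_along(tpl)
    idx <- idx[idx <= n]
    sig[idx, ] <<- sig[idx, ] + outer(tpl[seq_along(idx)], weights)
    mask[idx, frontal] <<- TRUE
    length(idx) / fs
  })
  add_events("muscle", 2, 2.1, function(tt) {
    len <- stats::runif(1, 0.5, 2)
    m <- round(len * fs)
    idx <- floor(tt * fs) + seq_len(m)
    idx <- idx[idx <= n]
    chans <- which(stats::runif(nc) < 0.5)
    if (!length(chans)) chans <- sample.int(nc, 1)
    taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
    for (ch in chans) {
      burst <- 30 * band_noise(length(idx) + 64, fs, c(20, min(90, fs / 2 - 1)))
      sig[idx, ch] <<- sig[idx, ch] + burst[65:(64 + length(idx))] * taper
    }
    mask[idx, chans] <<- TRUE
    length(idx) / fs
  })
  add_events("flatline", 3, 5.1, function(tt) {
    len <- stats::runif(1, 2, 5)
    idx <- floor(tt * fs) + seq_len(round(len * fs))
    idx <- idx[idx <= n]
    sig[idx, ] <<- matrix(sig[idx[1], ], length(idx), nc, byrow = TRUE)
    mask[idx, ] <<- TRUE
    length(idx) / fs
  })
  add_events("saturation", 4, 3.1, function(tt) {
    len <- stats::runif(1, 1, 3)
    idx <- floor(tt * fs) + seq_len(round(len * fs))
    idx <- idx[idx <= n]
    s <- sign(sig[idx, , drop = FALSE])
    s[s == 0] <- 1
    sig[idx, ] <<- s * config$rail
    mask[idx, ] <<- TRUE
    length(idx) / fs
  })

  record$signal <- sig
  truth$artefact_mask <- mask
  truth$events <- events
  list(record = record, truth = truth)
}

#' Apply slow concept drift to a recording
#'
#' The background alpha-band (8-13 Hz) amplitude declines linearly in time:
#' at time `t` seconds the alpha component is scaled by
#' `max(1 - drift_rate * t / 3600, 0.1)`, emulating the slow suppression of
#' the posterior rhythm seen across long pre-surgical monitoring (e.g. under
#' medication tapering). The drift is a deterministic function of the
#' configuration (no randomness), and `drift_rate = 0` is the identity.
#'
#' @param record an [eeg_record()].
#' @param config the [synth_config()] (only `drift_rate` is used).
#' @return The drifted [eeg_record()].
#' @export
apply_concept_drift <- function(record, config) {
  if (config$drift_rate == 0) return(record)
  fs <- record$fs
  n <- n_samples(record)
  g <- pmax(1 - config$drift_rate * (seq_len(n) - 1) / fs / 3600, 0.1) - 1
  b <- signal::butter(2, c(8, 13) / (fs / 2), type = "pass")
  for (ch in seq_len(n_channels(record))) {
    alpha <- iir_filtfilt(b, record$signal[, ch])
    record$signal[, ch] <- record$signal[, ch] + g * alpha
  }
  record
}

#' Generate a complete synthetic patient
#'
#' Convenience wrapper: [generate_recording()], then [apply_concept_drift()],
#' then [inject_artefacts()].
#'
#' @param config a [synth_config()].
#' @return A list with `record`, `truth` and the `config`.
#' @export
synth_patient <- function(config) {
  g <- generate_recording(config)
  g$record <- apply_concept_drift(g$record, config)
  g$truth$clean_signal <- g$record$signal
  g <- inject_artefacts(g$record, g$truth, config)
  list(record = g$record, truth = g$truth, config = config)
}
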