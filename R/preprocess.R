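#' Band-pass and notch filter an EEG recording
#'
#' Applies a fourth-order 0.5-100 Hz Butterworth band-pass and a second-order
#' 50 Hz notch (49-51 Hz band-stop), zero-phase, per channel. Zero-phase
#' filtering avoids phase distortion of the features computed downstream; it
#' is realised in the frequency domain by applying the cascade's squared
#' magnitude response (identical to forward-backward filtering up to
#' boundary transients, and considerably faster on multi-hour recordings).
#'
#' @param record an [eeg_record()]; sampling rate must exceed 200 Hz so the
#'   100 Hz band edge stays below Nyquist.
#' @return The filtered [eeg_record()], same shape.
#' @name frequency_filter
NULL

.filter_gain_cache <- new.env(parent = emptyenv())

# Squared-magnitude response |H_bp|^2 * |H_notch|^2 on m FFT bins: the exact
# amplitude response of the zero-phase (forward-backward) cascade.
zero_phase_gain <- function(m, fs) {
  key <- paste0(m, "_", fs)
  if (!exists(key, envir = .filter_gain_cache)) {
    bp <- signal::butter(2, c(0.5, 100) / (fs / 2), type = "pass")
    notch <- signal::butter(1, c(49, 51) / (fs / 2), type = "stop")
    z <- exp(-2i * pi * (seq_len(m) - 1) / m)
    polyval_z <- function(cf) {
      acc <- rep(cf[length(cf)] + 0i, m)
      for (j in (length(cf) - 1):1) acc <- acc * z + cf[j]
      acc
    }
    g <- Mod(polyval_z(bp$b) / polyval_z(bp$a))^2 *
      Mod(polyval_z(notch$b) / polyval_z(notch$a))^2
    if (length(ls(.filter_gain_cache)) > 2) {
      rm(list = ls(.filter_gain_cache), envir = .filter_gain_cache)
    }
    assign(key, g, envir = .filter_gain_cache)
  }
  get(key, envir = .filter_gain_cache)
}

#' @rdname frequency_filter
#' @export
frequency_filter <- function(record) {
  fs <- record$fs
  if (fs <= 200) stopf("sampling rate %g Hz too low: 100 Hz band edge at or above Nyquist", fs)
  n <- n_samples(record)
  m <- stats::nextn(n, c(2, 3, 5))
  g <- zero_phase_gain(m, fs)
  for (ch in seq_len(n_channels(record))) {
    xf <- stats::fft(c(record$signal[, ch], numeric(m - n)))
    record$signal[, ch] <- Re(stats::fft(xf * g, inverse = TRUE))[seq_len(n)] / m
  }
  record
}

# Per-channel runs of >= min_len identical consecutive samples.
flatline_samples <- function(x, min_len) {
  out <- logical(length(x))
  r <- true_runs(c(FALSE, diff(x) == 0))
  r <- r[r$length >= min_len - 1, , drop = FALSE]
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      out[(r$start[i] - 1):(r$start[i] + r$length[i] - 1)] <- TRUE
    }
  }
  out
}

#' Mark experimental errors: flatlines, saturation, extreme amplitude
#'
#' Detects acquisition errors on the raw signal and returns a per-sample
#' validity mask (`TRUE` = usable). A sample is invalid on all channels when,
#' on any channel, it lies inside a flatline run of at least `flat_min_s`
#' seconds, inside a run of at least `sat_min_s` seconds of samples at or
#' above `sat_frac` of the converter rail (estimated as the maximum absolute
#' amplitude observed), or when its absolute amplitude exceeds `amp_max`.
#' Run this before band-pass filtering: zero-phase filtering destroys the
#' exact sample equality that identifies flatlines.
#'
#' @param record an [eeg_record()] (raw, unfiltered).
#' @param flat_min_s minimum flatline duration in seconds.
#' @param sat_frac fraction of the observed rail treated as clipping.
#' @param amp_max absolute amplitude threshold in microvolts.
#' @param sat_min_s minimum duration of a clipped run in seconds.
#' @return Logical vector of length `n_samples`, `TRUE` where valid.
#' @export
remove_experimental_errors <- function(record, flat_min_s = 1,
                                       sat_frac = 0.99, amp_max = 500,
                                       sat_min_s = 0.25) {
  stopifnot(flat_min_s > 0, sat_frac > 0, amp_max > 0)
  fs <- record$fs
  n <- n_samples(record)
  invalid <- logical(n)
  rail <- max(abs(record$signal))
  for (ch in seq_len(n_channels(record))) {
    x <- record$signal[, ch]
    ax <- abs(x)
    d0 <- c(FALSE, diff(x) == 0)
    if (any(d0)) invalid <- invalid | flatline_samples(x, round(flat_min_s * fs))
    sat <- ax >= sat_frac * rail
    if (any(sat)) {
      r <- true_runs(sat)
      r <- r[r$length >= round(sat_min_s * fs), , drop = FALSE]
      if (nrow(r)) {
        for (i in seq_len(nrow(r))) {
          invalid[r$start[i]:(r$start[i] + r$length[i] - 1)] <- TRUE
        }
      }
    }
    invalid <- invalid | (ax > amp_max)
  }
  !invalid
}

#' Discard the postictal period after each seizure onset
#'
#' Marks the first 30 minutes of signal after each seizure onset as invalid,
#' eliminating the influence of a possible postictal state.
#'
#' @param record an [eeg_record()] with onset annotations.
#' @param postictal_s discarded interval length in seconds.
#' @return Logical validity vector (`TRUE` = usable).
#' @export
discard_postictal <- function(record, postictal_s = 1800) {
  n <- n_samples(record)
  fs <- record$fs
  valid <- rep(TRUE, n)
  for (on in record$onsets) {
    lo <- floor(on * fs) + 1
    hi <- min(n, ceiling((on + postictal_s) * fs))
    if (lo <= hi) valid[lo:hi] <- FALSE
  }
  valid
}

# ---- Denoiser interface ---------------------------------------------------

.denoisers <- new.env(parent = emptyenv())

#' Denoisers: pluggable artefact-removal stage
#'
#' A denoiser is a named transform `eeg_record -> eeg_record` of identical
#' shape. Two are built in: `"identity"` (no-op; the noisy branch of the
#' pipeline) and `"default"` (a deterministic blink-regression and
#' muscle-burst attenuator; the denoised branch). Custom denoisers, e.g. a
#' trained neural model, can be registered under a new name.
#'
#' @param name denoiser name.
#' @param transform function of one argument (an [eeg_record()]) returning an
#'   [eeg_record()] of the same shape.
#' @return `new_denoiser()` returns the denoiser object; `register_denoiser()`
#'   returns it invisibly; `get_denoiser()` looks one up by name.
#' @export
new_denoiser <- function(name, transform) {
  structure(list(name = name, transform = transform), class = "eeg_denoiser")
}

#' @rdname new_denoiser
#' @export
register_denoiser <- function(denoiser) {
  stopifnot(inherits(denoiser, "eeg_denoiser"))
  assign(denoiser$name, denoiser, envir = .denoisers)
  invisible(denoiser)
}

#' @rdname new_denoiser
#' @export
get_denoiser <- function(name) {
  if (inherits(name, "eeg_denoiser")) return(name)
  if (!exists(name, envir = .denoisers)) {
    stopf("unknown denoiser '%s'; registered: %s", name,
          paste(ls(.denoisers), collapse = ", "))
  }
  get(name, envir = .denoisers)
}

#' Apply a denoiser to a recording
#'
#' @param record an [eeg_record()].
#' @param denoiser a denoiser object or registered name.
#' @return The denoised [eeg_record()], same shape.
#' @export
denoise <- function(record, denoiser = "default") {
  d <- get_denoiser(denoiser)
  out <- d$transform(record)
  stopifnot(identical(dim(out$signal), dim(record$signal)))
  out
}

# Default denoiser: (1) remove frontally-referenced low-frequency blink
# transients by a robust (median-of-ratios) regression of each channel's low
# band on a frontal reference, restricted to samples where the reference is
# in a transient; (2) attenuate 20-90 Hz bursts whose short-window RMS
# exceeds a rolling median by a configurable factor. Deterministic and
# dependency-free; stands behind the pluggable interface that a trained
# artefact-removal model would occupy.
default_denoise_transform <- function(record, burst_factor = 4) {
  fs <- record$fs
  nc <- n_channels(record)
  n <- n_samples(record)
  sig <- record$signal
  lowp <- signal::butter(2, 5 / (fs / 2), type = "low")
  frontal <- seq_len(min(4, nc))
  ylow <- iir_filtfilt(lowp, sig)
  ref <- rowMeans(ylow[, frontal, drop = FALSE])
  thr <- 4 * stats::mad(ref)
  flagged <- abs(ref) > thr
  # dilate the flagged spans by 0.2 s so whole transients are covered
  if (any(flagged)) {
    k <- round(0.2 * fs)
    flagged <- as.logical(stats::filter(as.numeric(flagged), rep(1, 2 * k + 1),
                                        sides = 2))
    flagged[is.na(flagged)] <- FALSE
  }
  if (sum(flagged) >= fs) {
    idx <- which(flagged)
    # slope estimation only needs a thinned sample of the flagged region
    fit_idx <- idx[abs(ref[idx]) > thr]
    if (length(fit_idx) > 20000) {
      fit_idx <- fit_idx[seq(1, length(fit_idx), length.out = 20000)]
    }
    for (ch in seq_len(nc)) {
      b <- stats::median(ylow[fit_idx, ch] / ref[fit_idx])
      sig[idx, ch] <- sig[idx, ch] - b * ref[idx]
    }
  }
  hi_edge <- min(90, 0.45 * fs)
  hb_filt <- signal::butter(2, c(20, hi_edge) / (fs / 2), type = "pass")
  blk <- max(1, round(0.25 * fs))
  n_blk <- floor(n / blk)
  if (n_blk >= 3) {
    hb_all <- iir_filtfilt(hb_filt, sig)
    for (ch in seq_len(nc)) {
      hb <- hb_all[, ch]
      m <- matrix(hb[seq_len(n_blk * blk)]^2, blk, n_blk)
      rms <- sqrt(colMeans(m))
      k <- min(n_blk - (1 - n_blk %% 2), 241)
      med <- stats::runmed(rms, k)
      hot <- which(rms > burst_factor * med & rms > 0)
      for (b in hot) {
        span <- ((b - 1) * blk + 1):(b * blk)
        sig[span, ch] <- sig[span, ch] - hb[span] * (1 - med[b] / rms[b])
      }
    }
  }
  record$signal <- sig
  record
}

ensure_builtin_denoisers <- function() {
  if (!exists("identity", envir = .denoisers)) {
    register_denoiser(new_denoiser("identity", function(record) record))
    register_denoiser(new_denoiser("default", default_denoise_transform))
  }
}

.onLoad <- function(libname, pkgname) {
  ensure_builtin_denoisers()
}

# ---- Windowing ------------------------------------------------------------

#' Segment a recording into non-overlapping 10-second windows
#'
#' Windows are aligned to the record start on a fixed 10-s grid; any window
#' spanning an invalid sample is dropped, as is a partial trailing window.
#' Each emitted window carries a flag stating whether it is temporally
#' contiguous with the previously emitted one (gaps are left by dropped
#' windows). Window data is not copied: the window set references the parent
#' record and materialises windows on demand.
#'
#' @param record an [eeg_record()].
#' @param validity logical per-sample validity mask (defaults to all valid).
#' @param window_s window length in seconds.
#' @return An object of class `eeg_windows` with fields `timestamps` (window
#'   start times in seconds), `contiguous_with_previous`, `fs`,
#'   `window_s`, `n_dropped`, and the parent record.
#' @export
segment <- function(record, validity = NULL, window_s = 10) {
  fs <- record$fs
  n <- n_samples(record)
  L <- round(window_s * fs)
  n_slots <- floor(n / L)
  if (is.null(validity)) validity <- rep(TRUE, n)
  stopifnot(length(validity) == n)
  if (n_slots == 0) {
    keep <- logical(0)
  } else {
    vm <- matrix(validity[seq_len(n_slots * L)], L, n_slots)
    keep <- colSums(vm) == L
  }
  starts <- (which(keep) - 1L) * window_s
  contig <- c(FALSE, diff(starts) == window_s)
  structure(
    list(record = record, fs = fs, window_s = window_s,
         timestamps = starts,
         contiguous_with_previous = as.logical(contig),
         n_slots = n_slots, n_dropped = n_slots - sum(keep)),
    class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows of %g s (%d slots, %d dropped), %d channels\n",
              length(x$timestamps), x$window_s, x$n_slots, x$n_dropped,
              n_channels(x$record)))
  invisible(x)
}

#' Number of emitted windows in a window set
#'
#' @param ws an `eeg_windows` object.
#' @return Window count.
#' @export
n_windows <- function(ws) length(ws$timestamps)

#' Materialise one window's samples
#'
#' @param ws an `eeg_windows` object from [segment()].
#' @param i window index.
#' @return A (window length x channels) numeric matrix.
#' @export
window_data <- function(ws, i) {
  L <- round(ws$window_s * ws$fs)
  start <- round(ws$timestamps[i] * ws$fs)
  ws$record$signal[(start + 1):(start + L), , drop = FALSE]
}
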