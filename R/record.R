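#' EEG recording container
#'
#' Bundles a multichannel EEG signal with its sampling rate, channel labels,
#' absolute start time, and seizure-onset annotations. The signal is stored as
#' a samples x channels numeric matrix in microvolts (column-major storage
#' makes per-channel operations cheap in R).
#'
#' @param signal numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param start_time absolute start time of the recording in seconds.
#' @param onsets numeric vector of seizure-onset times, in seconds from the
#'   start of the recording, strictly increasing.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, channel_labels = NULL, start_time = 0,
                       onsets = numeric(0)) {
  signal <- as.matrix(signal)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(signal)))
  }
  if (length(channel_labels) != ncol(signal)) {
    stopf("number of channel labels (%d) must equal number of channels (%d)",
          length(channel_labels), ncol(signal))
  }
  onsets <- as.numeric(onsets)
  if (is.unsorted(onsets, strictly = TRUE)) {
    stopf("seizure onsets must be strictly increasing")
  }
  dur <- nrow(signal) / fs
  if (length(onsets) && (min(onsets) < 0 || max(onsets) > dur)) {
    stopf("onsets must lie within [0, %g] s", dur)
  }
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         start_time = start_time, onsets = onsets),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f h), %d seizure onset(s)\n",
              ncol(x$signal), nrow(x$signal), x$fs,
              nrow(x$signal) / x$fs / 3600, length(x$onsets)))
  invisible(x)
}

#' Record accessors
#'
#' @param record an [eeg_record()].
#' @return Sample count, channel count, or duration in seconds.
#' @export
n_samples <- function(record) nrow(record$signal)

#' @rdname n_samples
#' @export
n_channels <- function(record) ncol(record$signal)

#' @rdname n_samples
#' @export
record_duration <- function(record) nrow(record$signal) / record$fs

# ---- EDF I/O --------------------------------------------------------------
# Minimal continuous-signal EDF (16-bit integers with physical scaling, 1-s
# data records). Covers exactly what the pipeline emits and reads back; not a
# general EDF+ implementation.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with per-channel physical scaling and 1-second data records.
#' Recordings whose duration is not a whole number of seconds are zero-padded
#' to the next full second.
#'
#' @param record an [eeg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  fs <- record$fs
  nc <- n_channels(record)
  ns <- n_samples(record)
  n_rec <- ceiling(ns / fs)
  sig <- record$signal
  if (n_rec * fs > ns) {
    sig <- rbind(sig, matrix(0, n_rec * fs - ns, nc))
  }
  phys_max <- pmax(apply(abs(sig), 2, max), 1)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(x, width) {
    writeChar(paste0(edf_pad(x, width), collapse = ""), con, eos = NULL)
  }
  wchar("0", 8)
  wchar("synthetic subject", 80)
  wchar("synthetic recording", 80)
  wchar("01.01.00", 8)
  wchar("00.00.00", 8)
  wchar(as.character(256 + 256 * nc), 8)
  wchar("", 44)
  wchar(as.character(n_rec), 8)
  wchar("1", 8)
  wchar(as.character(nc), 4)
  for (lab in record$channel_labels) wchar(lab, 16)
  for (i in seq_len(nc)) wchar("", 80)
  for (i in seq_len(nc)) wchar("uV", 8)
  for (i in seq_len(nc)) wchar(sprintf("%.6g", -phys_max[i]), 8)
  for (i in seq_len(nc)) wchar(sprintf("%.6g", phys_max[i]), 8)
  for (i in seq_len(nc)) wchar(as.character(-dig_max), 8)
  for (i in seq_len(nc)) wchar(as.character(dig_max), 8)
  for (i in seq_len(nc)) wchar("", 80)
  for (i in seq_len(nc)) wchar(as.character(fs), 8)
  for (i in seq_len(nc)) wchar("", 32)
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nc)) {
      dig <- as.integer(round(sig[idx, ch] * scale[ch]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param onsets optional seizure-onset annotations (seconds) to attach.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, onsets = numeric(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rchar(8); rchar(80); rchar(80); rchar(8); rchar(8); rchar(8); rchar(44)
  n_rec <- as.integer(rchar(8))
  rec_dur <- as.numeric(rchar(8))
  nc <- as.integer(rchar(4))
  labels <- vapply(seq_len(nc), function(i) rchar(16), "")
  for (i in seq_len(nc)) rchar(80)
  for (i in seq_len(nc)) rchar(8)
  phys_min <- vapply(seq_len(nc), function(i) as.numeric(rchar(8)), 0)
  phys_max <- vapply(seq_len(nc), function(i) as.numeric(rchar(8)), 0)
  dig_min <- vapply(seq_len(nc), function(i) as.numeric(rchar(8)), 0)
  dig_max <- vapply(seq_len(nc), function(i) as.numeric(rchar(8)), 0)
  for (i in seq_len(nc)) rchar(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(rchar(8)), 0L)
  for (i in seq_len(nc)) rchar(32)
  if (length(unique(spr)) != 1) stopf("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- matrix(0, n_rec * spr[1], nc)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      sig[idx, ch] <- dig * scale[ch]
    }
  }
  eeg_record(sig, fs, labels, onsets = onsets)
}

#' Read or write seizure-onset annotations as CSV
#'
#' The annotation file has columns `onset_seconds` and `label`.
#'
#' @param onsets numeric vector of onset times in seconds.
#' @param path CSV file path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns a data.frame with columns `onset_seconds`
#'   and `label`.
#' @export
write_annotations <- function(onsets, path) {
  utils::write.csv(
    data.frame(onset_seconds = as.numeric(onsets),
               label = rep("seizure_onset", length(onsets))),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset_seconds", "label") %in% names(df))) {
    stopf("annotation file must have columns onset_seconds,label")
  }
  df
}
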