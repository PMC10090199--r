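# SOP/SPH labelling and chronological train/test assembly.
#
# Label semantics per window start time t and seizure onset o:
#   preictal  (1): t in [o - SPH - SOP, o - SPH)   -- the training SOP
#   discarded (-1): t in [o - SPH, o)              -- the SPH, not used
#   interictal (0): anything earlier than o - SPH - SOP (or after an onset,
#                   once the postictal discard has removed the first 30 min).

#' Label windows under SOP/SPH semantics
#'
#' Each window is assigned by its start time: preictal (1) inside the
#' seizure occurrence period `[onset - sph_s - sop_s, onset - sph_s)`,
#' discarded (-1) inside the prediction horizon `[onset - sph_s, onset)`,
#' interictal (0) otherwise. `seizure_index` is the index of the next onset
#' after the window (NA after the last onset).
#'
#' @param windows an `eeg_windows` object or a numeric vector of window
#'   start times in seconds.
#' @param onsets sorted seizure-onset times in seconds.
#' @param sop_s seizure occurrence period in seconds (30 min).
#' @param sph_s seizure prediction horizon in seconds (10 min).
#' @return A `labelled_windows` data.frame with columns `timestamp`, `label`,
#'   `seizure_index`.
#' @export
label_windows <- function(windows, onsets, sop_s = 1800, sph_s = 600) {
  ts <- if (inherits(windows, "eeg_windows")) windows$timestamps else as.numeric(windows)
  stopifnot(!is.unsorted(onsets))
  lab <- integer(length(ts))
  seiz <- rep(NA_integer_, length(ts))
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    pre <- ts >= on - sph_s - sop_s & ts < on - sph_s
    sph <- ts >= on - sph_s & ts < on
    lab[pre] <- 1L
    lab[sph] <- -1L
    seiz[ts < on & is.na(seiz)] <- i
  }
  out <- data.frame(timestamp = ts, label = lab, seizure_index = seiz)
  attr(out, "sop_s") <- sop_s
  attr(out, "sph_s") <- sph_s
  class(out) <- c("labelled_windows", "data.frame")
  out
}

#' Chronological 60/40 seizure-level split
#'
#' The first `round(train_fraction * n)` seizures (round half up, minimum 2)
#' form the training set; the remainder are test seizures. Requires at least
#' three seizures, mirroring the patient-selection rule of the emulated
#' cohort.
#'
#' @param onsets seizure-onset times (only their count is used).
#' @param train_fraction fraction of seizures assigned to training.
#' @return A list with `train` and `test` seizure indices.
#' @export
chronological_split <- function(onsets, train_fraction = 0.6) {
  n <- length(onsets)
  if (n < 3) stopf("at least 3 seizures are required; got %d", n)
  n_train <- max(2L, as.integer(floor(train_fraction * n + 0.5)))
  n_train <- min(n_train, n - 1L)
  structure(list(train = seq_len(n_train), test = (n_train + 1L):n,
                 train_fraction = train_fraction),
            class = "split_spec")
}

#' Restrict training data to the hours before each training seizure
#'
#' For every training seizure, only windows starting within
#' `[onset - train_window_s, onset)` are retained (including SPH-discarded
#' ones, which the trainer ignores). The restriction bounds the interictal
#' class and the training compute.
#'
#' @param labelled a `labelled_windows` data.frame.
#' @param split a split from [chronological_split()].
#' @param onsets seizure-onset times in seconds.
#' @param train_window_s retained pre-onset history in seconds (4 h).
#' @return Integer row indices into `labelled`.
#' @export
training_view <- function(labelled, split, onsets, train_window_s = 14400) {
  keep <- logical(nrow(labelled))
  for (i in split$train) {
    on <- onsets[i]
    keep <- keep | (labelled$timestamp >= on - train_window_s &
                    labelled$timestamp < on &
                    !is.na(labelled$seizure_index) &
                    labelled$seizure_index == i)
  }
  which(keep)
}

#' Test segments: from 30 min after the previous onset to the current onset
#'
#' For each test seizure the evaluation segment runs from 30 minutes after
#' the previous seizure's onset (skipping its postictal) until the onset
#' under analysis.
#'
#' @inheritParams training_view
#' @param postictal_s skipped post-onset interval of the previous seizure.
#' @return A list with `rows` (integer row indices into `labelled`) and
#'   `segments` (data.frame `seizure_index`, `start`, `end` in seconds).
#' @export
test_view <- function(labelled, split, onsets, postictal_s = 1800) {
  rows <- integer(0)
  segs <- data.frame(seizure_index = integer(0), start = numeric(0),
                     end = numeric(0))
  for (i in split$test) {
    start <- onsets[i - 1] + postictal_s
    end <- onsets[i]
    sel <- which(labelled$timestamp >= start & labelled$timestamp < end)
    rows <- c(rows, sel)
    segs <- rbind(segs, data.frame(seizure_index = i, start = start, end = end))
  }
  list(rows = rows, segments = segs)
}

#' Sample-level holdout split for early stopping
#'
#' Randomly divides labelled training samples into a new training set and a
#' validation set (default 80/20), stratified by class so a small preictal
#' class is represented in both; deterministic given the seed. Set
#' `stratify = FALSE` for a plain random split.
#'
#' @param labels class labels (0/1) of the candidate samples.
#' @param ratio fraction assigned to the new training set.
#' @param seed integer seed.
#' @param stratify stratify by class?
#' @return A list with integer index vectors `train` and `validation`.
#' @export
holdout_split <- function(labels, ratio = 0.8, seed = 1, stratify = TRUE) {
  n <- length(labels)
  if (n < 5) stopf("need at least 5 labelled samples; got %d", n)
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  local_seed(derive_seed(seed, 11), {
    if (stratify) {
      tr <- integer(0)
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        k <- round(ratio * length(idx))
        tr <- c(tr, sort(sample(idx, k)))
      }
      tr <- sort(tr)
    } else {
      tr <- sort(sample(n, round(ratio * n)))
    }
    list(train = tr, validation = setdiff(seq_len(n), tr))
  })
}

#' Z-score normalisation fitted on training samples only
#'
#' `zscore_fit()` computes per-column means and standard deviations from the
#' training matrix; `zscore_apply()` standardises any matrix with those
#' statistics. Columns with zero training SD map to 0. The normaliser
#' records the number of samples it was fitted on, so leakage audits can
#' confirm no test data entered it.
#'
#' @param X numeric matrix (samples x features), training samples only.
#' @return For `zscore_fit()`, a `zscore_normaliser`; for `zscore_apply()`,
#'   the standardised matrix.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  structure(list(mean = colMeans(X), sd = apply(X, 2, stats::sd),
                 n_fit = nrow(X)),
            class = "zscore_normaliser")
}

#' @rdname zscore_fit
#' @param normaliser a fitted `zscore_normaliser`.
#' @export
zscore_apply <- function(normaliser, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(normaliser$mean))
  sd <- normaliser$sd
  out <- sweep(X, 2, normaliser$mean)
  out <- sweep(out, 2, ifelse(sd > 0, sd, 1), "/")
  out[, sd == 0] <- 0
  out
}
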