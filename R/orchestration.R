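# End-to-end per-patient experiment driver: preprocessing branch (noisy /
# denoised), classifier family (shallow features / deep time series),
# training regime (standard / chronological), firing-power alarms and
# surrogate-validated evaluation.

#' Experiment configuration
#'
#' Collects every stage parameter of the per-patient pipeline. Defaults are
#' the full-scale study conditions (SOP 30 min, SPH 10 min, postictal
#' discard 30 min, 4-h training restriction, 60/40 chronological split,
#' 80/20 sample holdout, firing-power window tau = SOP / 10 s = 180,
#' threshold 0.5, refractory 40 min, 31-member ensembles).
#' [desk_experiment_config()] is a reduced profile for desk-scale synthetic
#' studies: 2-h training restriction, 5-member ensembles, shorter training
#' schedule, and a compact deep profile.
#'
#' @param branch `"noisy"` (identity denoiser) or `"denoised"` (default
#'   denoiser, or the denoiser named in `denoiser`).
#' @param classifier `"shallow_features"` or `"deep_timeseries"`.
#' @param regime `"standard"` or `"chronological"`.
#' @param sop_s,sph_s,postictal_s label/alarm semantics in seconds.
#' @param train_window_s pre-onset history retained per training seizure.
#' @param train_fraction seizure-level training fraction.
#' @param holdout_ratio,stratify sample-level holdout for early stopping.
#' @param threshold,refractory_s alarm generation parameters.
#' @param n_surrogates,surrogate_method chance-level analysis parameters.
#' @param train a [train_config()].
#' @param hidden_neurons optional hidden width of the shallow network.
#' @param deep named list of [deep_spec()] overrides (blocks,
#'   filters_start, lstm_units).
#' @param denoiser denoiser name used by the denoised branch.
#' @param flat_min_s,sat_frac,amp_max experimental-error thresholds.
#' @param seed_base base seed for every stochastic stage.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(branch = c("denoised", "noisy"),
                              classifier = c("shallow_features", "deep_timeseries"),
                              regime = c("standard", "chronological"),
                              sop_s = 1800, sph_s = 600, postictal_s = 1800,
                              train_window_s = 14400, train_fraction = 0.6,
                              holdout_ratio = 0.8, stratify = TRUE,
                              threshold = 0.5, refractory_s = sop_s + sph_s,
                              n_surrogates = 30, surrogate_method = "rank",
                              train = train_config(),
                              hidden_neurons = NULL,
                              deep = list(blocks = 3, filters_start = 128,
                                          lstm_units = 64),
                              denoiser = "default",
                              flat_min_s = 1, sat_frac = 0.99, amp_max = 500,
                              seed_base = 0) {
  structure(list(branch = match.arg(branch), classifier = match.arg(classifier),
                 regime = match.arg(regime), sop_s = sop_s, sph_s = sph_s,
                 postictal_s = postictal_s, train_window_s = train_window_s,
                 train_fraction = train_fraction,
                 holdout_ratio = holdout_ratio, stratify = stratify,
                 threshold = threshold, refractory_s = refractory_s,
                 tau = as.integer(round(sop_s / 10)),
                 n_surrogates = n_surrogates,
                 surrogate_method = surrogate_method, train = train,
                 hidden_neurons = hidden_neurons, deep = deep,
                 denoiser = denoiser, flat_min_s = flat_min_s,
                 sat_frac = sat_frac, amp_max = amp_max,
                 seed_base = seed_base),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param ... overrides passed to [experiment_config()].
#' @export
desk_experiment_config <- function(..., seed_base = 0) {
  experiment_config(
    train_window_s = 7200,
    train = train_config(runs = 5, epochs_max = 50, patience = 8,
                         seed_base = seed_base),
    deep = list(blocks = 2, filters_start = 8, lstm_units = 8),
    seed_base = seed_base, ...)
}

#' Approach label in the results naming scheme
#'
#' @param config an `experiment_config`.
#' @return E.g. `"Denoised Features_Chronological"`.
#' @export
approach_label <- function(config) {
  br <- if (config$branch == "denoised") "Denoised" else "Noisy"
  cl <- if (config$classifier == "deep_timeseries") "EEG" else "Features"
  rg <- if (config$regime == "chronological") "Chronological" else "Standard"
  paste0(br, " ", cl, "_", rg)
}

#' Preprocess a recording into labelled windows
#'
#' `preprocess_record()` performs the branch-independent stages: the
#' experimental-error mask is computed on the raw signal, then the
#' band-pass/notch filter is applied. `prepare_patient()` continues through
#' the branch's denoiser, discards postictal periods, segments into 10-s
#' windows and labels them under SOP/SPH; when both branches of one
#' recording are analysed, the `preprocess_record()` result can be shared.
#'
#' @param record an [eeg_record()] with onset annotations.
#' @param config an [experiment_config()].
#' @param pre optionally, the result of `preprocess_record()` for `record`.
#' @return `preprocess_record()`: list with `filtered` and `err_valid`;
#'   `prepare_patient()`: list with `ws` (windows), `labelled`, and
#'   preprocessing counts.
#' @export
preprocess_record <- function(record, config) {
  list(err_valid = remove_experimental_errors(record, config$flat_min_s,
                                              config$sat_frac, config$amp_max),
       filtered = frequency_filter(record))
}

#' @rdname preprocess_record
#' @export
prepare_patient <- function(record, config, pre = NULL) {
  if (is.null(pre)) pre <- preprocess_record(record, config)
  den <- if (config$branch == "denoised") config$denoiser else "identity"
  rec <- denoise(pre$filtered, den)
  validity <- pre$err_valid & discard_postictal(rec, config$postictal_s)
  ws <- segment(rec, validity)
  labelled <- label_windows(ws, rec$onsets, config$sop_s, config$sph_s)
  list(ws = ws, labelled = labelled,
       counts = list(windows_kept = n_windows(ws), windows_dropped = ws$n_dropped,
                     invalid_sample_frac = mean(!validity)))
}

# Build classifier inputs for a set of window rows. For the feature branch a
# cache maps window rows to feature-matrix rows so standard and
# chronological regimes never recompute a window.
input_builder <- function(ws, config) {
  if (config$classifier == "shallow_features") {
    cache <- new.env(parent = emptyenv())
    cache$rows <- integer(0)
    cache$X <- NULL
    fetch <- function(rows) {
      missing <- setdiff(rows, cache$rows)
      if (length(missing)) {
        Xm <- extract_features(ws, missing)
        cache$X <- rbind(cache$X, unclass(Xm)[, , drop = FALSE])
        cache$rows <- c(cache$rows, missing)
      }
      cache$X[match(rows, cache$rows), , drop = FALSE]
    }
    list(fetch = fetch, kind = "features")
  } else {
    L <- round(ws$window_s * ws$fs)
    nc <- n_channels(ws$record)
    fetch <- function(rows) {
      arr <- array(0, c(length(rows), L, nc))
      for (k in seq_along(rows)) arr[k, , ] <- window_data(ws, rows[k])
      arr
    }
    list(fetch = fetch, kind = "timeseries")
  }
}

fit_input_normaliser <- function(x) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    flat <- matrix(aperm(x, c(1, 2, 3)), d[1] * d[2], d[3])
    structure(list(mean = colMeans(flat), sd = apply(flat, 2, stats::sd),
                   n_fit = d[1], kind = "channels"),
              class = "zscore_normaliser")
  } else {
    zscore_fit(x)
  }
}

apply_input_normaliser <- function(norm, x) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    sd <- ifelse(norm$sd > 0, norm$sd, 1)
    for (ch in seq_len(d[3])) {
      x[, , ch] <- (x[, , ch] - norm$mean[ch]) / sd[ch]
    }
    x
  } else {
    zscore_apply(norm, x)
  }
}

build_model_spec <- function(config, builder_kind, ws) {
  if (builder_kind == "features") {
    shallow_spec(input_len = 55L * n_channels(ws$record),
                 hidden_neurons = config$hidden_neurons)
  } else {
    deep_spec(input_shape = c(round(ws$window_s * ws$fs), n_channels(ws$record)),
              blocks = config$deep$blocks,
              filters_start = config$deep$filters_start,
              lstm_units = config$deep$lstm_units)
  }
}

# Train an ensemble on the given training rows and predict the given test
# rows. Returns predictions plus an audit of what was trained on.
train_and_predict <- function(ws, labelled, builder, config, train_rows,
                              test_rows, round_seed) {
  lab <- labelled$label[train_rows]
  usable <- train_rows[lab >= 0]
  y <- labelled$label[usable]
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  ho <- holdout_split(y, config$holdout_ratio, seed = round_seed,
                      stratify = config$stratify)
  x_all <- builder$fetch(usable)
  x_tr <- slice_input(x_all, ho$train)
  norm <- fit_input_normaliser(x_tr)
  x_tr <- apply_input_normaliser(norm, x_tr)
  x_val <- apply_input_normaliser(norm, slice_input(x_all, ho$validation))
  spec <- build_model_spec(config, builder$kind, ws)
  tc <- config$train
  tc$seed_base <- tc$seed_base + round_seed
  ens <- train_ensemble(spec, x_tr, y[ho$train], x_val, y[ho$validation], tc)
  x_te <- apply_input_normaliser(norm, builder$fetch(test_rows))
  preds <- predict_windows(ens, x_te)
  list(preds = preds, ensemble = ens, normaliser = norm,
       epochs = vapply(ens$members, function(m) m$epochs_ran, 0L))
}

evaluate_predictions <- function(preds, labelled, test_rows, segments,
                                 test_onsets, config) {
  ps <- prediction_series(preds, labelled$timestamp[test_rows])
  fps <- firing_power(ps, config$tau)
  alarms <- raise_alarms(fps, config$threshold, config$refractory_s)
  cls <- classify_alarms(alarms, test_onsets, config$sop_s, config$sph_s)
  interictal_h <- sum(labelled$label[test_rows] == 0) * 10 / 3600
  surr <- surrogate_analysis(alarms, segments, test_onsets,
                             n_surrogates = config$n_surrogates,
                             seed = config$seed_base,
                             sop_s = config$sop_s, sph_s = config$sph_s,
                             method = config$surrogate_method)
  list(alarms = alarms, cls = cls, interictal_h = interictal_h, surr = surr,
       fps = fps)
}

#' Run the standard (train-once) regime for one patient
#'
#' Trains a single majority-vote ensemble on the chronologically first
#' seizures and evaluates firing-power alarms over every test seizure's
#' segment.
#'
#' @param record an [eeg_record()] with at least 3 annotated seizures.
#' @param config an [experiment_config()].
#' @param prep optionally, a precomputed [prepare_patient()] result.
#' @return An `eval_report`.
#' @export
run_standard <- function(record, config, prep = NULL) {
  if (is.null(prep)) prep <- prepare_patient(record, config)
  ws <- prep$ws
  labelled <- prep$labelled
  onsets <- record$onsets
  split <- chronological_split(onsets, config$train_fraction)
  tr_rows <- training_view(labelled, split, onsets, config$train_window_s)
  te <- test_view(labelled, split, onsets, config$postictal_s)
  builder <- input_builder(ws, config)
  tp <- train_and_predict(ws, labelled, builder, config, tr_rows, te$rows,
                          round_seed = config$seed_base)
  ev <- evaluate_predictions(tp$preds, labelled, te$rows, te$segments,
                             onsets[split$test], config)
  eval_report(length(split$test), ev$cls$n_true, ev$cls$n_false,
              ev$interictal_h, ev$surr,
              meta = list(approach = approach_label(config),
                          regime = "standard",
                          train_seizures = split$train,
                          test_seizures = split$test,
                          counts = prep$counts,
                          alarms = ev$alarms$alarm_times,
                          epochs = tp$epochs))
}

#' Run the chronological (periodically retrained) regime for one patient
#'
#' Iterates over test seizures in order: train an ensemble on the current
#' training seizures, evaluate on the next test seizure's segment, append
#' that seizure to the training set, re-partition and re-standardise, and
#' repeat. Data partitioning, holdout and normalisation are refitted at
#' every round; the report aggregates alarms over all test seizures. The
#' per-round training seizure sets are recorded in `meta$rounds` so leakage
#' audits can confirm a test seizure never contributed to the ensemble that
#' scored it.
#'
#' @inheritParams run_standard
#' @return An `eval_report`.
#' @export
run_chronological <- function(record, config, prep = NULL) {
  if (is.null(prep)) prep <- prepare_patient(record, config)
  ws <- prep$ws
  labelled <- prep$labelled
  onsets <- record$onsets
  split <- chronological_split(onsets, config$train_fraction)
  builder <- input_builder(ws, config)
  all_preds <- integer(0)
  all_rows <- integer(0)
  rounds <- list()
  epochs <- integer(0)
  current_train <- split$train
  for (k in split$test) {
    sub_split <- list(train = current_train, test = k)
    tr_rows <- training_view(labelled, sub_split, onsets, config$train_window_s)
    te_k <- test_view(labelled, list(test = k), onsets, config$postictal_s)
    round_seed <- config$seed_base + 1000 * length(rounds)
    tp <- train_and_predict(ws, labelled, builder, config, tr_rows,
                            te_k$rows, round_seed = round_seed)
    all_preds <- c(all_preds, tp$preds)
    all_rows <- c(all_rows, te_k$rows)
    epochs <- c(epochs, tp$epochs)
    rounds[[length(rounds) + 1]] <- list(test_seizure = k,
                                         train_seizures = current_train)
    current_train <- c(current_train, k)
  }
  te <- test_view(labelled, split, onsets, config$postictal_s)
  ev <- evaluate_predictions(all_preds, labelled, all_rows, te$segments,
                             onsets[split$test], config)
  eval_report(length(split$test), ev$cls$n_true, ev$cls$n_false,
              ev$interictal_h, ev$surr,
              meta = list(approach = approach_label(config),
                          regime = "chronological",
                          train_seizures = split$train,
                          test_seizures = split$test,
                          rounds = rounds,
                          counts = prep$counts,
                          alarms = ev$alarms$alarm_times,
                          epochs = epochs))
}

#' Run one patient under the configured regime
#'
#' @inheritParams run_standard
#' @return An `eval_report`.
#' @export
run_experiment <- function(record, config, prep = NULL) {
  if (config$regime == "chronological") run_chronological(record, config, prep)
  else run_standard(record, config, prep)
}

approach_families <- function() {
  list(
    list(family = "noisy_vs_denoised", dir_fpr = "b_less",
         pairs = list(c("Noisy EEG_Standard", "Denoised EEG_Standard"),
                      c("Noisy EEG_Chronological", "Denoised EEG_Chronological"),
                      c("Noisy Features_Standard", "Denoised Features_Standard"),
                      c("Noisy Features_Chronological", "Denoised Features_Chronological"))),
    list(family = "standard_vs_chronological", dir_fpr = "b_less",
         pairs = list(c("Denoised EEG_Standard", "Denoised EEG_Chronological"),
                      c("Noisy EEG_Standard", "Noisy EEG_Chronological"),
                      c("Denoised Features_Standard", "Denoised Features_Chronological"),
                      c("Noisy Features_Standard", "Noisy Features_Chronological"))),
    list(family = "deep_vs_shallow", dir_fpr = "b_greater",
         pairs = list(c("Denoised EEG_Standard", "Denoised Features_Standard"),
                      c("Denoised EEG_Chronological", "Denoised Features_Chronological"),
                      c("Noisy EEG_Standard", "Noisy Features_Standard"),
                      c("Noisy EEG_Chronological", "Noisy Features_Chronological"))))
}

#' Pairwise comparison of approaches across patients
#'
#' For every available pairing in the three comparison families (noisy vs
#' denoised, standard vs chronological, deep vs shallow), computes one-tailed
#' Mann-Whitney p-values across patients on seizure sensitivity (is group B
#' greater?) and FPR/h (is group B lower, except deep-vs-shallow where the
#' shallow group's FPR is tested as greater), plus above-chance counts.
#'
#' @param reports named list: approach label -> list of `eval_report`s, one
#'   per patient, aligned across approaches.
#' @return A data.frame with one row per pairing.
#' @export
compare_approaches <- function(reports) {
  if (length(reports) < 2) stopf("at least two approaches required")
  n_pat <- vapply(reports, length, 0L)
  if (length(unique(n_pat)) != 1) stopf("approaches cover different patient sets")
  sens <- lapply(reports, function(r) vapply(r, function(x) x$sensitivity, 0))
  fpr <- lapply(reports, function(r) vapply(r, function(x) x$fpr_per_h, 0))
  ac <- lapply(reports, function(r) sum(vapply(r, function(x) isTRUE(x$above_chance), TRUE)))
  out <- NULL
  for (fam in approach_families()) {
    for (p in fam$pairs) {
      if (!all(p %in% names(reports))) next
      a <- p[1]; b <- p[2]
      out <- rbind(out, data.frame(
        family = fam$family, group_a = a, group_b = b,
        p_sensitivity = mann_whitney_one_tailed(sens[[a]], sens[[b]],
                                                "b_greater"),
        p_fpr = mann_whitney_one_tailed(fpr[[a]], fpr[[b]], fam$dir_fpr),
        above_chance_a = ac[[a]], above_chance_b = ac[[b]]))
    }
  }
  out
}
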