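#!/usr/bin/env Rscript
# Preprocess patient A and extract the per-window feature matrix.
#
# Reports how much data each preprocessing stage removes and writes the
# labelled feature matrix of the training/test views to CSV.

suppressPackageStartupMessages(library(preictal))
dir.create("results", showWarnings = FALSE)

onsets <- c(7500, 23700, 39900, 56100)
cfg <- synth_config(duration = 56500, seizure_onsets = onsets,
                    n_channels = 2, preictal_effect = 0.7,
                    artefact_rates = list(blink = 120, muscle = 60,
                                          flatline = 1, saturation = 1),
                    seed = 101)
pat <- synth_patient(cfg)

ec <- desk_experiment_config(branch = "denoised", seed_base = 101)
prep <- prepare_patient(pat$record, ec)
cat(sprintf("windows kept %d, dropped %d (%.2f%% of samples invalid)\n",
            prep$counts$windows_kept, prep$counts$windows_dropped,
            100 * prep$counts$invalid_sample_frac))

lab <- prep$labelled
cat("label counts:", sprintf("interictal=%d preictal=%d discarded=%d",
                             sum(lab$label == 0), sum(lab$label == 1),
                             sum(lab$label == -1)), "\n")

split <- chronological_split(onsets, ec$train_fraction)
tr_rows <- training_view(lab, split, onsets, ec$train_window_s)
te <- test_view(lab, split, onsets, ec$postictal_s)
rows <- sort(union(tr_rows, te$rows))
cat(sprintf("extracting %d windows (%d training-view, %d test-view)\n",
            length(rows), length(tr_rows), length(te$rows)))

X <- extract_features(prep$ws, rows)
out <- data.frame(timestamp = attr(X, "timestamps"),
                  label = lab$label[rows],
                  seizure_index = lab$seizure_index[rows],
                  unclass(X), check.names = FALSE)
write.csv(out, "results/patient_A_features.csv", row.names = FALSE)
cat(sprintf("wrote results/patient_A_features.csv: %d windows x %d features\n",
            nrow(X), ncol(X)))
cat("first feature names:", paste(head(feature_names(), 8), collapse = ", "),
    "...\n")
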