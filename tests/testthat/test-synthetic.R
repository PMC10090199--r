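# The synthetic EEG generator: configuration invariants, determinism, the
# planted preictal signature, artefact injection, and concept drift.

test_that("configuration invariants are enforced", {
  expect_error(synth_config(40000, c(10000, 20000)), "16200")
  expect_error(synth_config(40000, c(20000, 10000)), "increasing")
  expect_error(synth_config(30000, c(10000, 40000)), "duration")
  expect_error(synth_config(40000, c(0, 16200), preictal_len = 16000),
               "preictal_len")
  cfg <- synth_config(600, numeric(0), n_channels = 2, seed = 1)
  expect_s3_class(cfg, "synth_config")
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- synth_config(120, numeric(0), n_channels = 2, seed = 9)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1$record$signal, g2$record$signal)
  g3 <- generate_recording(synth_config(120, numeric(0), n_channels = 2, seed = 10))
  expect_false(identical(g1$record$signal, g3$record$signal))
})

test_that("the preictal mask covers exactly [onset - 2400, onset - 600)", {
  cfg <- synth_config(7200, 7000, n_channels = 1, preictal_effect = 0.5, seed = 2)
  g <- generate_recording(cfg)
  fs <- 256
  idx <- which(g$truth$preictal_mask)
  expect_equal(min(idx), floor((7000 - 2400) * fs) + 1)
  expect_equal(max(idx) / fs, 7000 - 600, tolerance = 1e-3)
  expect_length(g$truth$preictal_mask, n_samples(g$record))
})

test_that("with no planted effect, preictal and interictal spectra are indistinguishable", {
  cfg <- synth_config(7200, 7000, n_channels = 1, preictal_effect = 0, seed = 3)
  g <- generate_recording(cfg)
  rel_theta <- function(seg) {
    sp <- stats::spec.pgram(seg, taper = 0, plot = FALSE)
    f <- sp$freq * 256
    sum(sp$spec[f >= 4 & f < 8]) / sum(sp$spec[f >= 0.5 & f < 90])
  }
  fs <- 256
  pre <- vapply(0:5, function(k) rel_theta(g$record$signal[(4600 + 300 * k) * fs + 1:(300 * fs), 1]), 0)
  inter <- vapply(0:5, function(k) rel_theta(g$record$signal[(600 + 300 * k) * fs + 1:(300 * fs), 1]), 0)
  p <- stats::wilcox.test(pre, inter)$p.value
  expect_gt(p, 0.01)
})

test_that("the planted band-power shift is recoverable by an independent periodogram", {
  eff <- 0.5
  cfg <- synth_config(7200, 7000, n_channels = 1, preictal_effect = eff, seed = 4)
  g <- generate_recording(cfg)
  fs <- 256
  rel_theta_win <- function(start_s) {
    seg <- g$record$signal[start_s * fs + 1:(10 * fs), 1]
    sp <- stats::spec.pgram(seg, taper = 0, plot = FALSE, detrend = TRUE)
    f <- sp$freq * fs
    sum(sp$spec[f >= 4 & f < 8]) / sum(sp$spec[f >= 0.5 & f < 90])
  }
  pre_w <- vapply(seq(4600, 6380, 10), rel_theta_win, 0)
  int_w <- vapply(seq(600, 2380, 10), rel_theta_win, 0)
  # planted windows are separable: threshold-free AUC from the rank sum
  w <- stats::wilcox.test(pre_w, int_w)$statistic
  auc <- w / (length(pre_w) * length(int_w))
  expect_gt(auc, 0.9)
  # the mean shift direction and a coarse magnitude check: theta amplitude
  # scaled by (1 + eff) raises mean relative theta noticeably
  expect_gt(mean(pre_w), mean(int_w) * 1.2)
})

test_that("artefact rates follow the Poisson law and masks match events", {
  cfg <- synth_config(3600, numeric(0), n_channels = 2,
                      artefact_rates = list(blink = 120), seed = 5)
  g <- generate_recording(cfg)
  out <- inject_artefacts(g$record, g$truth, cfg)
  n_blink <- sum(out$truth$events$type == "blink")
  expect_gt(n_blink, 120 - 3 * sqrt(120))
  expect_lt(n_blink, 120 + 3 * sqrt(120))
  # masks cover every event span on the affected (frontal) channels
  ev <- out$truth$events[1, ]
  fs <- 256
  span <- floor(ev$time * fs) + seq_len(round(ev$duration * fs))
  expect_true(all(out$truth$artefact_mask[span, 1]))
  # number of distinct masked components matches the event count (blinks
  # can merge when overlapping, so the component count is at most n_blink)
  comp <- sum(diff(c(FALSE, out$truth$artefact_mask[, 1])) == 1)
  expect_lte(comp, n_blink)
  expect_gt(comp, 0.7 * n_blink)
})

test_that("zero artefact rates leave the recording untouched", {
  cfg <- synth_config(300, numeric(0), n_channels = 2, seed = 6)
  g <- generate_recording(cfg)
  out <- inject_artefacts(g$record, g$truth, cfg)
  expect_identical(out$record$signal, g$record$signal)
  expect_false(any(out$truth$artefact_mask))
  expect_equal(nrow(out$truth$events), 0)
})

test_that("per-type seed streams are independent", {
  base <- synth_config(3600, numeric(0), n_channels = 2,
                       artefact_rates = list(blink = 30), seed = 7)
  both <- synth_config(3600, numeric(0), n_channels = 2,
                       artefact_rates = list(blink = 30, muscle = 20), seed = 7)
  g <- generate_recording(base)
  e1 <- inject_artefacts(g$record, g$truth, base)$truth$events
  e2 <- inject_artefacts(g$record, g$truth, both)$truth$events
  expect_equal(e1$time[e1$type == "blink"], e2$time[e2$type == "blink"])
})

test_that("flatline injection produces runs of identical samples where masked", {
  cfg <- synth_config(1800, numeric(0), n_channels = 2,
                      artefact_rates = list(flatline = 6), seed = 8)
  g <- generate_recording(cfg)
  out <- inject_artefacts(g$record, g$truth, cfg)
  ev <- out$truth$events[out$truth$events$type == "flatline", ][1, ]
  fs <- 256
  span <- floor(ev$time * fs) + seq_len(round(ev$duration * fs))
  expect_gte(length(span), fs)  # at least 1 s
  expect_equal(diff(out$record$signal[span, 1]), rep(0, length(span) - 1))
})

test_that("concept drift is deterministic, identity at zero, monotone in rate", {
  cfg0 <- synth_config(7200, numeric(0), n_channels = 1, seed = 11)
  g <- generate_recording(cfg0)
  expect_identical(apply_concept_drift(g$record, cfg0)$signal, g$record$signal)

  alpha_power <- function(sig, from_s, to_s) {
    fs <- 256
    seg <- sig[(from_s * fs + 1):(to_s * fs), 1]
    sp <- stats::spec.pgram(seg, taper = 0, plot = FALSE)
    f <- sp$freq * fs
    sum(sp$spec[f >= 8 & f < 13])
  }
  drifted <- list()
  for (dr in c(0.05, 0.2)) {
    cfg <- synth_config(7200, numeric(0), n_channels = 1, drift_rate = dr, seed = 11)
    d <- apply_concept_drift(g$record, cfg)
    drifted[[as.character(dr)]] <-
      alpha_power(d$signal, 5400, 7200) / alpha_power(d$signal, 0, 1800)
  }
  base_ratio <- alpha_power(g$record$signal, 5400, 7200) /
    alpha_power(g$record$signal, 0, 1800)
  # last-hour alpha declines relative to the first hour, more so at the
  # higher drift rate
  expect_lt(drifted[["0.05"]], base_ratio)
  expect_lt(drifted[["0.2"]], drifted[["0.05"]])
  # drift is a deterministic transform of the configuration
  cfg <- synth_config(7200, numeric(0), n_channels = 1, drift_rate = 0.1, seed = 11)
  expect_identical(apply_concept_drift(g$record, cfg)$signal,
                   apply_concept_drift(g$record, cfg)$signal)
})

test_that("EDF round trip preserves the signal to quantisation accuracy", {
  cfg <- synth_config(20, numeric(0), n_channels = 3, seed = 12)
  g <- generate_recording(cfg)
  tmp <- tempfile(fileext = ".edf")
  write_edf(g$record, tmp)
  back <- read_edf(tmp)
  expect_equal(dim(back$signal), dim(g$record$signal))
  qstep <- max(abs(g$record$signal)) / 32767
  expect_lt(max(abs(back$signal - g$record$signal)), qstep)
  expect_equal(back$fs, 256)
  unlink(tmp)
})

test_that("annotation CSV round trip", {
  tmp <- tempfile(fileext = ".csv")
  write_annotations(c(7500, 23700), tmp)
  ann <- read_annotations(tmp)
  expect_equal(ann$onset_seconds, c(7500, 23700))
  expect_true(all(ann$label == "seizure_onset"))
  unlink(tmp)
})
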