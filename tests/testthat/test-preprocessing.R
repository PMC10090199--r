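# Filtering, experimental-error masking, postictal discarding, denoising,
# and 10-second windowing.

test_that("the band-pass/notch cascade attenuates where it should", {
  fs <- 256
  # 50 Hz mains component: attenuated by at least 20 dB
  rec50 <- make_record(40, fs, list(function(t) sin(2 * pi * 50 * t)))
  out50 <- frequency_filter(rec50)
  mid <- (10 * fs):(30 * fs)  # avoid boundary transients
  expect_lt(20 * log10(rms(out50$signal[mid, 1]) / rms(rec50$signal[mid, 1])),
            -20)
  # 10 Hz passband component: within 1 dB
  rec10 <- make_record(40, fs, list(function(t) sin(2 * pi * 10 * t)))
  out10 <- frequency_filter(rec10)
  expect_lt(abs(20 * log10(rms(out10$signal[mid, 1]) / rms(rec10$signal[mid, 1]))),
            1)
  # DC offset removed by the 0.5 Hz high-pass edge
  recdc <- make_record(40, fs, list(function(t) rep(100, length(t)) + sin(2 * pi * 10 * t)))
  outdc <- frequency_filter(recdc)
  expect_lt(abs(mean(outdc$signal[mid, 1])), 1)
  # shape preserved
  expect_equal(dim(out50$signal), dim(rec50$signal))
})

test_that("filtering rejects sampling rates with the band edge at Nyquist", {
  rec <- eeg_record(matrix(rnorm(1000), ncol = 1), fs = 200)
  expect_error(frequency_filter(rec), "Nyquist")
})

test_that("filtering is idempotent in the passband within tolerance", {
  fs <- 256
  rec <- make_record(40, fs, list(function(t) sin(2 * pi * 12 * t)))
  once <- frequency_filter(rec)
  twice <- frequency_filter(once)
  mid <- (10 * fs):(30 * fs)
  expect_equal(rms(twice$signal[mid, 1]), rms(once$signal[mid, 1]),
               tolerance = 0.02)
})

test_that("experimental-error masking flags flatlines, clipping and spikes", {
  fs <- 256
  # a clean sinusoid is fully valid
  rec <- make_record(30, fs, list(function(t) 50 * sin(2 * pi * 7 * t)))
  expect_true(all(remove_experimental_errors(rec)))

  # a 2-s constant stretch is invalid under flat_min_s = 1
  sig <- 50 * sin(2 * pi * 7 * (0:(30 * fs - 1)) / fs)
  sig[(10 * fs):(12 * fs)] <- sig[10 * fs]
  recf <- eeg_record(matrix(sig, ncol = 1), fs)
  v <- remove_experimental_errors(recf, flat_min_s = 1)
  expect_true(all(!v[(10 * fs + 10):(12 * fs - 10)]))
  expect_true(all(v[1:(9 * fs)]))

  # amplitudes beyond amp_max are invalid
  sig2 <- 50 * sin(2 * pi * 7 * (0:(30 * fs - 1)) / fs)
  sig2[5000] <- 900
  reca <- eeg_record(matrix(sig2, ncol = 1), fs)
  va <- remove_experimental_errors(reca, amp_max = 500)
  expect_false(va[5000])
})

test_that("masking recovers the generator's injected flatlines and saturation", {
  cfg <- synth_config(1800, numeric(0), n_channels = 2,
                      artefact_rates = list(flatline = 8, saturation = 6),
                      seed = 31)
  p <- synth_patient(cfg)
  valid <- remove_experimental_errors(p$record)
  fs <- p$record$fs
  ev <- p$truth$events
  for (i in seq_len(nrow(ev))) {
    span <- floor(ev$time[i] * fs) + seq_len(round(ev$duration[i] * fs))
    span <- span[-c(1:8, (length(span) - 8):length(span))]  # interior
    expect_true(all(!valid[span]),
                label = sprintf("%s at %.1f s masked", ev$type[i], ev$time[i]))
  }
  # nearly everything outside events stays valid
  ev_mask <- rep(FALSE, n_samples(p$record))
  for (i in seq_len(nrow(ev))) {
    span <- floor(ev$time[i] * fs) + seq_len(round(ev$duration[i] * fs) + fs)
    ev_mask[span[span <= length(ev_mask)]] <- TRUE
  }
  expect_gt(mean(valid[!ev_mask]), 0.999)
})

test_that("postictal discard invalidates 30 minutes after each onset", {
  fs <- 256
  rec <- make_record(40, fs, list(function(t) sin(t)))
  expect_true(all(discard_postictal(rec)))

  sig <- matrix(rnorm(6000 * fs), ncol = 1)
  rec1 <- eeg_record(sig, fs, onsets = 3600)
  v <- discard_postictal(rec1)
  expect_true(all(!v[(3600 * fs + 1):(5400 * fs)]))
  expect_true(all(v[1:(3600 * fs)]))
  expect_true(all(v[(5400 * fs + 2):(6000 * fs)]))
})

test_that("two onsets 4 h 30 min apart leave two disjoint postictal gaps", {
  fs <- 32  # coarse rate keeps this fixture small
  n <- 36000 * fs
  rec <- eeg_record(matrix(0, n, 1), fs, onsets = c(10000, 26200))
  v <- discard_postictal(rec)
  inv <- true_runs_test(!v)
  expect_equal(nrow(inv), 2)
  expect_equal(inv$start, c(10000 * fs + 1, 26200 * fs + 1))
})

test_that("denoiser registry dispatches and validates", {
  rec <- make_record(10, 256, list(function(t) sin(2 * pi * 5 * t)))
  expect_identical(denoise(rec, "identity")$signal, rec$signal)
  expect_error(denoise(rec, "no_such_model"), "unknown denoiser")
  register_denoiser(new_denoiser("halve", function(r) {
    r$signal <- r$signal / 2
    r
  }))
  expect_equal(denoise(rec, "halve")$signal, rec$signal / 2)
})

test_that("the default denoiser reduces blink error and spares clean data", {
  cfg <- synth_config(1200, numeric(0), n_channels = 4,
                      artefact_rates = list(blink = 120, muscle = 40),
                      seed = 32)
  p <- synth_patient(cfg)
  noisy_err <- rms(p$record$signal - p$truth$clean_signal)
  den <- denoise(p$record, "default")
  den_err <- rms(den$signal - p$truth$clean_signal)
  expect_lt(den_err, noisy_err)

  clean_cfg <- synth_config(1200, numeric(0), n_channels = 4, seed = 33)
  cp <- synth_patient(clean_cfg)
  cden <- denoise(cp$record, "default")
  expect_lt(rms(cden$signal - cp$record$signal), 0.1 * rms(cp$record$signal))
})

test_that("segmentation drops windows spanning invalid samples and flags gaps", {
  fs <- 256
  rec <- make_record(60, fs, list(function(t) sin(2 * pi * 9 * t)))
  ws <- segment(rec)
  expect_equal(n_windows(ws), 6)
  expect_equal(ws$timestamps, seq(0, 50, 10))
  expect_equal(ws$contiguous_with_previous, c(FALSE, rep(TRUE, 5)))
  expect_equal(dim(window_data(ws, 1)), c(2560, 1))

  # a 300-s record with samples invalid during [250, 255) s
  rec2 <- make_record(300, fs, list(function(t) sin(2 * pi * 9 * t)))
  validity <- rep(TRUE, n_samples(rec2))
  validity[(250 * fs + 1):(255 * fs)] <- FALSE
  ws2 <- segment(rec2, validity)
  expect_false(250 %in% ws2$timestamps)
  expect_true(all(seq(0, 240, 10) %in% ws2$timestamps))
  expect_true(260 %in% ws2$timestamps)
  expect_false(ws2$contiguous_with_previous[ws2$timestamps == 260])

  # empty record
  ws0 <- segment(eeg_record(matrix(0, 0, 1), fs))
  expect_equal(n_windows(ws0), 0)
})

test_that("emitted plus dropped windows cover every aligned slot exactly once", {
  withr::local_seed(422)
  fs <- 256
  rec <- make_record(200, fs, list(function(t) rnorm(length(t))))
  validity <- runif(n_samples(rec)) > 0.0005
  ws <- segment(rec, validity)
  expect_equal(n_windows(ws) + ws$n_dropped, floor(n_samples(rec) / (10 * fs)))
  expect_false(any(duplicated(ws$timestamps)))
})

test_that("a partial trailing window is dropped", {
  rec <- make_record(25, 256, list(function(t) sin(t)))
  ws <- segment(rec)
  expect_equal(n_windows(ws), 2)
})
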