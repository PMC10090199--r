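# The 55 univariate features per channel: moments, Hjorth, decorrelation
# time, spectral features, wavelet energies, and the assembled vectors.

test_that("moment features match closed forms and the e1071 estimators", {
  m <- moments(c(1, 1, 1, 1))
  expect_equal(unname(m), c(1, 0, 0, 0, 1))

  x <- rep(c(-1, 1), 128)
  m <- moments(x)
  expect_equal(m[["mean"]], 0)
  expect_equal(m[["variance"]], stats::var(x))
  expect_equal(m[["norm_mean_intensity"]], 1)

  skip_if_not_installed("e1071")
  withr::local_seed(403)
  for (i in 1:5) {
    y <- rnorm(500)^2 + rnorm(500)
    m <- moments(y)
    expect_equal(m[["skewness"]], e1071::skewness(y, type = 1))
    expect_equal(m[["kurtosis"]], e1071::kurtosis(y, type = 1))
  }
})

test_that("Gaussian windows have near-zero skewness and excess kurtosis", {
  withr::local_seed(404)
  n <- 2560
  x <- rnorm(n)
  m <- moments(x)
  expect_lt(abs(m[["skewness"]]), 3 * sqrt(6 / n))
  expect_lt(abs(m[["kurtosis"]]), 3 * sqrt(24 / n))
})

test_that("Hjorth parameters match analytic values", {
  withr::local_seed(405)
  # white noise: var(diff) = 2 var(x) so mobility ~ sqrt(2)
  x <- rnorm(20000)
  h <- hjorth(x)
  expect_equal(h[["mobility"]], sqrt(2), tolerance = 0.02)
  # pure sinusoid: mobility of first difference = 2 sin(pi f / fs)
  fs <- 256
  t <- (0:2559) / fs
  s <- sin(2 * pi * 8 * t)
  expect_equal(hjorth(s)[["mobility"]], 2 * sin(pi * 8 / fs), tolerance = 1e-3)
  # degenerate constant window
  expect_equal(unname(hjorth(rep(2, 100))), c(0, 0))
})

test_that("decorrelation time finds the first autocorrelation zero crossing", {
  withr::local_seed(406)
  fs <- 256
  # white noise decorrelates at the first lag
  expect_equal(decorrelation_time(rnorm(2560), fs), 1 / fs)
  # 10 Hz sinusoid: cosine autocorrelation crosses zero at a quarter period
  t <- (0:2559) / fs
  expect_equal(decorrelation_time(sin(2 * pi * 10 * t), fs), 0.025,
               tolerance = 0.2)  # quantised to the 1/fs lag grid
  # constant signal never crosses: maximum searched lag
  expect_equal(decorrelation_time(rep(1, 100), fs), 99 / fs)
})

test_that("spectral features of a pure sinusoid concentrate in its band", {
  fs <- 256
  t <- (0:2559) / fs
  bp <- band_powers(sin(2 * pi * 10 * t), fs)
  expect_gt(bp$relative[["alpha"]], 0.95)
  expect_equal(bp$alpha_peak_freq, 10, tolerance = 0.5)
  expect_equal(unname(bp$sef[["sef50"]]), 10, tolerance = 0.5)
  expect_equal(sum(bp$absolute), bp$total_power)
})

test_that("white-noise relative band powers are proportional to bandwidth", {
  withr::local_seed(407)
  fs <- 256
  acc <- numeric(6)
  for (i in 1:20) {
    bp <- band_powers(rnorm(2560), fs)
    acc <- acc + bp$relative
  }
  rel <- acc / 20
  # flat spectrum: each relative power ~ bandwidth / total covered bandwidth
  widths <- c(3.5, 4, 5, 17, 17, 22)
  expect_equal(unname(rel), widths / 83.5, tolerance = 0.1)
})

test_that("stored relative powers plus the derived gamma-3 share sum to one", {
  withr::local_seed(408)
  bp <- band_powers(rnorm(2560), 256)
  rel7 <- sum(bp$relative) + bp$absolute[["gamma3"]] / bp$total_power
  expect_equal(unname(rel7), 1, tolerance = 1e-12)
})

test_that("band-power ratios follow their definition and degenerate safely", {
  fs <- 256
  t <- (0:2559) / fs
  bp <- band_powers(sin(2 * pi * 10 * t), fs)
  expect_equal(unname(bp$ratios[["delta/theta"]]),
               unname(bp$absolute[["delta"]] / bp$absolute[["theta"]]))
  z <- band_powers(rep(0, 2560), fs)
  expect_true(all(z$relative == 0))
  expect_true(all(z$ratios == 0))
})

test_that("one DWT step conserves energy (orthogonal periodised transform)", {
  withr::local_seed(409)
  x <- rnorm(256)
  st <- preictal:::dwt_step_periodic(matrix(x, ncol = 1),
                                     preictal:::db4_lo,
                                     rev(preictal:::db4_lo) * (-1)^(0:7))
  expect_equal(sum(st$approx^2) + sum(st$detail^2), sum(x^2), tolerance = 1e-9)
})

test_that("wavelet detail energies behave on canonical signals", {
  # constants live entirely in the approximation
  expect_equal(unname(wavelet_energies(rep(3, 256))), rep(0, 5))
  # the fastest alternation loads the first detail level
  alt <- rep(c(1, -1), 512)
  e <- wavelet_energies(alt)
  expect_gt(e[["wavelet_d1"]], 0.9)
  # bounds: each in [0,1], details sum to at most 1
  withr::local_seed(410)
  e2 <- wavelet_energies(rnorm(2560))
  expect_true(all(e2 >= 0 & e2 <= 1))
  expect_lte(sum(e2), 1)
})

test_that("feature vectors have the documented composition", {
  expect_length(feature_names(), 55)
  expect_false(any(duplicated(feature_names())))

  rec <- make_record(30, channels = rep(list(function(t) sin(2 * pi * 10 * t) + 0.1 * cos(2 * pi * 3 * t)), 19))
  ws <- segment(rec)
  X <- extract_features(ws)
  expect_equal(ncol(X), 1045)

  rec1 <- make_record(30, channels = list(function(t) sin(2 * pi * 7 * t)))
  X1 <- extract_features(segment(rec1))
  expect_equal(ncol(X1), 55)
})

test_that("extraction is deterministic and finite", {
  withr::local_seed(411)
  sig <- matrix(rnorm(2560 * 3 * 2), 2560 * 3, 2)
  rec <- eeg_record(sig, 256)
  ws <- segment(rec)
  X1 <- extract_features(ws)
  X2 <- extract_features(ws)
  expect_identical(unclass(X1), unclass(X2))
  expect_true(all(is.finite(X1)))
})

test_that("channel permutation permutes feature blocks accordingly", {
  withr::local_seed(412)
  sig <- matrix(rnorm(2560 * 2), 2560, 2)
  rec_ab <- eeg_record(sig, 256, c("a", "b"))
  rec_ba <- eeg_record(sig[, 2:1], 256, c("b", "a"))
  Xab <- extract_features(segment(rec_ab))
  Xba <- extract_features(segment(rec_ba))
  expect_equal(unname(Xab[1, 1:55]), unname(Xba[1, 56:110]))
  expect_equal(unname(Xab[1, 56:110]), unname(Xba[1, 1:55]))
})

test_that("batched and single-window extraction agree", {
  withr::local_seed(413)
  sig <- matrix(rnorm(2560 * 5), 2560 * 5, 1)
  rec <- eeg_record(sig, 256)
  ws <- segment(rec)
  Xall <- extract_features(ws, batch_size = 2)
  Xone <- extract_features(ws, indices = 3)
  expect_equal(unname(Xall[3, ]), unname(Xone[1, ]))
})
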