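# 55 univariate linear features per channel per 10-s window:
# 5 statistical moments, 2 Hjorth parameters (activity is the variance,
# already counted), decorrelation time, 7 absolute band powers, 6 relative
# band powers (gamma-3 relative omitted as linearly redundant), 21 pairwise
# band-power ratios, total power, spectral edge frequency and power at
# 50/75/90%, alpha peak frequency, and 5 relative wavelet detail energies
# (Daubechies-4, five decomposition levels).

eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma1 = c(30, 47), gamma2 = c(53, 75),
       gamma3 = c(75, 90))
}

#' Names of the 55 per-channel features
#'
#' @return Character vector of length 55; order matches the extraction.
#' @export
feature_names <- function() {
  bands <- names(eeg_bands())
  pairs <- utils::combn(bands, 2)
  c("mean", "variance", "skewness", "kurtosis", "norm_mean_intensity",
    "hjorth_mobility", "hjorth_complexity", "decorrelation_time",
    paste0("pow_", bands), paste0("rel_", bands[1:6]),
    paste0("ratio_", pairs[1, ], "_", pairs[2, ]),
    "total_power", "sef50", "sef75", "sef90", "sep50", "sep75", "sep90",
    "alpha_peak_freq", paste0("wavelet_d", 1:5))
}

#' Statistical moment features of one window
#'
#' Sample mean, sample (n-1) variance, skewness and excess kurtosis (moment
#' estimators; 0 by convention on constant signals), and the normalised mean
#' intensity `mean(|x|)/max(|x|)` (0 on an all-zero window).
#'
#' @param x numeric vector of samples.
#' @return Named numeric vector of length 5.
#' @export
moments <- function(x) {
  stopifnot(length(x) >= 2)
  m <- .moment_block(matrix(x, ncol = 1))
  stats::setNames(m[, 1], c("mean", "variance", "skewness", "kurtosis",
                            "norm_mean_intensity"))
}

.moment_block <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  m2 <- colMeans(xc^2)
  m3 <- colMeans(xc^3)
  m4 <- colMeans(xc^4)
  v <- m2 * n / (n - 1)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  mx <- apply(abs(X), 2, max)
  nmi <- ifelse(mx > 0, colMeans(abs(X)) / mx, 0)
  rbind(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
        norm_mean_intensity = nmi)
}

#' Hjorth mobility and complexity of one window
#'
#' `mobility = sd(diff(x)) / sd(x)`; `complexity = mobility(diff(x)) /
#' mobility(x)`. Hjorth activity is the variance, reported among the moment
#' features. Both are 0 by convention when the needed variance vanishes.
#'
#' @param x numeric vector of samples (at least 3).
#' @return Named numeric vector `c(mobility, complexity)`.
#' @export
hjorth <- function(x) {
  stopifnot(length(x) >= 3)
  h <- .hjorth_block(matrix(x, ncol = 1))
  stats::setNames(h[, 1], c("mobility", "complexity"))
}

col_var <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  (colSums(M * M) - n * mu^2) / (n - 1)
}

.hjorth_block <- function(X) {
  v0 <- col_var(X)
  D1 <- diff(X)
  v1 <- col_var(D1)
  v2 <- col_var(diff(D1))
  mob <- ifelse(v0 > 0, sqrt(v1 / v0), 0)
  mob_d <- ifelse(v1 > 0, sqrt(v2 / v1), 0)
  comp <- ifelse(mob > 0, mob_d / mob, 0)
  rbind(mobility = mob, complexity = comp)
}

#' Decorrelation time of one window
#'
#' Lag, in seconds, of the first zero crossing of the sample autocorrelation
#' function; when no crossing occurs within the window (including the
#' degenerate constant case), the maximum searched lag `(n - 1)/fs`.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @return Decorrelation time in seconds.
#' @export
decorrelation_time <- function(x, fs) {
  stopifnot(length(x) >= 2)
  .decorr_block(matrix(x, ncol = 1), fs)[1]
}

.decorr_block <- function(X, fs) {
  n <- nrow(X)
  nc <- ncol(X)
  xc <- sweep(X, 2, colMeans(X))
  M <- stats::nextn(2 * n - 1, c(2, 3, 5))
  P <- rbind(xc, matrix(0, M - n, nc))
  F <- stats::mvfft(P)
  ac <- Re(stats::mvfft(F * Conj(F), inverse = TRUE))[seq_len(n), , drop = FALSE] / M
  vapply(seq_len(nc), function(j) {
    a <- ac[, j]
    if (a[1] <= 0) return((n - 1) / fs)
    k <- which(a <= 0)[1]
    if (is.na(k)) (n - 1) / fs else (k - 1) / fs
  }, 0)
}

# Welch power spectral density, one-sided, averaged modified periodogram
# with seg_s-second Hann segments at 50% overlap. Returns freqs and a
# (n_freq x n_channels) PSD matrix.
welch_psd <- function(X, fs, seg_s = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  nc <- ncol(X)
  seg <- round(seg_s * fs)
  hop <- seg %/% 2
  if (n < seg) stopf("window too short for %g-s Welch segments", seg_s)
  n_seg <- (n - seg) %/% hop + 1
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  idx <- outer(seq_len(seg), (seq_len(n_seg) - 1) * hop, "+")
  big <- matrix(0, seg, n_seg * nc)
  for (ch in seq_len(nc)) {
    S <- matrix(X[idx + (ch - 1) * n], seg, n_seg)
    S <- sweep(S, 2, colMeans(S))
    big[, ((ch - 1) * n_seg + 1):(ch * n_seg)] <- S * w
  }
  F <- stats::mvfft(big)
  nf <- seg %/% 2 + 1
  P <- abs(F[seq_len(nf), , drop = FALSE])^2 / (fs * sum(w^2))
  P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
  psd <- matrix(0, nf, nc)
  for (ch in seq_len(nc)) {
    psd[, ch] <- rowMeans(P[, ((ch - 1) * n_seg + 1):(ch * n_seg), drop = FALSE])
  }
  list(freq = (seq_len(nf) - 1) * fs / seg, psd = psd)
}

#' Spectral features of one window
#'
#' Power spectral density is estimated by an averaged modified periodogram
#' (2-s Hann segments, 50% overlap). Reported are the 7 absolute band powers
#' (delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma1 30-47, gamma2
#' 53-75, gamma3 75-90 Hz), the first 6 relative band powers, the 21 pairwise
#' band-power ratios (band i over band j, i < j), the total power (sum of the
#' 7 absolute powers), spectral edge frequency and spectral edge power at
#' 50/75/90% of the cumulative 0.5-90 Hz power, and the alpha peak frequency
#' (argmax of the PSD within 8-13 Hz). Relative powers and ratios are 0 by
#' convention when their denominator vanishes.
#'
#' @param x numeric vector, one 10-s window of one channel.
#' @param fs sampling rate in Hz.
#' @return A list with elements `absolute`, `relative`, `ratios`,
#'   `total_power`, `sef`, `sep`, `alpha_peak_freq`.
#' @export
band_powers <- function(x, fs) {
  f <- .spectral_block(matrix(x, ncol = 1), fs)[, 1]
  bands <- names(eeg_bands())
  pairs <- utils::combn(bands, 2)
  list(absolute = stats::setNames(f[1:7], bands),
       relative = stats::setNames(f[8:13], bands[1:6]),
       ratios = stats::setNames(f[14:34], paste0(pairs[1, ], "/", pairs[2, ])),
       total_power = f[[35]],
       sef = stats::setNames(f[36:38], c("sef50", "sef75", "sef90")),
       sep = stats::setNames(f[39:41], c("sep50", "sep75", "sep90")),
       alpha_peak_freq = f[[42]])
}

# 42 spectral features per channel, as a (42 x nc) matrix.
.spectral_block <- function(X, fs) {
  W <- welch_psd(X, fs)
  freq <- W$freq
  df <- freq[2] - freq[1]
  bands <- eeg_bands()
  nb <- length(bands)
  nc <- ncol(W$psd)
  absp <- matrix(0, nb, nc)
  for (b in seq_len(nb)) {
    sel <- freq >= bands[[b]][1] & freq < bands[[b]][2]
    absp[b, ] <- colSums(W$psd[sel, , drop = FALSE]) * df
  }
  total <- colSums(absp)
  rel <- sweep(absp[1:6, , drop = FALSE], 2, ifelse(total > 0, total, 1), "/")
  rel[, total == 0] <- 0
  pairs <- utils::combn(nb, 2)
  ratios <- matrix(0, ncol(pairs), nc)
  for (p in seq_len(ncol(pairs))) {
    den <- absp[pairs[2, p], ]
    ratios[p, ] <- ifelse(den > 0, absp[pairs[1, p], ] / den, 0)
  }
  sel_all <- freq >= 0.5 & freq <= 90
  fr <- freq[sel_all]
  cum <- apply(W$psd[sel_all, , drop = FALSE] * df, 2, cumsum)
  sef <- matrix(0, 3, nc)
  sep <- matrix(0, 3, nc)
  qs <- c(0.5, 0.75, 0.9)
  for (ch in seq_len(nc)) {
    tot <- cum[nrow(cum), ch]
    for (qi in 1:3) {
      if (tot > 0) {
        k <- which(cum[, ch] >= qs[qi] * tot)[1]
        sef[qi, ch] <- fr[k]
        sep[qi, ch] <- cum[k, ch]
      }
    }
  }
  sel_a <- freq >= 8 & freq <= 13
  apk <- vapply(seq_len(nc), function(ch) {
    p <- W$psd[sel_a, ch]
    if (all(p == 0)) 0 else freq[sel_a][which.max(p)]
  }, 0)
  rbind(absp, rel, ratios, total, sef, sep, apk)
}

# ---- Wavelet features -----------------------------------------------------

# Daubechies-4 (8-tap) scaling filter; the wavelet filter is its quadrature
# mirror. Periodised decomposition keeps the transform orthogonal.
db4_lo <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

.dwt_idx_cache <- new.env(parent = emptyenv())

dwt_tap_indices <- function(n, k) {
  key <- paste0(n, "_", k)
  if (!exists(key, envir = .dwt_idx_cache)) {
    idx0 <- 2 * (seq_len(n %/% 2) - 1)
    assign(key, lapply(seq_len(k), function(m) (idx0 + m - 1) %% n + 1L),
           envir = .dwt_idx_cache)
  }
  get(key, envir = .dwt_idx_cache)
}

# One periodised analysis step on a (samples x channels) matrix.
dwt_step_periodic <- function(X, lo, hi) {
  X <- as.matrix(X)
  n <- nrow(X)
  half <- n %/% 2
  idx <- dwt_tap_indices(n, length(lo))
  a <- matrix(0, half, ncol(X))
  d <- matrix(0, half, ncol(X))
  for (m in seq_along(lo)) {
    xi <- X[idx[[m]], , drop = FALSE]
    a <- a + lo[m] * xi
    d <- d + hi[m] * xi
  }
  list(approx = a, detail = d)
}

#' Relative wavelet detail energies of one window
#'
#' Five-level discrete wavelet decomposition with the Daubechies-4 mother
#' wavelet (periodised, orthogonal). Each feature is the energy of one detail
#' level divided by the total energy across the five detail levels and the
#' final approximation.
#'
#' @param x numeric vector of samples (length at least 32).
#' @param levels decomposition depth.
#' @return Named numeric vector `wavelet_d1` ... `wavelet_d5`, each in
#'   `[0, 1]`, summing with the (unreported) approximation share to 1.
#' @export
wavelet_energies <- function(x, levels = 5) {
  stopifnot(length(x) >= 2^levels)
  e <- .wavelet_block(matrix(x, ncol = 1), levels)[, 1]
  stats::setNames(e, paste0("wavelet_d", seq_len(levels)))
}

.wavelet_block <- function(X, levels = 5) {
  lo <- db4_lo
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  nc <- ncol(X)
  e_detail <- matrix(0, levels, nc)
  A <- X
  for (l in seq_len(levels)) {
    if (nrow(A) %% 2 == 1) A <- rbind(A, A[1, ])
    st <- dwt_step_periodic(A, lo, hi)
    e_detail[l, ] <- colSums(st$detail^2)
    A <- st$approx
  }
  tot <- colSums(e_detail) + colSums(A^2)
  out <- sweep(e_detail, 2, ifelse(tot > 0, tot, 1), "/")
  out[, tot == 0] <- 0
  rownames(out) <- paste0("wavelet_d", seq_len(levels))
  out
}

# ---- Assembly -------------------------------------------------------------

features_one_window <- function(X, fs) {
  rbind(.moment_block(X), .hjorth_block(X),
        decorrelation_time = .decorr_block(X, fs),
        .spectral_block(X, fs), .wavelet_block(X))
}

#' Extract the 55-per-channel feature vectors of a window set
#'
#' Computes all 55 univariate features for every channel of every requested
#' window and flattens them channel-major (all features of channel 1, then
#' channel 2, ...): 55 x 19 = 1045 values per window at the emulated montage.
#'
#' @param ws an `eeg_windows` object from [segment()].
#' @param indices window indices to extract (default: all).
#' @return A `feature_matrix`: numeric matrix (windows x 55*channels) with
#'   attributes `timestamps`, `contiguous_with_previous`, `feature_names`
#'   (per channel), and `channel_labels`.
#' @export
extract_features <- function(ws, indices = NULL, batch_size = 128) {
  stopifnot(inherits(ws, "eeg_windows"))
  if (is.null(indices)) indices <- seq_len(n_windows(ws))
  nc <- n_channels(ws$record)
  L <- round(ws$window_s * ws$fs)
  fn <- feature_names()
  out <- matrix(0, length(indices), length(fn) * nc)
  colnames(out) <- as.vector(outer(fn, ws$record$channel_labels,
                                   function(f, c) paste0(c, "_", f)))
  # windows are processed in batches, stacked channel-wise as columns, so
  # every feature block runs vectorised across the whole batch
  for (start in seq(1, length(indices), by = batch_size)) {
    chunk <- indices[start:min(start + batch_size - 1, length(indices))]
    B <- length(chunk)
    Xbig <- matrix(0, L, B * nc)
    for (k in seq_len(B)) {
      Xbig[, ((k - 1) * nc + 1):(k * nc)] <- window_data(ws, chunk[k])
    }
    if (anyNA(Xbig)) stopf("window contains NA; preprocessing must drop such windows")
    Fb <- features_one_window(Xbig, ws$fs)
    out[start:(start + B - 1), ] <- t(matrix(Fb, length(fn) * nc, B))
  }
  if (any(!is.finite(out))) stopf("non-finite feature value produced")
  contig <- ws$contiguous_with_previous[indices]
  if (length(indices) > 1) {
    contig[-1] <- diff(ws$timestamps[indices]) == ws$window_s
  }
  structure(out, timestamps = ws$timestamps[indices],
            contiguous_with_previous = contig,
            feature_names = fn, channel_labels = ws$record$channel_labels,
            class = c("feature_matrix", "matrix", "array"))
}
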