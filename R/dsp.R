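# Spectral-domain signal processing. All filters are FFT masks: exactly
# zero-phase, with raised-cosine transitions. Sessions are padded to a whole
# number of seconds with a 2-3-5-smooth second count so the 500 Hz and
# 256 Hz DFT grids share bin spacing (1/duration), which makes 500 -> 256
# resampling an exact spectral truncation.

# pad length in samples so that n_seconds is 2-3-5-smooth
smooth_pad_seconds <- function(n, fs) {
  secs <- ceiling(n / fs)
  nextn(max(secs, 2L), c(2, 3, 5))
}

# frequency of each DFT bin for length m at rate fs
fft_freqs <- function(m, fs) {
  k <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1))
  k * fs / m
}

# raised-cosine band mask: 1 inside [lo, hi], cosine roll-off of `trans` Hz
# centered on each edge, 0 outside. lo = NULL -> low-pass, hi = NULL ->
# high-pass.
cosine_mask <- function(f, lo = NULL, hi = NULL, trans = 0.5) {
  af <- abs(f)
  m <- rep(1, length(f))
  ramp <- function(x) 0.5 * (1 + cos(pi * pmin(1, pmax(0, x))))
  if (!is.null(lo)) m <- m * ramp((lo + trans / 2 - af) / trans)
  if (!is.null(hi)) m <- m * ramp((af - (hi - trans / 2)) / trans)
  m
}

# forward FFT of a (samples x channels) matrix zero-padded to `m` samples
fft_padded <- function(x, m) {
  n <- nrow(x)
  if (m > n) x <- rbind(x, matrix(0, m - n, ncol(x)))
  mvfft(x)
}

#' Resample a session recording from 500 to 256 Hz
#'
#' Frequency-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency (an ideal anti-alias filter) and inverted on the 256 Hz grid.
#' Durations are preserved exactly; segment boundaries are remapped with
#' floor for starts and ceiling for ends so no segment sample is lost.
#'
#' @param recording An `eeg_session` at 500 Hz.
#' @return The recording resampled to 256 Hz (class unchanged).
#' @export
resample_256 <- function(recording) {
  fs <- recording$sampling_rate
  if (fs == 256) {
    inform("recording already at 256 Hz; returning unchanged")
    return(recording)
  }
  if (fs != 500) {
    abort(sprintf("unsupported sampling rate %g Hz: expected 500", fs))
  }
  n <- nrow(recording$signal)
  secs <- smooth_pad_seconds(n, fs)
  m500 <- secs * 500L
  m256 <- secs * 256L
  X <- fft_padded(recording$signal, m500)
  # shared bin spacing: keep bins 0..m256/2-1 and the mirrored negatives
  keep_pos <- seq_len(m256 / 2) # bins 0 .. m256/2 - 1
  Y <- matrix(0 + 0i, m256, ncol(X))
  Y[keep_pos, ] <- X[keep_pos, ]
  Y[m256 - seq_len(m256 / 2 - 1) + 1, ] <- X[m500 - seq_len(m256 / 2 - 1) + 1, ]
  y <- Re(mvfft(Y, inverse = TRUE)) / m500
  n256 <- as.integer(round(n * 256 / 500))
  y <- y[seq_len(n256), , drop = FALSE]
  colnames(y) <- colnames(recording$signal)

  out <- recording
  out$signal <- y
  out$sampling_rate <- 256
  out$segments <- remap_segments(recording$segments, 256 / 500, n256)
  out
}

# floor starts, ceil ends (1-based inclusive indices)
remap_segments <- function(segments, ratio, n_new) {
  segments$start_sample <- pmax(1L, as.integer(floor((segments$start_sample - 1L) * ratio)) + 1L)
  segments$end_sample <- pmin(as.integer(n_new), as.integer(ceiling(segments$end_sample * ratio)))
  segments
}

#' Band-pass filter a recording from 1 to 50 Hz
#'
#' Zero-phase spectral mask with 0.5 Hz raised-cosine transitions centered on
#' the band edges. DC is removed exactly; the passband (2-45 Hz) is flat.
#'
#' @param recording An `eeg_session` (any rate).
#' @param lo,hi Band edges in Hz (defaults 1 and 50).
#' @return The filtered recording.
#' @export
bandpass_1_50 <- function(recording, lo = 1, hi = 50) {
  x <- recording$signal
  m <- smooth_pad_seconds(nrow(x), recording$sampling_rate) * recording$sampling_rate
  X <- fft_padded(x, m)
  mask <- cosine_mask(fft_freqs(m, recording$sampling_rate), lo = lo, hi = hi)
  y <- Re(mvfft(X * mask, inverse = TRUE))[seq_len(nrow(x)), , drop = FALSE] / m
  colnames(y) <- colnames(x)
  recording$signal <- y
  recording
}

#' Band-limited power time series via the filter-Hilbert method
#'
#' Band-passes each channel to the requested band (zero-phase spectral mask,
#' 0.5 Hz transitions), forms the analytic signal and returns the squared
#' envelope, i.e. instantaneous power.
#'
#' @param x Numeric matrix (samples x channels) or vector.
#' @param band Length-2 numeric, band edges in Hz (inside [1, 50]).
#' @param fs Sampling rate in Hz.
#' @return Matrix of non-negative instantaneous power, same shape as `x`.
#' @export
#' @examples
#' fs <- 256
#' t <- seq(0, 10, by = 1 / fs)
#' p <- filter_hilbert_power(sin(2 * pi * 10 * t), c(9, 11), fs)
#' mean(p[fs:(9 * fs)]) # ~1: unit-amplitude tone -> unit envelope power
filter_hilbert_power <- function(x, band, fs) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (band[1] < 0.5 || band[2] > min(50, fs / 2)) {
    abort(sprintf("band [%g, %g] Hz outside the supported range", band[1], band[2]))
  }
  m <- smooth_pad_seconds(nrow(x), fs) * fs
  X <- fft_padded(x, m)
  env <- analytic_band(X, m, fs, band)[seq_len(nrow(x)), , drop = FALSE]
  cx_power_cpp(env)
}

# analytic signal of a band, from a precomputed forward FFT `X` of length m:
# positive frequencies doubled and masked to the band, negatives zeroed.
# Only the band's (few) nonzero bins are multiplied.
analytic_band <- function(X, m, fs, band, trans = 0.5) {
  f <- fft_freqs(m, fs)
  mask <- cosine_mask(f, lo = band[1], hi = band[2], trans = trans)
  mask <- mask * ifelse(f > 0, 2, ifelse(f == 0, 1, 0))
  nz <- which(mask != 0)
  Y <- matrix(0 + 0i, nrow(X), ncol(X))
  Y[nz, ] <- X[nz, , drop = FALSE] * mask[nz]
  mvfft(Y, inverse = TRUE) / m
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% overlap, the spectral
#' estimator used for IAF detection (4 s windows give 0.25 Hz resolution).
#'
#' @param x Numeric matrix (samples x channels) or vector.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 4).
#' @return A list with `freq` (Hz) and `psd` (power density averaged over
#'   windows, one column per channel).
#' @export
welch_psd <- function(x, fs, window_s = 4) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  nw <- as.integer(round(window_s * fs))
  if (nrow(x) < nw) abort("signal shorter than one Welch window")
  step <- nw %/% 2L
  starts <- seq(1L, nrow(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1)) # hann
  u <- sum(w^2)
  nfreq <- nw %/% 2L + 1L
  acc <- matrix(0, nfreq, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nw - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    S <- mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + (Re(S)^2 + Im(S)^2)
  }
  list(
    freq = (seq_len(nfreq) - 1) * fs / nw,
    psd = acc / (length(starts) * u * fs)
  )
}
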