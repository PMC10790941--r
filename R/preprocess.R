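# From raw session EEG to baseline-normalized band power: resample to
# 256 Hz, band-pass 1-50 Hz, estimate the IAF from the two eyes-closed
# baselines, build the four IAF-relative bands, filter-Hilbert each band and
# z-score against the first eyes-open baseline.

#' IAF-relative frequency band scheme
#'
#' The four contiguous 2 Hz bands anchored at the individual alpha frequency:
#' theta `[iaf-6, iaf-4]`, alpha_low1 `[iaf-4, iaf-2]`, alpha_low2
#' `[iaf-2, iaf]` and alpha_high `[iaf, iaf+2]`.
#'
#' @param iaf Individual alpha frequency in Hz, in [8, 15].
#' @return A `band_scheme`: list with `iaf` and a named list `bands` of
#'   length-2 numeric edges.
#' @export
#' @examples
#' define_bands(10)$bands$theta # 4 6
define_bands <- function(iaf) {
  if (iaf < 8 || iaf > 15) {
    abort(sprintf("IAF %g Hz outside the supported range [8, 15]", iaf))
  }
  structure(list(
    iaf = iaf,
    bands = list(
      theta = c(iaf - 6, iaf - 4),
      alpha_low1 = c(iaf - 4, iaf - 2),
      alpha_low2 = c(iaf - 2, iaf),
      alpha_high = c(iaf, iaf + 2)
    )
  ), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> IAF %.2f Hz\n", x$iaf))
  for (b in names(x$bands)) {
    cat(sprintf("  %-10s [%5.2f, %5.2f] Hz\n", b, x$bands[[b]][1], x$bands[[b]][2]))
  }
  invisible(x)
}

#' Estimate the individual alpha frequency
#'
#' The IAF is the mean of the two frequencies of maximal Welch power between
#' 8 and 15 Hz in the two eyes-closed baselines (start and end of session),
#' averaged over the configured channels (occipital by default, where the
#' alpha peak is strongest). Using both baselines absorbs slow IAF drift
#' over the session.
#'
#' @param eyes_closed_first,eyes_closed_last Numeric matrices
#'   (samples x channels) of the two eyes-closed baselines, at least 30 s.
#' @param fs Sampling rate (Hz).
#' @param channels Optional channel labels to average over (default
#'   `c("O1", "Oz", "O2")`); matched against column names when present.
#' @param peak_ratio_min Flatness guard: the in-band peak must exceed this
#'   multiple of the median in-band power, else a no-peak error is raised.
#' @return IAF in Hz (on the 0.25 Hz Welch grid).
#' @export
estimate_iaf <- function(eyes_closed_first, eyes_closed_last, fs = 256,
                         channels = c("O1", "Oz", "O2"),
                         peak_ratio_min = 2) {
  peak_of <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    if (nrow(x) < 30 * fs) abort("eyes-closed baseline must be at least 30 s")
    if (!is.null(colnames(x)) && any(channels %in% colnames(x))) {
      x <- x[, intersect(channels, colnames(x)), drop = FALSE]
    }
    w <- welch_psd(x, fs, window_s = 4)
    sel <- w$freq >= 8 & w$freq <= 15
    p <- rowMeans(w$psd)[sel]
    f <- w$freq[sel]
    if (max(p) < peak_ratio_min * median(p)) {
      abort("no alpha peak: spectrum is flat in 8-15 Hz (fall back to a configured default IAF if appropriate)")
    }
    f[which.max(p)]
  }
  (peak_of(eyes_closed_first) + peak_of(eyes_closed_last)) / 2
}

#' Z-score a power series against its first eyes-open baseline
#'
#' Per channel: `(power - mean(baseline)) / sd(baseline)`, with the baseline
#' statistics taken over the given segment of the same series. After
#' normalization the baseline segment itself has mean 0 and sd 1 exactly.
#'
#' @param power Numeric matrix (samples x channels) of raw band power.
#' @param baseline_idx Integer vector of row indices of the first eyes-open
#'   baseline segment (at least 30 s worth of samples).
#' @param fs Sampling rate (Hz), used only to check the baseline length.
#' @return Matrix of z-scored power, same shape as `power`.
#' @export
baseline_z_normalize <- function(power, baseline_idx, fs = 256) {
  if (length(baseline_idx) < 30 * fs) {
    abort("baseline segment must be at least 30 s")
  }
  base <- power[baseline_idx, , drop = FALSE]
  mu <- colMeans(base)
  n <- nrow(base)
  sdv <- sqrt(colSums(sweep(base, 2, mu)^2) / (n - 1))
  if (any(sdv == 0)) abort("degenerate baseline: zero standard deviation")
  out <- znorm_cpp(power, mu, sdv)
  colnames(out) <- colnames(power)
  out
}

#' Preprocess one session to normalized band power
#'
#' Runs the fixed pipeline: resample 500 to 256 Hz, band-pass 1-50 Hz,
#' optional artifact-removal hook, IAF estimation from the eyes-closed
#' baselines, IAF-relative band definition, filter-Hilbert power per band,
#' and z-normalization against the first eyes-open baseline. Only the
#' analysis-montage channels are carried through.
#'
#' For speed the spectral steps share one forward FFT (the masks compose
#' multiplicatively), which is numerically identical to composing
#' [resample_256()], [bandpass_1_50()] and [filter_hilbert_power()].
#'
#' @param session An `eeg_session` at 500 Hz.
#' @param montage Analysis montage tibble from [montage_subset()].
#' @param artifact_hook Optional function (matrix samples x channels,
#'   fs) -> matrix applied after band-pass filtering; identity by default.
#' @param iaf_channels Channels averaged for IAF estimation.
#' @param iaf_default Fallback IAF (Hz) used with a warning when no alpha
#'   peak is found; set `NULL` to propagate the error instead.
#' @return A `power_session`: list with `participant_id`, `fs` (256),
#'   `channels`, `iaf`, `bands` (a `band_scheme`), `power` (named list of
#'   four samples x channels matrices of z-scored power), `segments`
#'   (remapped to the 256 Hz clock) and `behavior`.
#' @export
preprocess_session <- function(session, montage = montage_subset(),
                               artifact_hook = NULL,
                               iaf_channels = c("O1", "Oz", "O2"),
                               iaf_default = 10) {
  stopifnot(inherits(session, "eeg_session"))
  keep <- union(montage$channel, iaf_channels)
  keep <- keep[keep %in% colnames(session$signal)]
  x <- session$signal[, keep, drop = FALSE]
  fs0 <- session$sampling_rate
  if (fs0 != 500) abort(sprintf("unsupported sampling rate %g Hz: expected 500", fs0))

  n <- nrow(x)
  secs <- smooth_pad_seconds(n, fs0)
  m500 <- secs * 500L
  m256 <- secs * 256L
  n256 <- as.integer(round(n * 256 / 500))

  # one forward FFT; resampling = spectral truncation onto the shared grid
  X <- fft_padded(x, m500)
  Y <- matrix(0 + 0i, m256, ncol(X))
  keep_pos <- seq_len(m256 / 2)
  Y[keep_pos, ] <- X[keep_pos, ]
  Y[m256 - seq_len(m256 / 2 - 1) + 1, ] <- X[m500 - seq_len(m256 / 2 - 1) + 1, ]
  rm(X, x) # the 500 Hz spectrum and signal are no longer needed
  Y <- Y / m500 * m256 # so that ifft(Y)/m256 has the original amplitude

  bp_mask <- cosine_mask(fft_freqs(m256, 256), lo = 1, hi = 50)
  Y <- Y * bp_mask
  segments <- remap_segments(session$segments, 256 / 500, n256)

  if (!is.null(artifact_hook)) {
    filtered <- Re(mvfft(Y, inverse = TRUE))[seq_len(n256), , drop = FALSE] / m256
    colnames(filtered) <- keep
    filtered <- artifact_hook(filtered, 256)
    # hook output re-enters the spectral pathway
    Y <- fft_padded(filtered, m256)
    iaf_sig <- filtered[, intersect(iaf_channels, keep), drop = FALSE]
  } else {
    # no hook: only the IAF channels need the filtered time series
    icols <- match(intersect(iaf_channels, keep), keep)
    iaf_sig <- Re(mvfft(Y[, icols, drop = FALSE], inverse = TRUE))[
      seq_len(n256), ,
      drop = FALSE
    ] / m256
    colnames(iaf_sig) <- keep[icols]
  }

  ec <- segments[segments$segment_kind == "eyes_closed", ]
  iaf <- tryCatch(
    estimate_iaf(
      iaf_sig[ec$start_sample[1]:ec$end_sample[1], , drop = FALSE],
      iaf_sig[ec$start_sample[2]:ec$end_sample[2], , drop = FALSE],
      fs = 256, channels = iaf_channels
    ),
    error = function(e) {
      if (is.null(iaf_default)) stop(e)
      warn(sprintf("%s; using default IAF %g Hz", conditionMessage(e), iaf_default))
      iaf_default
    }
  )
  scheme <- define_bands(iaf)

  eo_first <- segments[segments$segment_kind == "eyes_open", ][1, ]
  base_idx <- seq(eo_first$start_sample, eo_first$end_sample)

  # columns of Y restricted to the montage order once, then per band the
  # fused mask -> inverse FFT -> squared envelope -> z-score kernel
  mont_cols <- match(montage$channel, keep)
  Ym <- Y[, mont_cols, drop = FALSE]
  f256 <- fft_freqs(m256, 256)
  power <- lapply(scheme$bands, function(band) {
    mask <- cosine_mask(f256, lo = band[1], hi = band[2]) *
      ifelse(f256 > 0, 2, ifelse(f256 == 0, 1, 0))
    nz <- which(mask != 0)
    Z <- matrix(0 + 0i, m256, ncol(Ym))
    Z[nz, ] <- Ym[nz, , drop = FALSE] * mask[nz]
    env <- mvfft(Z, inverse = TRUE) # un-normalized; scale folded in below
    p <- power_znorm_cpp(env,
      scale = m256, n_keep = n256,
      base_start = base_idx[1], base_end = base_idx[length(base_idx)]
    )
    colnames(p) <- montage$channel
    p
  })

  structure(list(
    participant_id = session$participant_id,
    is_responder = session$is_responder,
    fs = 256,
    channels = montage$channel,
    iaf = iaf,
    bands = scheme,
    power = power,
    segments = segments,
    behavior = session$behavior
  ), class = "power_session")
}

#' @export
print.power_session <- function(x, ...) {
  cat(sprintf(
    "<power_session> %s: %d channels x 4 bands @ %g Hz, IAF %.2f Hz\n",
    x$participant_id, length(x$channels), x$fs, x$iaf
  ))
  invisible(x)
}
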