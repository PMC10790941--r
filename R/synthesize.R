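# Synthetic EEG: 1/f background noise plus amplitude-modulated sinusoids at
# participant-specific frequencies. Oscillations carry the planted structure
# the analysis pipeline is meant to recover: a theta tone at IAF-5 Hz, a
# constant lower-alpha tone at IAF-1 Hz, and an upper-alpha tone at IAF+1 Hz
# whose amplitude follows the proficiency trajectory for responders.

# Baseline per-region oscillation weights; jittered per participant.
REGION_WEIGHTS <- c(
  frontal = 0.6, temporal = 0.35, parietal = 0.85,
  occipital = 1.0, central = 0.3
)

# amplitude conventions (microvolt)
AMP_NOISE_SD <- 10   # pink-noise scale
AMP_THETA <- 4       # theta tone at IAF-5
AMP_ALPHA <- 6       # alpha tones during task / eyes-open rest
AMP_ALPHA_EC <- 18   # alpha tone at IAF during eyes-closed rest

# One amplitude-modulated sinusoid, shared across channels (per-channel
# gains are applied by the caller via outer()).
am_tone <- function(n, fs, freq, mod_depth = 0.25, mod_freq = 0.4) {
  t <- (seq_len(n) - 1) / fs
  phase <- runif(1, 0, 2 * pi)
  mod_phase <- runif(1, 0, 2 * pi)
  (1 + mod_depth * sin(2 * pi * mod_freq * t + mod_phase)) *
    sin(2 * pi * freq * t + phase)
}

#' Synthesize one segment of multi-channel EEG
#'
#' Produces `duration * fs` samples of 64-channel EEG-like signal: pink noise
#' with spectral slope `noise_exponent`, a theta tone at `iaf - 5` Hz, a
#' constant lower-alpha tone at `iaf - 1` Hz and an upper-alpha tone whose
#' amplitude is scaled by `alpha_high_gain`, placed at `iaf + 1` Hz for task
#' and eyes-open segments (the center of the upper-alpha band) or exactly at
#' `iaf` for eyes-closed rest (so the resting spectrum peaks at the IAF).
#' Per-channel oscillation gains come from `region_weights`.
#'
#' @param duration Segment duration in seconds (> 0).
#' @param iaf Individual alpha frequency in Hz.
#' @param alpha_high_gain Dimensionless gain on the upper-alpha amplitude.
#' @param region_weights Named numeric vector of per-channel gains (names are
#'   channel labels); channels with weight 0 receive no oscillation.
#' @param fs Sampling rate in Hz (default 500).
#' @param noise_exponent 1/f spectral slope (default 1).
#' @param kind `"navigation"`, `"eyes_open"` or `"eyes_closed"`; controls the
#'   alpha-tone placement and amplitude as described above.
#' @param noise_seed Integer seed for the C++ pink-noise stream.
#' @return Numeric matrix, `duration * fs` rows x `length(region_weights)`
#'   columns, in microvolt.
#' @export
synthesize_trial_eeg <- function(duration, iaf, alpha_high_gain,
                                 region_weights, fs = 500,
                                 noise_exponent = 1,
                                 kind = c("navigation", "eyes_open", "eyes_closed"),
                                 noise_seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(duration > 0)
  n <- round(duration * fs)
  nch <- length(region_weights)
  if (is.null(noise_seed)) noise_seed <- sample.int(.Machine$integer.max, 1)
  x <- pink_noise_cpp(n, nch, noise_exponent, as.double(noise_seed)) * AMP_NOISE_SD

  w <- as.numeric(region_weights)
  # tones as columns, per-channel amplitudes as rows: one BLAS multiply
  if (kind == "eyes_closed") {
    tones <- cbind(
      am_tone(n, fs, iaf - 5),
      am_tone(n, fs, iaf, mod_depth = 0.15)
    )
    amps <- cbind(AMP_THETA * w, AMP_ALPHA_EC * alpha_high_gain * w)
  } else {
    tones <- cbind(
      am_tone(n, fs, iaf - 5),
      am_tone(n, fs, iaf - 1),
      am_tone(n, fs, iaf + 1)
    )
    amps <- cbind(AMP_THETA * w, AMP_ALPHA * w, AMP_ALPHA * alpha_high_gain * w)
  }
  x <- x + tcrossprod(tones, amps)
  colnames(x) <- names(region_weights)
  x
}

# Per-participant latent parameters (IAF, spectral slope, region weights).
draw_participant_params <- function(spec) {
  regions <- full_montage_regions()
  iaf <- runif(1, spec$iaf_range[1], spec$iaf_range[2])
  slope <- spec$noise_exponent + runif(1, -0.1, 0.1)
  w <- REGION_WEIGHTS[regions$region] * exp(rnorm(nrow(regions), sd = 0.15))
  names(w) <- regions$channel
  list(iaf = iaf, noise_exponent = slope, weights = w)
}

#' Generate a synthetic cohort of training sessions
#'
#' Deterministically (given `seed`) simulates `spec$n_participants` single
#' training sessions with the layout the analysis pipeline expects: an
#' eyes-closed baseline, then for each block an eyes-open baseline followed
#' by `block_size` navigation trials, then a final eyes-closed baseline.
#' Responders' upper-alpha amplitude rises along the certainty trajectory by
#' a factor `alpha_effect_size`; non-responders stay flat or decrease.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; every downstream draw derives from it.
#' @return A list of class `eeg_cohort`: one `eeg_session` per participant,
#'   plus the `spec` and `seed` as attributes. Each `eeg_session` has fields
#'   `participant_id`, `is_responder`, `gain_profile`, `sampling_rate`,
#'   `channel_labels`, `iaf_true`, `signal` (samples x channels, microvolt),
#'   `segments` and `behavior` tibbles.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(
#'   n_participants = 2, n_trials = 12, block_size = 6,
#'   baseline_duration = 30, ideal_time_range = c(6, 10),
#'   max_trial_duration = 20
#' ), seed = 1)
#' cohort[[1]]$segments
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  validate_cohort_spec(spec)
  n_resp <- as.integer(round(spec$responder_fraction * spec$n_participants))
  n_non <- spec$n_participants - n_resp
  n_dec <- as.integer(round(spec$nonresponder_decreasing_fraction * n_non))
  profiles <- c(
    rep("rising", n_resp),
    rep("decreasing", n_dec),
    rep("flat", n_non - n_dec)
  )
  sessions <- lapply(seq_len(spec$n_participants), function(p) {
    simulate_session(spec, participant = p, profile = profiles[p], seed = seed)
  })
  structure(sessions,
    class = "eeg_cohort",
    spec = spec, seed = seed
  )
}

# One participant's session. All randomness flows through derived streams so
# participants are independent of each other and of cohort size.
simulate_session <- function(spec, participant, profile, seed) {
  pid <- sprintf("P%02d", participant)
  params <- with_stream(seed, participant, 1, expr = draw_participant_params(spec))

  beh <- with_stream(seed, participant, 2, expr = {
    certainty <- certainty_trajectory(spec$certainty, spec$n_trials, spec$block_size)
    ideal <- runif(spec$n_trials, spec$ideal_time_range[1], spec$ideal_time_range[2])
    ttime <- trial_times(spec$time_excess, ideal,
      block_size = spec$block_size,
      max_trial_duration = spec$max_trial_duration
    )
    tibble(
      trial_index = seq_len(spec$n_trials),
      block_index = rep(seq_len(spec$n_blocks), each = spec$block_size),
      certainty_rating = certainty,
      trial_time_s = ttime,
      ideal_time_s = ideal
    )
  })

  # upper-alpha gain per trial, driven by the saturation curve
  g <- saturation_curve(spec$n_trials, spec$certainty$plateau_block, spec$block_size)
  gain <- switch(profile,
    rising = 1 + (spec$alpha_effect_size - 1) * g,
    flat = rep(1, spec$n_trials),
    decreasing = 1 + (1 / spec$alpha_effect_size - 1) * g
  )

  # assemble segments: EC, then per block EO + trials, then EC
  seg_plan <- list(list(kind = "eyes_closed", dur = spec$baseline_duration,
                        trial = NA_integer_, block = NA_integer_, baseline = 1L))
  for (b in seq_len(spec$n_blocks)) {
    seg_plan[[length(seg_plan) + 1L]] <- list(
      kind = "eyes_open", dur = spec$baseline_duration,
      trial = NA_integer_, block = b, baseline = b
    )
    for (tr in which(beh$block_index == b)) {
      seg_plan[[length(seg_plan) + 1L]] <- list(
        kind = "navigation", dur = beh$trial_time_s[tr],
        trial = tr, block = b, baseline = NA_integer_
      )
    }
  }
  seg_plan[[length(seg_plan) + 1L]] <- list(
    kind = "eyes_closed", dur = spec$baseline_duration,
    trial = NA_integer_, block = NA_integer_, baseline = 2L
  )

  # whole-sample segment lengths; navigation trials keep sub-second tails
  fs <- spec$sampling_rate
  lens <- vapply(seg_plan, function(s) as.integer(round(s$dur * fs)), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)

  # one continuous pink-noise bed for the whole session (a single C++ call),
  # then the per-segment oscillations on top — the same signal model as
  # synthesize_trial_eeg(), assembled session-wise for speed
  n_total <- ends[length(ends)]
  signal <- pink_noise_cpp(
    n_total, length(params$weights), params$noise_exponent,
    as.double(seed_stream(seed, participant, 4))
  ) * AMP_NOISE_SD
  w <- as.numeric(params$weights)
  for (i in seq_along(seg_plan)) {
    s <- seg_plan[[i]]
    seg_gain <- if (s$kind == "navigation") gain[s$trial] else 1
    osc <- with_stream(seed, participant, 3, i, expr = {
      if (s$kind == "eyes_closed") {
        tones <- cbind(
          am_tone(lens[i], fs, params$iaf - 5),
          am_tone(lens[i], fs, params$iaf, mod_depth = 0.15)
        )
        amps <- cbind(AMP_THETA * w, AMP_ALPHA_EC * seg_gain * w)
      } else {
        tones <- cbind(
          am_tone(lens[i], fs, params$iaf - 5),
          am_tone(lens[i], fs, params$iaf - 1),
          am_tone(lens[i], fs, params$iaf + 1)
        )
        amps <- cbind(AMP_THETA * w, AMP_ALPHA * w, AMP_ALPHA * seg_gain * w)
      }
      tcrossprod(tones, amps)
    })
    rows <- starts[i]:ends[i]
    signal[rows, ] <- signal[rows, ] + osc
  }
  colnames(signal) <- names(params$weights)

  segments <- tibble(
    segment_kind = vapply(seg_plan, `[[`, character(1), "kind"),
    trial_index = vapply(seg_plan, `[[`, integer(1), "trial"),
    baseline_index = vapply(seg_plan, `[[`, integer(1), "baseline"),
    block_index = vapply(seg_plan, `[[`, integer(1), "block"),
    start_sample = starts,
    end_sample = ends
  )

  structure(list(
    participant_id = pid,
    is_responder = profile == "rising",
    gain_profile = profile,
    sampling_rate = fs,
    channel_labels = montage_full(),
    iaf_true = params$iaf,
    signal = signal,
    segments = segments,
    behavior = beh
  ), class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf(
    "<eeg_session> %s: %d channels x %d samples @ %g Hz (%.0f s), %d navigation trials%s\n",
    x$participant_id, ncol(x$signal), nrow(x$signal), x$sampling_rate,
    nrow(x$signal) / x$sampling_rate, sum(x$segments$segment_kind == "navigation"),
    if (x$is_responder) ", responder" else paste0(", non-responder (", x$gain_profile, ")")
  ))
  invisible(x)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "<eeg_cohort> %d sessions (%d responders), seed %d\n",
    length(x), sum(vapply(x, `[[`, logical(1), "is_responder")), attr(x, "seed")
  ))
  invisible(x)
}
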