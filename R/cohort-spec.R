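#' Specification of a synthetic training cohort
#'
#' Collects every knob of the synthetic cohort generator. The defaults mirror
#' the single-session navigation-training study design the package models:
#' 15 participants, 60 navigation trials in 10 blocks of 6, a 1-min eyes-open
#' baseline before each block, eyes-closed baselines at the start and end of
#' the session, 500 Hz 64-channel recording, and a 3-min cap per trial.
#'
#' @param n_participants Number of participants (default 15).
#' @param responder_fraction Fraction of participants whose upper-alpha power
#'   rises with proficiency (default 9/15). `responder_fraction *
#'   n_participants` must be a whole number.
#' @param n_trials Navigation trials per participant (default 60); must be an
#'   integer multiple of `block_size`.
#' @param block_size Trials per block (default 6).
#' @param sampling_rate Recording rate in Hz (default 500).
#' @param max_trial_duration Trial time cap in seconds (default 180, the
#'   protocol maximum; may not exceed 180).
#' @param baseline_duration Duration of each baseline rest period in seconds
#'   (default 60; must be at least 30 so baseline statistics and IAF spectra
#'   are well determined).
#' @param iaf_range Interval (Hz) from which each participant's individual
#'   alpha frequency is drawn uniformly (default `c(8.5, 12.5)`).
#' @param alpha_effect_size Multiplicative gain of the upper-alpha oscillation
#'   amplitude between the low- and high-proficiency ends of a responder's
#'   session (default 2).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background noise
#'   (default 1).
#' @param ideal_time_range Interval (s) from which each trial's "ideal"
#'   completion time is drawn (default `c(15, 40)`).
#' @param nonresponder_decreasing_fraction Fraction of non-responders whose
#'   upper-alpha gain *decreases* over the session instead of staying flat
#'   (default 0.5, i.e. 3 of 6 at study scale).
#' @param certainty Trajectory parameters for the self-reported certainty
#'   ratings, from [trajectory_params()].
#' @param time_excess Trajectory parameters for the percent excess over ideal
#'   completion time, from [trajectory_params()].
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 2, n_trials = 12, block_size = 6)
#' spec$n_blocks
cohort_spec <- function(n_participants = 15,
                        responder_fraction = 9 / 15,
                        n_trials = 60,
                        block_size = 6,
                        sampling_rate = 500,
                        max_trial_duration = 180,
                        baseline_duration = 60,
                        iaf_range = c(8.5, 12.5),
                        alpha_effect_size = 2,
                        noise_exponent = 1,
                        ideal_time_range = c(15, 40),
                        nonresponder_decreasing_fraction = 0.5,
                        certainty = NULL,
                        time_excess = NULL) {
  n_blocks <- n_trials / block_size
  spec <- structure(list(
    n_participants = as.integer(n_participants),
    responder_fraction = responder_fraction,
    n_trials = as.integer(n_trials),
    block_size = as.integer(block_size),
    n_blocks = as.integer(round(n_blocks)),
    sampling_rate = sampling_rate,
    max_trial_duration = max_trial_duration,
    baseline_duration = baseline_duration,
    iaf_range = iaf_range,
    alpha_effect_size = alpha_effect_size,
    noise_exponent = noise_exponent,
    ideal_time_range = ideal_time_range,
    nonresponder_decreasing_fraction = nonresponder_decreasing_fraction,
    certainty = certainty %||% trajectory_params(
      certainty_floor = 2, certainty_ceiling = 10,
      plateau_block = min(7, floor(n_blocks)), noise_sd = 0.8
    ),
    time_excess = time_excess %||% trajectory_params(
      time_excess_start = 150, time_excess_end = 10,
      plateau_block = min(7, floor(n_blocks)), noise_sd = 8
    )
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_trials %% spec$block_size != 0) {
    abort(sprintf(
      "invalid cohort spec: `n_trials` (%d) must be an integer multiple of `block_size` (%d)",
      spec$n_trials, spec$block_size
    ))
  }
  n_resp <- spec$responder_fraction * spec$n_participants
  if (abs(n_resp - round(n_resp)) > 1e-8) {
    abort(sprintf(
      "invalid cohort spec: `responder_fraction` (%g) times `n_participants` (%d) must be a whole number",
      spec$responder_fraction, spec$n_participants
    ))
  }
  if (spec$max_trial_duration > 180) {
    abort("invalid cohort spec: `max_trial_duration` may not exceed 180 s")
  }
  if (spec$baseline_duration < 30) {
    abort("invalid cohort spec: `baseline_duration` must be at least 30 s")
  }
  if (spec$sampling_rate != 500) {
    abort("invalid cohort spec: `sampling_rate` must be 500 Hz (the recording rate the pipeline expects)")
  }
  for (p in list(spec$certainty, spec$time_excess)) {
    if (p$plateau_block > spec$n_blocks) {
      abort("invalid cohort spec: `plateau_block` exceeds the number of blocks")
    }
  }
  spec
}

#' Behavioral trajectory parameters
#'
#' Shapes the two behavioral time courses of a synthetic session: the
#' self-reported certainty ratings (which rise to a plateau) and the percent
#' excess over the ideal completion time (which falls toward a floor). Both
#' follow a logistic saturation in trial index that reaches its plateau at
#' the end of `plateau_block`.
#'
#' @param certainty_floor,certainty_ceiling Rating values (1-10 scale) at the
#'   start and plateau of the session.
#' @param time_excess_start,time_excess_end Percent over ideal completion
#'   time at the start and plateau of the session.
#' @param plateau_block Block index at which the trajectory saturates.
#' @param noise_sd Trial-to-trial noise (rating units for certainty, percent
#'   for time excess), added before rounding/clipping.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(certainty_floor = 2, certainty_ceiling = 10,
                              time_excess_start = 150, time_excess_end = 10,
                              plateau_block = 7, noise_sd = 0.8) {
  if (certainty_ceiling < certainty_floor) {
    abort("`certainty_ceiling` must be >= `certainty_floor`")
  }
  structure(list(
    certainty_floor = certainty_floor,
    certainty_ceiling = certainty_ceiling,
    time_excess_start = time_excess_start,
    time_excess_end = time_excess_end,
    plateau_block = plateau_block,
    noise_sd = noise_sd
  ), class = "trajectory_params")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d participants (%g%% responders), %d trials in %d blocks of %d\n",
    x$n_participants, 100 * x$responder_fraction, x$n_trials, x$n_blocks, x$block_size
  ))
  cat(sprintf(
    "  %g Hz, trial cap %g s, baselines %g s, IAF in [%g, %g] Hz, alpha effect %g\n",
    x$sampling_rate, x$max_trial_duration, x$baseline_duration,
    x$iaf_range[1], x$iaf_range[2], x$alpha_effect_size
  ))
  invisible(x)
}
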