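# Behavioral trajectories of a synthetic session: certainty ratings rise
# along a logistic saturation to a plateau; completion-time excess falls
# along its complement.

# Normalized saturation curve over trial index: 0 at trial 1, exactly 1 from
# the last trial of `plateau_block` onward, logistic in between.
saturation_curve <- function(n_trials, plateau_block, block_size) {
  t_p <- plateau_block * block_size
  if (t_p <= 1) {
    return(rep(1, n_trials))
  }
  t <- seq_len(n_trials)
  k <- 10 / t_p # logistic steepness; ~saturated over the ramp
  l <- function(x) 1 / (1 + exp(-k * (x - t_p / 2)))
  g <- (l(t) - l(1)) / (l(t_p) - l(1))
  pmin(pmax(g, 0), 1)
}

#' Simulate a session's certainty-rating trajectory
#'
#' Ratings follow a logistic rise from `certainty_floor` to
#' `certainty_ceiling`, saturating at the end of `plateau_block`, with
#' Gaussian trial-to-trial noise added before rounding to integers and
#' clipping to the 1-10 scale.
#'
#' @param params A [trajectory_params()] object.
#' @param n_trials Number of trials.
#' @param block_size Trials per block (defines where the plateau sits).
#' @return Integer vector of length `n_trials` with values in 1..10,
#'   non-decreasing in expectation.
#' @export
#' @examples
#' p <- trajectory_params(certainty_floor = 1, certainty_ceiling = 10,
#'                        plateau_block = 7, noise_sd = 0)
#' r <- certainty_trajectory(p, n_trials = 60, block_size = 6)
#' r[1]        # 1
#' r[43:60]    # all 10
certainty_trajectory <- function(params, n_trials, block_size = 6) {
  g <- saturation_curve(n_trials, params$plateau_block, block_size)
  m <- params$certainty_floor +
    (params$certainty_ceiling - params$certainty_floor) * g
  noisy <- m + rnorm(n_trials, sd = params$noise_sd)
  as.integer(pmin(10L, pmax(1L, round(noisy))))
}

#' Simulate trial completion times
#'
#' Completion time for trial t is `ideal_time * (1 + excess(t)/100)`, where
#' the percent excess declines from `time_excess_start` to `time_excess_end`
#' along the complement of the logistic saturation curve. Times are capped at
#' `max_trial_duration` and floored at `min_trial_time` so every trial yields
#' at least a few 1-s epochs.
#'
#' @param params A [trajectory_params()] object.
#' @param ideal_times Positive numeric vector of per-trial ideal times (s).
#' @param block_size Trials per block.
#' @param max_trial_duration Cap in seconds.
#' @param min_trial_time Floor in seconds (default 5).
#' @return Numeric vector of trial times (s), same length as `ideal_times`.
#' @export
trial_times <- function(params, ideal_times, block_size = 6,
                        max_trial_duration = 180, min_trial_time = 5) {
  if (any(ideal_times <= 0)) abort("`ideal_times` must be positive")
  n <- length(ideal_times)
  g <- saturation_curve(n, params$plateau_block, block_size)
  excess <- params$time_excess_start +
    (params$time_excess_end - params$time_excess_start) * g
  excess <- excess + rnorm(n, sd = params$noise_sd)
  tt <- ideal_times * (1 + excess / 100)
  pmin(max_trial_duration, pmax(min_trial_time, tt))
}
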