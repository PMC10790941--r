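# Welch alpha power around the IAF (+/- 1 Hz window) on one channel
alpha_power_at <- function(x, fs, iaf, window_s = 2) {
  w <- welch_psd(x, fs, window_s = window_s)
  sel <- w$freq >= iaf - 1 & w$freq <= iaf + 1
  mean(rowMeans(w$psd)[sel])
}

test_that("trial synthesis is deterministic and shaped by region weights", {
  w <- c(O1 = 1, Oz = 1, F3 = 0.5, Cz = 0)
  a <- synthesize_trial_eeg(10, 10, 1, w, noise_seed = 9)
  b <- synthesize_trial_eeg(10, 10, 1, w, noise_seed = 9)
  expect_identical(dim(a), c(5000L, 4L))
  expect_identical(colnames(a), names(w))
  # deterministic noise; tone phases drawn from the R stream
  withr::with_seed(1, a2 <- synthesize_trial_eeg(10, 10, 1, w, noise_seed = 9))
  withr::with_seed(1, b2 <- synthesize_trial_eeg(10, 10, 1, w, noise_seed = 9))
  expect_identical(a2, b2)

  # zero-weight channel shows no alpha peak above its 1/f neighborhood
  ec <- withr::with_seed(
    2,
    synthesize_trial_eeg(40, 10, 1, w, kind = "eyes_closed", noise_seed = 3)
  )
  wp <- welch_psd(ec, 500, window_s = 4)
  peak_ratio <- function(ch) {
    band <- wp$freq >= 8 & wp$freq <= 12
    flank <- (wp$freq >= 5 & wp$freq < 8) | (wp$freq > 12 & wp$freq <= 15)
    max(wp$psd[band, ch]) / median(wp$psd[flank, ch])
  }
  expect_gt(peak_ratio("O1"), 10)
  expect_lt(peak_ratio("Cz"), 3)
})

test_that("doubling the upper-alpha gain raises alpha-band power on every weighted channel", {
  w <- c(O1 = 1, Oz = 0.8, P3 = 0.6, F3 = 0.4)
  p1 <- sapply(seq_along(w), function(ch) {
    x <- withr::with_seed(
      7, synthesize_trial_eeg(30, 10.5, 1, w, noise_seed = 11)
    )
    alpha_power_at(x[, ch], 500, 10.5)
  })
  p2 <- sapply(seq_along(w), function(ch) {
    x <- withr::with_seed(
      7, synthesize_trial_eeg(30, 10.5, 2, w, noise_seed = 11)
    )
    alpha_power_at(x[, ch], 500, 10.5)
  })
  expect_true(all(p2 > p1))
})

test_that("eyes-closed baselines put the spectral peak at the IAF", {
  for (iaf in c(9, 10, 11.5)) {
    ec <- withr::with_seed(3, synthesize_trial_eeg(
      40, iaf, 1, c(O1 = 1, Oz = 1, O2 = 1),
      kind = "eyes_closed", noise_seed = 4
    ))
    w <- welch_psd(ec, 500, window_s = 4)
    sel <- w$freq >= 8 & w$freq <= 15
    f_peak <- w$freq[sel][which.max(rowMeans(w$psd)[sel])]
    expect_lt(abs(f_peak - iaf), 0.25 + 1e-9) # within one Welch bin
  }
})

test_that("cohort generation respects the design counts and is deterministic", {
  spec <- cohort_spec(
    n_participants = 2, responder_fraction = 0.5, n_trials = 12,
    block_size = 6, baseline_duration = 30, ideal_time_range = c(5, 7),
    max_trial_duration = 15,
    certainty = trajectory_params(plateau_block = 1),
    time_excess = trajectory_params(plateau_block = 1, noise_sd = 5)
  )
  cohort <- simulate_cohort(spec, seed = 3)
  expect_length(cohort, 2)
  expect_equal(sum(vapply(cohort, `[[`, logical(1), "is_responder")), 1L)
  for (s in cohort) {
    kinds <- s$segments$segment_kind
    expect_equal(sum(kinds == "navigation"), 12L)
    expect_equal(sum(kinds == "eyes_open"), 2L) # one per block
    expect_equal(sum(kinds == "eyes_closed"), 2L)
    expect_equal(kinds[1], "eyes_closed")
    expect_equal(kinds[length(kinds)], "eyes_closed")
    # segments ordered, non-overlapping, inside the signal
    expect_true(all(s$segments$end_sample > s$segments$start_sample))
    expect_true(all(diff(s$segments$start_sample) > 0))
    expect_true(all(
      s$segments$start_sample[-1] == head(s$segments$end_sample, -1) + 1
    ))
    expect_lte(max(s$segments$end_sample), nrow(s$signal))
    expect_true(all(s$behavior$certainty_rating %in% 1:10))
    expect_true(all(s$behavior$trial_time_s > 0 &
      s$behavior$trial_time_s <= spec$max_trial_duration))
  }
  cohort2 <- simulate_cohort(spec, seed = 3)
  expect_identical(cohort[[1]]$signal, cohort2[[1]]$signal)
  expect_identical(cohort[[2]]$behavior, cohort2[[2]]$behavior)
})

test_that("invalid cohort specs fail naming the offending field", {
  expect_error(cohort_spec(n_trials = 61, block_size = 6), "n_trials")
  expect_error(
    cohort_spec(n_participants = 6, responder_fraction = 0.6),
    "responder_fraction"
  )
  expect_error(cohort_spec(max_trial_duration = 200), "max_trial_duration")
})

test_that("responders gain upper-alpha power from first to last block; flat non-responders do not", {
  # small 10-block geometry; per seed, mean alpha power (IAF +/- 1 Hz) of an
  # occipital channel over last-block trials vs first-block trials
  ratio_for <- function(seed, frac) {
    spec <- cohort_spec(
      n_participants = 1, responder_fraction = frac, n_trials = 20,
      block_size = 2, baseline_duration = 30, ideal_time_range = c(5, 7),
      max_trial_duration = 15, nonresponder_decreasing_fraction = 0,
      certainty = trajectory_params(plateau_block = 7, noise_sd = 0.5),
      time_excess = trajectory_params(plateau_block = 7, noise_sd = 5)
    )
    s <- simulate_cohort(spec, seed = seed)[[1]]
    pw <- function(block) {
      segs <- s$segments[s$segments$segment_kind == "navigation" &
        s$segments$block_index == block, ]
      mean(vapply(seq_len(nrow(segs)), function(i) {
        x <- s$signal[segs$start_sample[i]:segs$end_sample[i], "Oz"]
        alpha_power_at(x, 500, s$iaf_true)
      }, numeric(1)))
    }
    pw(10) / pw(1)
  }
  resp <- vapply(1:20, ratio_for, numeric(1), frac = 1)
  flat <- vapply(1:10, ratio_for, numeric(1), frac = 0)
  # responders: last-block alpha power clearly above first block
  expect_lt(t.test(log(resp), alternative = "greater")$p.value, 0.01)
  expect_true(all(resp > 1))
  # flat non-responders: no systematic change
  expect_gt(t.test(log(flat))$p.value, 0.01)
  expect_lt(abs(mean(log(flat))), 0.3)
})
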