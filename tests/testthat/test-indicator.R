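test_that("the neural indicator is the epoch-mean predicted class per trial", {
  # one run, all epochs predicted high
  t1 <- compute_ni(fake_lopo(matrix(c(1, 1, 1, 1), 4, 1), trials = rep(1, 4)))
  expect_equal(t1$ni, 1)
  # one run, half the epochs high
  t2 <- compute_ni(fake_lopo(matrix(c(0, 1, 1, 0), 4, 1), trials = rep(1, 4)))
  expect_equal(t2$ni, 0.5)
  expect_equal(t2$n_epochs, 4L)
  # two runs with per-run NI 0.5 and 0.75: averaging orders commute
  preds <- cbind(c(0, 1, 1, 0), c(1, 1, 1, 0))
  t3 <- compute_ni(fake_lopo(preds, trials = rep(1, 4)))
  expect_equal(t3$ni, 0.625)
  per_run_ni <- colMeans(preds)
  expect_equal(t3$ni, mean(per_run_ni))
  # bounds hold for arbitrary prediction matrices
  withr::with_seed(1, {
    pr <- matrix(rbinom(60, 1, 0.4), 20, 3)
    tr <- rep(1:5, each = 4)
  })
  t4 <- compute_ni(fake_lopo(pr, trials = tr))
  expect_true(all(t4$ni >= 0 & t4$ni <= 1))
  # single-run NI times epoch count is an integer count of class-1 epochs
  t5 <- compute_ni(fake_lopo(pr[, 1, drop = FALSE], trials = tr))
  expect_equal(t5$ni * t5$n_epochs, round(t5$ni * t5$n_epochs))
})

test_that("block NI is the unweighted mean of trial NIs", {
  trace <- tibble::tibble(
    participant_id = "P", trial_index = 1:6,
    block_index = rep(1L, 6),
    n_epochs = c(10L, 1L, 1L, 1L, 1L, 1L),
    ni = c(0, 0, 0, 1, 1, 1)
  )
  expect_equal(block_ni(trace)$ni_block, 0.5)
  # epoch weighting is the documented alternative
  expect_equal(
    block_ni(trace, epoch_weighted = TRUE)$ni_block,
    sum(trace$ni * trace$n_epochs) / sum(trace$n_epochs)
  )
  const <- dplyr::mutate(trace,
    ni = 0.42,
    block_index = rep(1:2, each = 3)
  )
  expect_equal(block_ni(const)$ni_block, c(0.42, 0.42))
})

test_that("trend regression recovers exact linear trends and flags null ones", {
  blocks <- dplyr::mutate(
    tidyr::expand_grid(
      participant_id = sprintf("P%02d", 1:5),
      block_index = 1:10
    ),
    ni_block = 0.1 * block_index
  )
  tr <- trend_regression(blocks)
  expect_equal(tr$slope_per_block, 0.1, tolerance = 1e-8)
  expect_lt(tr$p_value, 1e-6)
  td <- tidy(tr)
  expect_equal(td$estimate, tr$slope_per_block)
  expect_equal(glance(tr)$n_participants, 5)

  # participant-specific constants: no block effect
  flat <- dplyr::mutate(
    tidyr::expand_grid(
      participant_id = sprintf("P%02d", 1:5),
      block_index = 1:10
    ),
    ni_block = 0.1 * as.integer(factor(participant_id))
  )
  tr0 <- trend_regression(flat)
  expect_lt(abs(tr0$slope_per_block), 1e-8)
  expect_gt(tr0$p_value, 0.05)

  # noisy case through the mixed model proper
  noisy <- withr::with_seed(2, dplyr::mutate(blocks,
    ni_block = ni_block + rnorm(dplyr::n(), sd = 0.05) +
      rep(rnorm(5, sd = 0.1), each = 10)
  ))
  trn <- trend_regression(noisy)
  expect_equal(trn$method, "lmer")
  expect_equal(trn$slope_per_block, 0.1, tolerance = 0.25)
  expect_lt(trn$p_value, 0.001)

  expect_error(trend_regression(blocks[blocks$participant_id == "P01", ]), "2 participants")
  expect_error(trend_regression(blocks[blocks$block_index < 3, ]), "3 blocks")
})

test_that("NI correlations with behavior cover both scopes and both measures", {
  n <- 60
  withr::with_seed(4, {
    cert <- pmin(10, pmax(1, round(seq(1, 10, length.out = n) + rnorm(n, sd = 0.5))))
    ni <- (cert - 1) / 9 # affine in certainty: r = 1
    beh <- tibble::tibble(
      participant_id = "P01", trial_index = 1:n,
      certainty_rating = cert,
      time_performance_pct = 100 * exp(-seq_len(n) / 20) + rnorm(n, sd = 2)
    )
    trace <- tibble::tibble(
      participant_id = "P01", trial_index = 1:n, block_index = rep(1:10, each = 6),
      n_epochs = 5L, ni = ni
    )
  })
  ct <- ni_correlations(trace, beh)
  expect_equal(nrow(ct), 4)
  expect_setequal(ct$scope, c("all", "extremes"))
  expect_equal(ct$r[ct$measure == "certainty" & ct$scope == "all"], 1)
  expect_equal(ct$n[ct$scope == "extremes"], rep(24, 2)) # first + last 20%
  expect_lt(ct$r[ct$measure == "time" & ct$scope == "all"], 0)
  expect_true(all(ct$r >= -1 & ct$r <= 1))

  # independent NI: correlations are small for most seeds
  hits <- 0
  for (seed in 1:20) {
    tr2 <- withr::with_seed(seed, dplyr::mutate(trace, ni = runif(n)))
    r <- ni_correlations(tr2, beh)
    r_all <- r$r[r$measure == "certainty" & r$scope == "all"]
    if (abs(r_all) < 0.4) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("feature histograms conserve the k x n_runs selection total", {
  feats <- toy_features(shift = 3)
  res <- lopo_run(feats, "S01", n_runs = 7, k = 3, seed = 2)
  h <- feature_histogram(res, montage = montage_subset())
  expect_equal(sum(h$count), 7 * 3)
  expect_true(all(h$band == "band")) # toy feature names f01_band
  # a degenerate result where every run selects the same features
  res2 <- res
  res2$runs$selected <- rep(list(c("O1_alpha_high", "Oz_alpha_low1", "Pz_theta")), 7)
  h2 <- feature_histogram(res2)
  expect_equal(sort(unique(h2$count)), 7)
  expect_setequal(h2$band, c("alpha_high", "alpha_low1", "theta"))
  expect_equal(h2$region[h2$channel == "Pz"], "parietal")
  expect_equal(sum(h2$count), 21)
})

test_that("effectiveness grouping follows the permutation threshold with a 1/n floor", {
  perm <- structure(list(
    test_participant = "P01", true_accuracy = 0.9,
    null_accuracies = rep(0.5, 200), p_value = 0
  ), class = "ni_permutation")
  expect_equal(classify_effectiveness(perm), "effective")
  perm$p_value <- 0.5
  expect_equal(classify_effectiveness(perm), "ineffective")
  # with n_perm = 200 the effective threshold is 1/200, not 0.001
  perm$p_value <- 1 / 250
  expect_equal(classify_effectiveness(perm), "effective")
})
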