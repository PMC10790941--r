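test_that("class balancing subsamples the larger class without replacement", {
  rows <- tibble::tibble(
    participant_id = "S01",
    epoch_id = 1:420,
    class_label = rep(c(0L, 1L), c(300, 120))
  )
  withr::with_seed(1, b <- balance_within_participant(rows))
  expect_equal(sum(b$class_label == 0), 120)
  expect_equal(sum(b$class_label == 1), 120)
  # the smaller class is untouched, the subsample is a subset of the original
  expect_setequal(b$epoch_id[b$class_label == 1], 301:420)
  expect_true(all(b$epoch_id[b$class_label == 0] %in% 1:300))
  expect_equal(anyDuplicated(b$epoch_id), 0)

  # already balanced: unchanged
  even <- rows[c(1:50, 301:350), ]
  expect_identical(balance_within_participant(even), even)

  # different seeds: same counts, generally different subsets
  withr::with_seed(2, b2 <- balance_within_participant(rows))
  expect_equal(nrow(b2), nrow(b))
  expect_false(identical(b$epoch_id, b2$epoch_id))

  expect_error(
    balance_within_participant(rows[rows$class_label == 0, ]),
    "both classes"
  )
})

test_that("linear SVM separates point clouds and respects label symmetry", {
  withr::with_seed(3, {
    x <- rbind(
      matrix(rnorm(100, mean = -3, sd = 0.5), 50, 2),
      matrix(rnorm(100, mean = 3, sd = 0.5), 50, 2)
    )
  })
  d <- tibble::tibble(a = x[, 1], b = x[, 2], class_label = rep(0:1, each = 50))
  fit <- train_linear_svm(d, c("a", "b"))
  expect_equal(predict(fit, d), d$class_label)

  flipped <- dplyr::mutate(d, class_label = 1L - class_label)
  fit2 <- train_linear_svm(flipped, c("a", "b"))
  expect_equal(predict(fit2, d), 1L - predict(fit, d))

  # duplicating the training set leaves the boundary unchanged
  fit3 <- train_linear_svm(dplyr::bind_rows(d, d), c("a", "b"))
  probe <- tibble::tibble(a = rnorm(50, sd = 4), b = rnorm(50, sd = 4))
  expect_equal(predict(fit3, probe), predict(fit, probe))

  expect_error(train_linear_svm(d[1:50, ], c("a", "b")), "both classes")
})

test_that("block-extremes accuracy scores first-block 0s and last-block 1s", {
  expect_equal(block_extremes_accuracy(c(0, 0, 1, 1), c(1, 1, 10, 10)), 1)
  # degenerate all-0 predictor: accuracy is the share of first-block epochs
  expect_equal(
    block_extremes_accuracy(rep(0, 10), rep(c(1, 10), each = 5)),
    0.5
  )
  # 85% of block-1 epochs predicted 0 and 81% of block-10 predicted 1 with
  # equal epoch counts gives 83% overall
  pred <- c(rep(0, 85), rep(1, 15), rep(1, 81), rep(0, 19))
  blk <- rep(c(1, 10), each = 100)
  expect_equal(block_extremes_accuracy(pred, blk), 0.83)
  # middle blocks are ignored
  expect_equal(
    block_extremes_accuracy(c(0, 1, 1), c(1, 5, 10)),
    1
  )
})

test_that("LOPO runs keep the test data fixed, rebalance each run and count selections", {
  feats <- toy_features(shift = 3)
  res <- lopo_run(feats, "S01", n_runs = 5, k = 3, seed = 9)
  expect_equal(nrow(res$runs), 5)
  expect_true(all(vapply(res$runs$selected, length, integer(1)) == 3))
  expect_true(all(vapply(res$runs$selected, anyDuplicated, integer(1)) == 0))
  expect_equal(nrow(res$predictions), sum(feats$participant_id == "S01"))
  expect_false(anyNA(res$predictions))
  # informative features dominate the selections
  expect_true(mean(unlist(res$runs$selected) %in% c("f01_band", "f02_band", "f03_band")) > 0.5)
  # planted effect: strong block-extremes accuracy for every run
  expect_true(all(res$runs$block_extremes_accuracy > 0.9))

  # reproducibility and fixed-test contract
  res_b <- lopo_run(feats, "S01", n_runs = 5, k = 3, seed = 9)
  expect_identical(res$predictions, res_b$predictions)
  res_c <- lopo_run(feats, "S01", n_runs = 1, k = 3, seed = 10)
  expect_identical(res_c$test_meta, res$test_meta)

  expect_error(lopo_run(feats, "nope", n_runs = 1), "unknown participant")
})

test_that("no training row of the held-out participant influences the model", {
  feats <- toy_features(shift = 3)
  perturbed <- feats
  cols <- nitrack:::feature_names(feats)
  is_test <- perturbed$participant_id == "S02"
  perturbed[is_test, cols] <- perturbed[is_test, cols] * 5 + 100
  a <- lopo_run(feats, "S02", n_runs = 3, k = 3, seed = 4, keep_models = TRUE)
  b <- lopo_run(perturbed, "S02", n_runs = 3, k = 3, seed = 4, keep_models = TRUE)
  expect_identical(a$runs$selected, b$runs$selected)
  probe <- feats[feats$participant_id == "S01", ]
  for (r in 1:3) {
    expect_identical(
      predict(a$models[[r]], probe),
      predict(b$models[[r]], probe)
    )
  }
})

test_that("permutation p-values follow the null-proportion definition", {
  feats <- toy_features(shift = 3)
  # separable cohort: true accuracy 1 beats every permuted-label accuracy
  pt <- permutation_test(feats, "S01",
    n_perm = 30, n_runs_null = 1, k = 3,
    seed = 5, true_accuracy = 1
  )
  expect_length(pt$null_accuracies, 30)
  expect_true(all(pt$null_accuracies >= 0 & pt$null_accuracies <= 1))
  expect_equal(pt$p_value, mean(pt$null_accuracies >= 1))
  expect_lt(pt$p_value, 0.1)
  # a true accuracy at the floor is beaten by every permutation
  pt0 <- permutation_test(feats, "S01",
    n_perm = 10, n_runs_null = 1, k = 3,
    seed = 5, true_accuracy = 0
  )
  expect_equal(pt0$p_value, 1)
  expect_error(
    permutation_test(feats, "S01", n_perm = 0, true_accuracy = 1),
    "n_perm"
  )
})
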