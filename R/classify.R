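# Subject-independent classification: per-participant class balancing,
# mRMR + linear SVM per run, leave-one-participant-out evaluation and the
# label-permutation null.

#' Balance the two proficiency classes within one participant
#'
#' Subsamples the larger class (without replacement) down to the size of the
#' smaller class; the smaller class is kept untouched. Never upsamples.
#'
#' @param rows Tibble of one participant's labeled epochs (`class_label`
#'   0/1).
#' @return Tibble with equal class counts.
#' @export
balance_within_participant <- function(rows) {
  n0 <- sum(rows$class_label == 0L)
  n1 <- sum(rows$class_label == 1L)
  if (n0 == 0 || n1 == 0) abort("both classes must be present to balance")
  n <- min(n0, n1)
  keep0 <- which(rows$class_label == 0L)
  keep1 <- which(rows$class_label == 1L)
  if (n0 > n) keep0 <- sort(sample(keep0, n))
  if (n1 > n) keep1 <- sort(sample(keep1, n))
  rows[sort(c(keep0, keep1)), , drop = FALSE]
}

#' Train a linear SVM on selected features
#'
#' Standardizes the selected features with training-set mean/sd, then fits a
#' linear-kernel SVM (via e1071/libsvm) with cost `C`.
#'
#' @param training_rows Tibble of balanced labeled epochs.
#' @param selected_features Character vector of feature columns to use.
#' @param C Regularization constant (default 1).
#' @return A `ni_svm`: list with the fitted model, feature names and the
#'   standardization statistics.
#' @export
train_linear_svm <- function(training_rows, selected_features, C = 1) {
  y <- factor(training_rows$class_label, levels = c(0L, 1L))
  if (length(unique(training_rows$class_label)) < 2) {
    abort("training data must contain both classes")
  }
  x <- as.matrix(training_rows[, selected_features, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fit <- e1071::svm(xs, y, kernel = "linear", cost = C, scale = FALSE)
  structure(
    list(fit = fit, features = selected_features, center = center, scale = scale_),
    class = "ni_svm"
  )
}

#' Predict proficiency classes for epochs
#'
#' @param object A `ni_svm` from [train_linear_svm()].
#' @param newdata Tibble or matrix containing the model's feature columns.
#' @param ... Unused.
#' @return Integer vector of predicted classes (0/1).
#' @export
predict.ni_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.integer(as.character(predict(object$fit, xs)))
}

#' Accuracy on the extreme blocks
#'
#' Scores epochs of the first block as correct when predicted class 0 and
#' epochs of the last block as correct when predicted class 1; the accuracy
#' is the fraction correct over the two blocks pooled.
#'
#' @param predictions Integer vector of predicted classes (0/1) per epoch.
#' @param block_index Integer vector of the epochs' block indices.
#' @param first_block,last_block Block indices scored (defaults: min and max
#'   of `block_index`).
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' block_extremes_accuracy(c(0, 0, 1, 1), c(1, 1, 10, 10)) # 1
block_extremes_accuracy <- function(predictions, block_index,
                                    first_block = min(block_index),
                                    last_block = max(block_index)) {
  lo <- block_index == first_block
  hi <- block_index == last_block
  correct <- sum(predictions[lo] == 0L) + sum(predictions[hi] == 1L)
  correct / (sum(lo) + sum(hi))
}

# one classification run: balance each training participant, select
# features, fit, predict the (fixed) test epochs.
run_once <- function(train_labeled, test_rows, feat_names, k, C, bins) {
  balanced <- train_labeled %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::group_modify(~ balance_within_participant(.x)) %>%
    dplyr::ungroup()
  selected <- mrmr_select(
    as.matrix(balanced[, feat_names, drop = FALSE]),
    balanced$class_label,
    k = k, bins = bins
  )
  model <- train_linear_svm(balanced, selected, C = C)
  list(
    selected = selected,
    model = model,
    predictions = predict(model, test_rows)
  )
}

#' Leave-one-participant-out classification runs
#'
#' Holds out one participant and runs the classification `n_runs` times.
#' Each run freshly rebalances every training participant's classes (a new
#' random subsample), reruns mRMR on the balanced pool, refits the linear
#' SVM and predicts every epoch of the held-out participant. The test data
#' are identical across runs; no test-participant row enters feature
#' selection or training.
#'
#' @param features Labeled cohort feature table from [cohort_features()].
#' @param test_participant Participant id to hold out.
#' @param n_runs Number of runs (default 100).
#' @param k Features per run (default 10).
#' @param C SVM cost (default 1).
#' @param bins mRMR discretization bins (default 3).
#' @param seed Master seed; each run draws from its own derived stream.
#' @param keep_models Keep the per-run fitted models (default FALSE).
#' @return A `lopo_result`: list with `test_participant`, `runs` (tibble of
#'   run index, selected features list-column and block-extremes accuracy),
#'   `predictions` (epochs x runs integer matrix), `test_meta` (epoch
#'   annotations) and optionally `models`.
#' @export
lopo_run <- function(features, test_participant, n_runs = 100, k = 10,
                     C = 1, bins = 3, seed = 1, keep_models = FALSE) {
  ids <- unique(features$participant_id)
  if (!test_participant %in% ids) {
    abort(sprintf("unknown participant '%s'", test_participant))
  }
  if (length(ids) < 2) abort("need at least two participants")
  feat_names <- feature_names(features)
  is_test <- features$participant_id == test_participant
  test_rows <- features[is_test, , drop = FALSE]
  train_labeled <- features[!is_test & !is.na(features$class_label), , drop = FALSE]

  p_idx <- match(test_participant, sort(ids))
  runs <- vector("list", n_runs)
  predictions <- matrix(NA_integer_, nrow(test_rows), n_runs)
  models <- if (keep_models) vector("list", n_runs) else NULL

  for (r in seq_len(n_runs)) {
    res <- with_stream(seed, p_idx, r, expr = {
      run_once(train_labeled, test_rows, feat_names, k, C, bins)
    })
    predictions[, r] <- res$predictions
    runs[[r]] <- tibble(
      run = r,
      selected = list(res$selected),
      block_extremes_accuracy = block_extremes_accuracy(
        res$predictions, test_rows$block_index
      )
    )
    if (keep_models) models[[r]] <- res$model
  }

  structure(list(
    test_participant = test_participant,
    runs = dplyr::bind_rows(runs),
    predictions = predictions,
    test_meta = test_rows[, c(
      "participant_id", "trial_index", "block_index", "epoch_index", "class_label"
    )],
    models = models
  ), class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf(
    "<lopo_result> held-out %s: %d runs, %d test epochs, mean block-extremes accuracy %.3f\n",
    x$test_participant, nrow(x$runs), nrow(x$test_meta),
    mean(x$runs$block_extremes_accuracy)
  ))
  invisible(x)
}

#' Run the LOPO evaluation for every participant
#'
#' @inheritParams lopo_run
#' @return Named list of `lopo_result`, one per participant.
#' @export
lopo_all <- function(features, n_runs = 100, k = 10, C = 1, bins = 3, seed = 1) {
  ids <- sort(unique(features$participant_id))
  out <- lapply(ids, function(id) {
    lopo_run(features, id, n_runs = n_runs, k = k, C = C, bins = bins, seed = seed)
  })
  names(out) <- ids
  out
}

#' Permutation-null significance of a participant's accuracy
#'
#' Builds a null distribution of block-extremes accuracies by shuffling the
#' proficiency class labels within each training participant's labeled
#' epochs (label counts preserved) and rerunning the identical balanced
#' mRMR + SVM procedure. The held-out participant's block-1/last-block
#' scoring is fixed by block membership. The p-value is the proportion of
#' null accuracies greater than or equal to the true accuracy.
#'
#' @inheritParams lopo_run
#' @param n_perm Number of permutations (default 1000).
#' @param n_runs_null Runs per permutation (default 1; the full 100-run
#'   average is only needed for the true statistic).
#' @param true_accuracy Observed mean block-extremes accuracy; computed from
#'   a fresh [lopo_run()] with `n_runs_true` runs when omitted.
#' @param n_runs_true Runs for the true statistic when it must be computed
#'   (default 100).
#' @return A `ni_permutation`: list with `test_participant`,
#'   `true_accuracy`, `null_accuracies` and `p_value`.
#' @export
permutation_test <- function(features, test_participant, n_perm = 1000,
                             n_runs_null = 1, k = 10, C = 1, bins = 3,
                             seed = 1, true_accuracy = NULL,
                             n_runs_true = 100) {
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  if (is.null(true_accuracy)) {
    true_res <- lopo_run(features, test_participant,
      n_runs = n_runs_true,
      k = k, C = C, bins = bins, seed = seed
    )
    true_accuracy <- mean(true_res$runs$block_extremes_accuracy)
  }
  feat_names <- feature_names(features)
  is_test <- features$participant_id == test_participant
  test_rows <- features[is_test, , drop = FALSE]
  train_labeled <- features[!is_test & !is.na(features$class_label), , drop = FALSE]
  p_idx <- match(test_participant, sort(unique(features$participant_id)))

  null_acc <- vapply(seq_len(n_perm), function(j) {
    with_stream(seed, p_idx, 100000 + j, expr = {
      shuffled <- train_labeled %>%
        dplyr::group_by(.data$participant_id) %>%
        dplyr::mutate(class_label = sample(.data$class_label)) %>%
        dplyr::ungroup()
      accs <- vapply(seq_len(n_runs_null), function(r) {
        res <- run_once(shuffled, test_rows, feat_names, k, C, bins)
        block_extremes_accuracy(res$predictions, test_rows$block_index)
      }, numeric(1))
      mean(accs)
    })
  }, numeric(1))

  structure(list(
    test_participant = test_participant,
    true_accuracy = true_accuracy,
    null_accuracies = null_acc,
    p_value = mean(null_acc >= true_accuracy)
  ), class = "ni_permutation")
}

#' @export
print.ni_permutation <- function(x, ...) {
  cat(sprintf(
    "<ni_permutation> %s: true accuracy %.3f vs %d-permutation null (mean %.3f), p = %.4g\n",
    x$test_participant, x$true_accuracy, length(x$null_accuracies),
    mean(x$null_accuracies), x$p_value
  ))
  invisible(x)
}
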