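# 1-s epoch feature tables and proficiency class labels.

#' Percent time performance relative to an ideal
#'
#' `100 * (trial_time - ideal_time) / ideal_time`: 0 means ideal, positive
#' means slower than ideal.
#'
#' @param trial_time,ideal_time Times in seconds; `ideal_time > 0`.
#' @return Percent difference (vectorized).
#' @export
#' @examples
#' time_performance(120, 100) # 20
time_performance <- function(trial_time, ideal_time) {
  if (any(ideal_time <= 0)) abort("`ideal_time` must be positive")
  100 * (trial_time - ideal_time) / ideal_time
}

#' Per-trial behavior table
#'
#' Augments a session's behavior records with the percent time performance
#' and the completion order.
#'
#' @param behavior Tibble with columns `trial_index`, `certainty_rating`,
#'   `trial_time_s`, `ideal_time_s` (as produced by [simulate_cohort()]).
#' @return Tibble with added `time_performance_pct` and `completion_order`.
#' @export
behavior_table <- function(behavior) {
  behavior %>%
    dplyr::mutate(
      time_performance_pct = time_performance(.data$trial_time_s, .data$ideal_time_s),
      completion_order = rank(.data$trial_index, ties.method = "first")
    )
}

#' Rank trials by self-reported certainty
#'
#' Trials are ordered by increasing certainty rating, ties broken by
#' completion order (a single stable sort). The head of the ranking holds
#' the least-certain trials, the tail the most certain; within ties at the
#' top, later completion ranks higher.
#'
#' @param behavior Tibble with one row per trial and columns
#'   `trial_index` and `certainty_rating` (and optionally
#'   `completion_order`, defaulting to trial order).
#' @return Integer vector of trial indices, a permutation of
#'   `behavior$trial_index`.
#' @export
#' @examples
#' b <- tibble::tibble(trial_index = 1:3, certainty_rating = c(3, 1, 2))
#' rank_trials(b) # 2 3 1
rank_trials <- function(behavior) {
  if (anyNA(behavior$certainty_rating)) {
    bad <- behavior$trial_index[is.na(behavior$certainty_rating)]
    abort(sprintf("missing certainty rating for trial(s) %s", paste(bad, collapse = ", ")))
  }
  co <- behavior[["completion_order"]] %||% behavior$trial_index
  behavior$trial_index[order(behavior$certainty_rating, co)]
}

#' Assign proficiency class labels from ranked trials
#'
#' The bottom 10% of the certainty ranking becomes class 0 ("low
#' proficiency"), the top 10% class 1 ("high proficiency"), everything in
#' between stays unlabeled. With `n_trials` not divisible by ten the class
#' size is `floor(0.10 * n_trials)`, at least 2.
#'
#' @param ranked Trial indices in increasing-certainty order, from
#'   [rank_trials()].
#' @param n_trials Total number of trials (defaults to `length(ranked)`).
#' @param fraction Fraction per class (default 0.10).
#' @return Tibble with columns `trial_index` and `class_label`
#'   (integer 0/1/NA), one row per trial.
#' @export
#' @examples
#' assign_classes(rank_trials(tibble::tibble(
#'   trial_index = 1:60, certainty_rating = rep(1:10, each = 6)
#' )))
assign_classes <- function(ranked, n_trials = length(ranked), fraction = 0.10) {
  n_class <- max(2L, floor(fraction * n_trials))
  if (2L * n_class > n_trials) {
    abort(sprintf("cannot label %d trials per class out of %d trials", n_class, n_trials))
  }
  tibble(
    trial_index = ranked,
    class_label = c(
      rep(0L, n_class),
      rep(NA_integer_, n_trials - 2L * n_class),
      rep(1L, n_class)
    )
  ) %>% dplyr::arrange(.data$trial_index)
}

#' Epoch a power session into the feature table
#'
#' Cuts every navigation trial into contiguous, non-overlapping 1-s epochs
#' (256 samples; the trailing partial second is discarded) and takes the
#' mean z-scored power per epoch for every montage channel and band:
#' `41 channels x 4 bands = 164` feature columns named `<channel>_<band>`.
#'
#' @param power_session A `power_session` from [preprocess_session()].
#' @param montage Analysis montage (must match the session's channels).
#' @return Tibble, one row per epoch: `participant_id`, `trial_index`,
#'   `block_index`, `epoch_index` (within trial), then the 164 features.
#' @export
epoch_features <- function(power_session, montage = montage_subset()) {
  stopifnot(inherits(power_session, "power_session"))
  fs <- power_session$fs
  nav <- power_session$segments %>% dplyr::filter(.data$segment_kind == "navigation")

  n_ep <- as.integer((nav$end_sample - nav$start_sample + 1L) %/% fs)
  if (any(n_ep == 0)) {
    warn(sprintf(
      "trial(s) %s shorter than 1 s produce no epochs",
      paste(nav$trial_index[n_ep == 0], collapse = ", ")
    ))
  }
  # row indices of every epoch sample, trial by trial
  idx <- unlist(lapply(seq_len(nrow(nav)), function(i) {
    if (n_ep[i] == 0) return(integer(0))
    seq(nav$start_sample[i], length.out = n_ep[i] * fs)
  }))
  n_epochs_total <- sum(n_ep)
  groups <- rep(seq_len(n_epochs_total), each = fs)

  feat <- lapply(names(power_session$power), function(band) {
    p <- power_session$power[[band]][idx, montage$channel, drop = FALSE]
    means <- rowsum(p, groups, reorder = FALSE) / fs
    colnames(means) <- paste(montage$channel, band, sep = "_")
    means
  })
  feat <- do.call(cbind, feat)

  meta <- tibble(
    participant_id = power_session$participant_id,
    trial_index = rep(nav$trial_index, n_ep),
    block_index = rep(nav$block_index, n_ep),
    epoch_index = unlist(lapply(n_ep, seq_len))
  )
  dplyr::bind_cols(meta, as_tibble(feat))
}

#' Feature table with class labels for a whole cohort
#'
#' Convenience wrapper: preprocesses every session, epochs it, ranks trials
#' by certainty, assigns proficiency classes and binds everything into one
#' labeled feature table ready for classification.
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()] (or any list of
#'   `eeg_session` objects).
#' @param montage Analysis montage.
#' @param ... Passed on to [preprocess_session()].
#' @return Tibble: one row per epoch with `participant_id`, `trial_index`,
#'   `block_index`, `epoch_index`, `class_label` and the 164 features; the
#'   per-trial behavior (with `time_performance_pct`) is attached as
#'   attribute `"behavior"`.
#' @export
cohort_features <- function(cohort, montage = montage_subset(), ...) {
  per <- lapply(cohort, function(session) {
    ps <- preprocess_session(session, montage = montage, ...)
    feats <- epoch_features(ps, montage = montage)
    beh <- behavior_table(session$behavior)
    labels <- assign_classes(rank_trials(beh))
    list(
      features = dplyr::left_join(feats, labels, by = "trial_index") %>%
        dplyr::relocate("class_label", .after = "epoch_index"),
      behavior = dplyr::mutate(beh, participant_id = session$participant_id, .before = 1),
      iaf = ps$iaf
    )
  })
  out <- dplyr::bind_rows(lapply(per, `[[`, "features"))
  attr(out, "behavior") <- dplyr::bind_rows(lapply(per, `[[`, "behavior"))
  attr(out, "iaf") <- vapply(per, `[[`, numeric(1), "iaf")
  out
}

# column names of the feature block of a table
feature_names <- function(features) {
  setdiff(
    names(features),
    c("participant_id", "trial_index", "block_index", "epoch_index", "class_label")
  )
}
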