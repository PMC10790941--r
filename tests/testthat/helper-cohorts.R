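# Shared synthetic fixtures, generated once per session and cached.
# Desk-preset cohorts are the expensive ones; every test that can share a
# cohort does so through these helpers.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# desk-preset cohort spec with a forced responder mix
desk_spec <- function(kind = c("mixed", "responders", "flat")) {
  kind <- match.arg(kind)
  frac <- switch(kind, mixed = 4 / 6, responders = 1, flat = 0)
  nitrack:::config_to_spec(pipeline_config("desk",
    responder_fraction = frac,
    nonresponder_decreasing_fraction = 0
  ))
}

# labeled feature table of a desk cohort (cached per kind/seed). For the
# shared responder seed the first participant's power session is computed
# from the same cohort and cached alongside, so the cohort (large) is
# simulated once and never retained.
desk_features <- function(kind, seed) {
  cache_get(sprintf("feat_%s_%d", kind, seed), function() {
    cohort <- simulate_cohort(desk_spec(kind), seed = seed)
    if (kind == "responders" && seed == 101) {
      assign(sprintf("power_%d", seed), preprocess_session(cohort[[1]]),
        envir = .fixture_cache
      )
    }
    cohort_features(cohort)
  })
}

# one preprocessed desk session (cached; shares the seed-101 cohort above)
desk_power_session <- function(seed = 101) {
  if (!exists(sprintf("power_%d", seed), envir = .fixture_cache)) {
    desk_features("responders", seed)
  }
  get(sprintf("power_%d", seed), envir = .fixture_cache)
}

# a short single-participant session for structural tests (fast: ~90 s of
# signal); plateau after the first of two blocks
tiny_session <- function(seed = 5, profile_responder = TRUE) {
  cache_get(sprintf("tiny_%d_%d", seed, profile_responder), function() {
    spec <- cohort_spec(
      n_participants = 1,
      responder_fraction = as.numeric(profile_responder),
      n_trials = 8, block_size = 4,
      baseline_duration = 30,
      ideal_time_range = c(5, 7), max_trial_duration = 20,
      certainty = trajectory_params(plateau_block = 1, noise_sd = 0.5),
      time_excess = trajectory_params(plateau_block = 1, noise_sd = 5)
    )
    simulate_cohort(spec, seed = seed)[[1]]
  })
}

# hand-built power_session with constant per-band values, for exact epoch
# arithmetic checks without any signal processing
constant_power_session <- function(trial_lens_s, value = 1, fs = 256,
                                   montage = montage_subset()) {
  n_nav <- sum(round(trial_lens_s * fs))
  n_base <- 31 * fs
  n <- n_base + n_nav
  ends <- n_base + cumsum(round(trial_lens_s * fs))
  starts <- c(n_base + 1, head(ends, -1) + 1)
  segments <- tibble::tibble(
    segment_kind = c("eyes_open", rep("navigation", length(trial_lens_s))),
    trial_index = c(NA, seq_along(trial_lens_s)),
    baseline_index = c(1L, rep(NA, length(trial_lens_s))),
    block_index = c(NA, rep(1L, length(trial_lens_s))),
    start_sample = c(1L, as.integer(starts)),
    end_sample = c(as.integer(n_base), as.integer(ends))
  )
  bands <- define_bands(10)
  power <- lapply(bands$bands, function(b) {
    m <- matrix(value, n, nrow(montage))
    colnames(m) <- montage$channel
    m
  })
  structure(list(
    participant_id = "T01", is_responder = TRUE, fs = fs,
    channels = montage$channel, iaf = 10, bands = bands,
    power = power, segments = segments,
    behavior = tibble::tibble(
      trial_index = seq_along(trial_lens_s),
      block_index = 1L,
      certainty_rating = seq_along(trial_lens_s),
      trial_time_s = trial_lens_s,
      ideal_time_s = trial_lens_s
    )
  ), class = "power_session")
}

# minimal lopo_result for NI arithmetic tests: predictions is an
# epochs x runs matrix, trials gives the trial index of each epoch
fake_lopo <- function(predictions, trials, blocks = NULL) {
  predictions <- as.matrix(predictions)
  if (is.null(blocks)) blocks <- rep(1L, length(trials))
  structure(list(
    test_participant = "T01",
    runs = tibble::tibble(
      run = seq_len(ncol(predictions)),
      selected = list(character(0)),
      block_extremes_accuracy = NA_real_
    ),
    predictions = predictions,
    test_meta = tibble::tibble(
      participant_id = "T01",
      trial_index = as.integer(trials),
      block_index = as.integer(blocks),
      epoch_index = stats::ave(seq_along(trials), trials, FUN = seq_along),
      class_label = NA_integer_
    ),
    models = NULL
  ), class = "lopo_result")
}

# gaussian feature table with a class-dependent mean shift on some
# features: fast stand-in for testing the classification machinery without
# signal processing. Trials of 4 epochs; first/last blocks labeled.
toy_features <- function(n_participants = 4, n_trials = 12, block_size = 3,
                         n_features = 12, n_informative = 3, shift = 2,
                         seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      for (tr in seq_len(n_trials)) {
        block <- (tr - 1) %/% block_size + 1
        n_ep <- 4
        # latent proficiency rises with trial
        prof <- (tr - 1) / (n_trials - 1)
        x <- matrix(rnorm(n_ep * n_features), n_ep, n_features)
        x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift * prof
        colnames(x) <- sprintf("f%02d_band", seq_len(n_features))
        cls <- if (tr <= 2) 0L else if (tr > n_trials - 2) 1L else NA_integer_
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(
            participant_id = sprintf("S%02d", p),
            trial_index = tr, block_index = block,
            epoch_index = seq_len(n_ep), class_label = cls
          ),
          tibble::as_tibble(x)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
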