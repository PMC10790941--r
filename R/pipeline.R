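# End-to-end orchestration: configuration presets, stage-by-stage execution
# with on-disk artifacts, a manifest with the config hash, and resumability.

#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline in one flat list. Two presets are
#' built in: `"paper"` — the full study geometry (15 participants, 60 trials
#' in 10 blocks of 6, 1-min baselines, 100 runs, 1000 permutations; hours of
#' compute) — and `"desk"` — a scaled-down geometry for interactive use and
#' testing (6 participants, 20 trials in 4 blocks of 5, 35-s baselines, 30-s
#' trial cap, 10 runs, 50 permutations; minutes).
#'
#' @param preset `"desk"` (default) or `"paper"`.
#' @param ... Named overrides of any config entry.
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config("desk", seed = 42)
#' cfg$n_runs
pipeline_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    n_participants = 15L, responder_fraction = 9 / 15,
    n_trials = 60L, block_size = 6L,
    sampling_rate = 500, max_trial_duration = 180, baseline_duration = 60,
    iaf_min = 8.5, iaf_max = 12.5,
    alpha_effect_size = 2, noise_exponent = 1,
    ideal_time_min = 15, ideal_time_max = 40,
    nonresponder_decreasing_fraction = 0.5,
    plateau_block = 7L,
    epoch_s = 1, k = 10L, n_runs = 100L, n_perm = 1000L, n_runs_null = 1L,
    svm_cost = 1, mrmr_bins = 3L, extreme_fraction = 0.10,
    montage_path = NA_character_,
    seed = 1L
  )
  if (preset == "desk") {
    base[c(
      "n_participants", "responder_fraction", "n_trials", "block_size",
      "baseline_duration", "max_trial_duration", "ideal_time_min",
      "ideal_time_max", "plateau_block", "n_runs", "n_perm"
    )] <- list(6L, 4 / 6, 20L, 5L, 35, 30, 8, 15, 3L, 10L, 50L)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    abort(paste0("unknown config entries: ", paste(unknown, collapse = ", ")))
  }
  base[names(over)] <- over
  cfg <- structure(base, class = "pipeline_config")
  config_to_spec(cfg) # validates
  cfg
}

config_to_spec <- function(cfg) {
  cohort_spec(
    n_participants = cfg$n_participants,
    responder_fraction = cfg$responder_fraction,
    n_trials = cfg$n_trials,
    block_size = cfg$block_size,
    sampling_rate = cfg$sampling_rate,
    max_trial_duration = cfg$max_trial_duration,
    baseline_duration = cfg$baseline_duration,
    iaf_range = c(cfg$iaf_min, cfg$iaf_max),
    alpha_effect_size = cfg$alpha_effect_size,
    noise_exponent = cfg$noise_exponent,
    ideal_time_range = c(cfg$ideal_time_min, cfg$ideal_time_max),
    nonresponder_decreasing_fraction = cfg$nonresponder_decreasing_fraction,
    certainty = trajectory_params(
      plateau_block = cfg$plateau_block, noise_sd = 0.8
    ),
    time_excess = trajectory_params(
      plateau_block = cfg$plateau_block, noise_sd = 8
    )
  )
}

#' Read / write pipeline configuration as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly. The round-trip is lossless.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(preset = raw$preset), raw[setdiff(names(raw), "preset")]))
}

config_hash <- function(cfg) {
  # dependency-free stable hash of the flat config (FNV-1a over the
  # serialized key=value lines)
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","),
    character(1)
  ), sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  # polynomial rolling hash in exact double arithmetic (mod 2^31 - 1)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' simulate -> preprocess/features -> classify -> indicator/statistics, with
#' each stage's artifacts written under `out_dir` and recorded in a manifest
#' carrying the config hash. Completed stages (matching hash) are skipped on
#' rerun; the same config and seed reproduce identical outputs.
#'
#' Stages and artifacts:
#' * `simulate` — `edf/` (one EDF per participant) + `edf/sessions.csv`
#' * `features` — `features.csv` (epoch x feature table with labels),
#'   `behavior.csv`, `iaf.csv`
#' * `classify` — `runs.csv` (per run: participant, run, accuracy, selected
#'   features), `predictions.csv` (per epoch mean predicted class),
#'   `permutation.json` (per participant: true accuracy, null summary, p)
#' * `stats` — `ni_trial.csv`, `ni_block.csv`, `trend.json`,
#'   `correlations.csv`, `feature_histogram.csv`
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Stages to run (default all, in order).
#' @param run_permutations Run the permutation nulls (default TRUE; the
#'   most expensive stage component).
#' @return Invisibly, a list with the key in-memory results (`features`,
#'   `lopo`, `trace`, `blocks`, `trend`, `correlations`, `histogram`,
#'   `permutations`, `manifest`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir,
                         stages = c("simulate", "features", "classify", "stats"),
                         run_permutations = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(config_hash = hash, seed = cfg$seed, stages = list())
  }
  if (!identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = cfg$seed, stages = list())
  }
  write_config(cfg, file.path(out_dir, "config.yaml"))
  montage <- if (is.na(cfg$montage_path)) montage_subset() else montage_subset(cfg$montage_path)
  spec <- config_to_spec(cfg)

  done <- function(stage) identical(manifest$stages[[stage]], hash)
  mark <- function(stage) {
    manifest$stages[[stage]] <<- hash
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }
  say <- function(stage, msg) inform(sprintf("[%s] %s", stage, msg))

  results <- list(manifest = manifest)

  if ("simulate" %in% stages && !done("simulate")) {
    t0 <- Sys.time()
    cohort <- simulate_cohort(spec, seed = cfg$seed)
    write_cohort(cohort, file.path(out_dir, "edf"))
    say("simulate", sprintf(
      "%d sessions written in %.1f s",
      length(cohort), as.numeric(Sys.time() - t0, units = "secs")
    ))
    mark("simulate")
  }

  if ("features" %in% stages && !done("features")) {
    t0 <- Sys.time()
    cohort <- read_cohort(file.path(out_dir, "edf"))
    features <- cohort_features(cohort, montage = montage)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(attr(features, "behavior"), file.path(out_dir, "behavior.csv"))
    readr::write_csv(
      tibble(
        participant_id = vapply(cohort, `[[`, character(1), "participant_id"),
        iaf = attr(features, "iaf")
      ),
      file.path(out_dir, "iaf.csv")
    )
    say("features", sprintf(
      "%d epochs x %d features in %.1f s",
      nrow(features), length(feature_names(features)),
      as.numeric(Sys.time() - t0, units = "secs")
    ))
    mark("features")
  }

  features <- readr::read_csv(file.path(out_dir, "features.csv"), show_col_types = FALSE)
  behavior <- readr::read_csv(file.path(out_dir, "behavior.csv"), show_col_types = FALSE)

  if ("classify" %in% stages && !done("classify")) {
    t0 <- Sys.time()
    lopo <- lopo_all(features,
      n_runs = cfg$n_runs, k = cfg$k, C = cfg$svm_cost,
      bins = cfg$mrmr_bins, seed = cfg$seed
    )
    runs_tbl <- purrr::map_dfr(lopo, function(res) {
      res$runs %>%
        dplyr::mutate(
          participant_id = res$test_participant,
          selected = vapply(.data$selected, paste, character(1), collapse = ";"),
          .before = 1
        )
    })
    readr::write_csv(runs_tbl, file.path(out_dir, "runs.csv"))
    pred_tbl <- purrr::map_dfr(lopo, function(res) {
      res$test_meta %>% dplyr::mutate(mean_predicted_class = rowMeans(res$predictions))
    })
    readr::write_csv(pred_tbl, file.path(out_dir, "predictions.csv"))
    saveRDS(lopo, file.path(out_dir, "lopo.rds"))
    say("classify", sprintf(
      "%d participants x %d runs in %.1f s", length(lopo), cfg$n_runs,
      as.numeric(Sys.time() - t0, units = "secs")
    ))

    if (run_permutations) {
      t0 <- Sys.time()
      perms <- lapply(lopo, function(res) {
        permutation_test(features, res$test_participant,
          n_perm = cfg$n_perm, n_runs_null = cfg$n_runs_null,
          k = cfg$k, C = cfg$svm_cost, bins = cfg$mrmr_bins, seed = cfg$seed,
          true_accuracy = mean(res$runs$block_extremes_accuracy)
        )
      })
      jsonlite::write_json(
        lapply(perms, function(p) {
          list(
            true_accuracy = p$true_accuracy,
            null_mean = mean(p$null_accuracies),
            null_q95 = unname(quantile(p$null_accuracies, 0.95)),
            n_perm = length(p$null_accuracies),
            p_value = p$p_value,
            effectiveness = classify_effectiveness(p, alpha = 0.001)
          )
        }),
        file.path(out_dir, "permutation.json"),
        auto_unbox = TRUE, digits = NA
      )
      saveRDS(perms, file.path(out_dir, "permutations.rds"))
      say("classify", sprintf(
        "%d-permutation nulls in %.1f s", cfg$n_perm,
        as.numeric(Sys.time() - t0, units = "secs")
      ))
    }
    mark("classify")
  }

  if ("stats" %in% stages && !done("stats")) {
    t0 <- Sys.time()
    lopo <- readRDS(file.path(out_dir, "lopo.rds"))
    trace <- purrr::map_dfr(lopo, compute_ni)
    blocks <- block_ni(trace)
    trend <- trend_regression(blocks)
    correlations <- ni_correlations(trace, behavior,
      extreme_fraction = 0.2
    )
    histogram <- feature_histogram(lopo, montage = montage)
    readr::write_csv(as_tibble(trace), file.path(out_dir, "ni_trial.csv"))
    readr::write_csv(blocks, file.path(out_dir, "ni_block.csv"))
    jsonlite::write_json(
      c(tidy(trend)[1, ], glance(trend)[1, ], config_hash = hash),
      file.path(out_dir, "trend.json"),
      auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    readr::write_csv(as_tibble(histogram), file.path(out_dir, "feature_histogram.csv"))
    say("stats", sprintf("NI statistics in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
    mark("stats")

    results$trace <- trace
    results$blocks <- blocks
    results$trend <- trend
    results$correlations <- correlations
    results$histogram <- histogram
    results$lopo <- lopo
    if (run_permutations && file.exists(file.path(out_dir, "permutations.rds"))) {
      results$permutations <- readRDS(file.path(out_dir, "permutations.rds"))
    }
  }
  results$features <- features
  results$manifest <- manifest
  invisible(results)
}
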