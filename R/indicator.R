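# The per-trial neural indicator and its statistics: block aggregates,
# mixed-model trend, behavioral correlations, feature-selection histograms
# and the effective/ineffective grouping.

#' Compute the neural indicator per trial
#'
#' For each epoch the predicted class is averaged over runs; the neural
#' indicator of trial t is the mean of those per-epoch averages over the
#' trial's epochs: `NI_t = sum(cbar_i) / n_t`. Because the test set is fixed
#' across runs this equals the mean over runs of the per-run trial NI. A 95%
#' normal-approximation confidence band across runs is attached.
#'
#' @param lopo A `lopo_result` from [lopo_run()].
#' @return A `ni_trace` tibble: `participant_id`, `trial_index`,
#'   `block_index`, `n_epochs`, `ni`, `ni_lo`, `ni_hi`.
#' @export
#' @examples
#' # Eq.-style arithmetic: one run, predictions 0,1,1,0 -> NI 0.5
compute_ni <- function(lopo) {
  stopifnot(inherits(lopo, "lopo_result"))
  meta <- lopo$test_meta
  cbar <- rowMeans(lopo$predictions)
  key <- paste(meta$participant_id, meta$trial_index)
  # per-run trial NI for the CI across runs
  per_run <- rowsum(lopo$predictions, key, reorder = FALSE) /
    as.vector(table(factor(key, levels = unique(key))))
  trace <- meta %>%
    dplyr::group_by(.data$participant_id, .data$trial_index, .data$block_index) %>%
    dplyr::summarise(n_epochs = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$trial_index)
  ni <- rowsum(cbar, key, reorder = FALSE)[, 1] /
    as.vector(table(factor(key, levels = unique(key))))
  ord <- match(paste(trace$participant_id, trace$trial_index), unique(key))
  trace$ni <- as.numeric(ni[ord])
  run_sd <- apply(per_run, 1, sd)[ord]
  n_runs <- ncol(lopo$predictions)
  half <- 1.96 * run_sd / sqrt(n_runs)
  trace$ni_lo <- pmax(0, trace$ni - half)
  trace$ni_hi <- pmin(1, trace$ni + half)
  class(trace) <- c("ni_trace", class(trace))
  trace
}

#' Per-block mean neural indicator
#'
#' Unweighted mean of the trial NIs within each block (set
#' `epoch_weighted = TRUE` to weight trials by their epoch counts instead).
#'
#' @param trace A `ni_trace` from [compute_ni()] (may hold several
#'   participants).
#' @param epoch_weighted Weight trials by `n_epochs` (default FALSE).
#' @return Tibble: `participant_id`, `block_index`, `ni_block`.
#' @export
block_ni <- function(trace, epoch_weighted = FALSE) {
  trace %>%
    as_tibble() %>%
    dplyr::group_by(.data$participant_id, .data$block_index) %>%
    dplyr::summarise(
      ni_block = if (epoch_weighted) {
        sum(.data$ni * .data$n_epochs) / sum(.data$n_epochs)
      } else {
        mean(.data$ni)
      },
      .groups = "drop"
    )
}

#' Mixed-model trend of the neural indicator over blocks
#'
#' Fits `ni_block ~ block_index + (1 | participant_id)` (random-intercept
#' repeated-measures regression) and reports the fixed block slope with its
#' t statistic and p-value. The default p-value uses the normal
#' approximation to the t statistic; `df_method = "satterthwaite"` uses
#' lmerTest when available. A singular mixed fit (e.g. no between-participant
#' variance) falls back to ordinary least squares with cluster-robust
#' (participant-clustered) standard errors and is flagged.
#'
#' @param blocks Tibble from [block_ni()] with at least 2 participants and
#'   3 blocks.
#' @param df_method `"normal"` (default) or `"satterthwaite"`.
#' @return A `ni_trend` object; see [tidy.ni_trend()] and
#'   [glance.ni_trend()].
#' @export
trend_regression <- function(blocks, df_method = c("normal", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (length(unique(blocks$participant_id)) < 2) {
    abort("trend regression needs at least 2 participants")
  }
  if (length(unique(blocks$block_index)) < 3) {
    abort("trend regression needs at least 3 blocks")
  }
  nobs <- nrow(blocks)
  df_nominal <- nobs - 2

  # degenerate inputs (exact fits, zero variance) are handled explicitly via
  # the singular-fit fallback; the optimizer chatter they provoke is not
  # user-actionable, so it is silenced here
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(
      ni_block ~ block_index + (1 | participant_id),
      data = blocks, REML = TRUE
    ))),
    error = function(e) NULL
  )
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)

  if (!singular) {
    if (df_method == "satterthwaite" && requireNamespace("lmerTest", quietly = TRUE)) {
      fit <- lmerTest::as_lmerModLmerTest(fit)
      cf <- coef(summary(fit))["block_index", ]
      est <- cf[["Estimate"]]; se <- cf[["Std. Error"]]
      tval <- cf[["t value"]]; dfree <- cf[["df"]]; p <- cf[["Pr(>|t|)"]]
    } else {
      cf <- coef(summary(fit))["block_index", ]
      est <- cf[["Estimate"]]; se <- cf[["Std. Error"]]; tval <- cf[["t value"]]
      dfree <- df_nominal
      p <- 2 * pnorm(-abs(tval))
    }
    method <- "lmer"
  } else {
    # degenerate random-intercept structure: OLS with cluster-robust errors
    ols <- lm(ni_block ~ block_index, data = blocks)
    est <- coef(ols)[["block_index"]]
    vc <- tryCatch(
      suppressWarnings(sandwich::vcovCL(ols, cluster = blocks$participant_id)),
      error = function(e) suppressWarnings(vcov(ols))
    )
    se <- sqrt(vc["block_index", "block_index"])
    dfree <- df_nominal
    if (se < 1e-12) {
      tval <- if (abs(est) < 1e-12) 0 else sign(est) * Inf
      p <- if (abs(est) < 1e-12) 1 else 0
    } else {
      tval <- est / se
      p <- 2 * pnorm(-abs(tval))
    }
    method <- "ols_cluster_robust"
    fit <- ols
  }

  structure(list(
    slope_per_block = est, std_error = se, t_statistic = tval,
    degrees_of_freedom = dfree, p_value = p,
    n_obs = nobs, n_participants = length(unique(blocks$participant_id)),
    method = method, df_method = df_method, singular = singular, fit = fit
  ), class = "ni_trend")
}

#' @export
print.ni_trend <- function(x, ...) {
  cat(sprintf(
    "<ni_trend> beta_block = %.4f (se %.4f), t(%s) = %.2f, p = %.3g [%s]\n",
    x$slope_per_block, x$std_error, format(x$degrees_of_freedom),
    x$t_statistic, x$p_value, x$method
  ))
  invisible(x)
}

#' @rdname trend_regression
#' @param x A `ni_trend` object.
#' @param ... Unused.
#' @export
tidy.ni_trend <- function(x, ...) {
  tibble(
    term = "block_index",
    estimate = x$slope_per_block,
    std.error = x$std_error,
    statistic = x$t_statistic,
    df = x$degrees_of_freedom,
    p.value = x$p_value
  )
}

#' @rdname trend_regression
#' @export
glance.ni_trend <- function(x, ...) {
  tibble(
    nobs = x$n_obs,
    n_participants = x$n_participants,
    method = x$method,
    singular = x$singular
  )
}

#' Correlations of the neural indicator with behavior
#'
#' Pearson correlations, per participant, of the trial NI with (1) the
#' perceived certainty rating and (2) the percent time performance, over all
#' trials and over the session "extremes" (first and last 20% of trials by
#' completion order, where the indicator is expected to be most reliable).
#'
#' @param trace A `ni_trace`.
#' @param behavior Behavior tibble (attribute `"behavior"` of
#'   [cohort_features()], or any table with `participant_id`, `trial_index`,
#'   `certainty_rating`, `time_performance_pct`).
#' @param extreme_fraction Fraction at each end of the session (default 0.2).
#' @return Tibble: `participant_id`, `measure` (certainty/time), `scope`
#'   (all/extremes), `r`, `p_value`, `n`.
#' @export
ni_correlations <- function(trace, behavior, extreme_fraction = 0.2) {
  joined <- dplyr::inner_join(
    as_tibble(trace), behavior,
    by = c("participant_id", "trial_index")
  )
  one <- function(d, measure, scope) {
    v <- if (measure == "certainty") d$certainty_rating else d$time_performance_pct
    ct <- suppressWarnings(cor.test(d$ni, v, method = "pearson"))
    tibble(
      measure = measure, scope = scope,
      r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d)
    )
  }
  joined %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::group_modify(function(d, g) {
      d <- dplyr::arrange(d, .data$trial_index)
      n_ext <- max(2L, round(extreme_fraction * nrow(d)))
      ext <- dplyr::bind_rows(head(d, n_ext), tail(d, n_ext))
      dplyr::bind_rows(
        one(d, "certainty", "all"),
        one(ext, "certainty", "extremes"),
        one(d, "time", "all"),
        one(ext, "time", "extremes")
      )
    }) %>%
    dplyr::ungroup()
}

#' Histogram of selected features over runs
#'
#' Counts how often each feature was selected across all runs (and, when a
#' list of results is given, across participants), with region and band
#' marginals. The total count equals `k * n_runs * n_results`.
#'
#' @param results A `lopo_result` or list of them.
#' @param montage Analysis montage (for the region of each channel).
#' @return A `ni_feature_histogram` tibble: `participant_id`, `feature`,
#'   `channel`, `band`, `region`, `count`.
#' @export
feature_histogram <- function(results, montage = montage_subset()) {
  if (inherits(results, "lopo_result")) results <- list(results)
  counts <- purrr::map_dfr(results, function(res) {
    tibble(
      participant_id = res$test_participant,
      feature = unlist(res$runs$selected)
    )
  }) %>%
    dplyr::count(.data$participant_id, .data$feature, name = "count")
  # feature names are <channel>_<band>; channels never contain "_"
  counts$channel <- sub("_.*$", "", counts$feature)
  counts$band <- sub("^[^_]+_", "", counts$feature)
  counts$region <- montage$region[match(counts$channel, montage$channel)]
  class(counts) <- c("ni_feature_histogram", class(counts))
  counts
}

#' Classify a participant as NI-effective or NI-ineffective
#'
#' A participant's indicator is deemed effective when the permutation
#' p-value beats the significance level; with few permutations the level is
#' floored at `1/n_perm` (the smallest attainable nonzero p).
#'
#' @param perm A `ni_permutation` from [permutation_test()].
#' @param alpha Nominal significance level (default 0.001, appropriate at
#'   1000 permutations).
#' @return `"effective"` or `"ineffective"`.
#' @export
classify_effectiveness <- function(perm, alpha = 0.001) {
  thr <- max(alpha, 1 / length(perm$null_accuracies))
  if (perm$p_value < thr) "effective" else "ineffective"
}
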