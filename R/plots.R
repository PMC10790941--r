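# ggplot2 views of the analysis products.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the neural indicator per trial
#'
#' One panel per participant: trial NI with its 95% confidence band across
#' runs (low proficiency = 0, high proficiency = 1).
#'
#' @param object A `ni_trace` from [compute_ni()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ni_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial_index, y = .data$ni)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ni_lo, ymax = .data$ni_hi),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Trial", y = "Neural indicator (NI)",
      title = "Neural indicator per trial",
      subtitle = "0 = low proficiency, 1 = high proficiency; band = 95% CI across runs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-block NI, optionally by group
#'
#' @param blocks Tibble from [block_ni()].
#' @param groups Optional named character vector mapping participant id to a
#'   group label (e.g. effective/ineffective); adds a color aesthetic with
#'   group means.
#' @return A ggplot.
#' @export
plot_block_ni <- function(blocks, groups = NULL) {
  if (!is.null(groups)) {
    blocks <- dplyr::mutate(blocks, group = groups[.data$participant_id])
    agg <- blocks %>%
      dplyr::group_by(.data$group, .data$block_index) %>%
      dplyr::summarise(ni_block = mean(.data$ni_block), .groups = "drop")
    p <- ggplot2::ggplot(agg, ggplot2::aes(
      x = .data$block_index, y = .data$ni_block, color = .data$group
    ))
  } else {
    agg <- blocks %>%
      dplyr::group_by(.data$block_index) %>%
      dplyr::summarise(ni_block = mean(.data$ni_block), .groups = "drop")
    p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$block_index, y = .data$ni_block))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Block", y = "Mean NI",
      title = "Mean neural indicator per block"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the feature-selection histogram
#'
#' Selection counts per channel, faceted by region, colored by band.
#'
#' @param object A `ni_feature_histogram` from [feature_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ni_feature_histogram <- function(object, ...) {
  agg <- object %>%
    as_tibble() %>%
    dplyr::group_by(.data$region, .data$channel, .data$band) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$channel, y = .data$count, fill = .data$band
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "Times selected",
      title = "mRMR feature selections by channel, band and region"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
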