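#' Standard 10-20 recording montage (64 channels)
#'
#' The full recording montage used by the synthetic cohort generator: a
#' 64-channel extended 10-20 layout including the central strip (C*, FC*,
#' CP* rows), the reference position FCz and the ground FPz, none of which
#' enter the analysis montage.
#'
#' @return Character vector of 64 channel labels, in recording order.
#' @seealso [montage_subset()] for the 41-channel analysis montage.
#' @export
montage_full <- function() {
  c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "TP9", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz"
  )
}

#' 41-channel analysis montage with region labels
#'
#' The feature-extraction montage: 41 electrodes over the frontal, temporal,
#' parietal and occipital regions. The central strip (C*, FC*, CP* rows),
#' the reference (FCz) and ground (FPz) are excluded. The default can be
#' replaced by any 2-column (channel, region) table with 41 rows, e.g. read
#' from the CSV shipped at `system.file("extdata", "montage_41.csv",
#' package = "nitrack")`.
#'
#' @param path Optional path to a montage CSV with columns `channel` and
#'   `region`. When `NULL` (default) the built-in montage is returned.
#' @return A tibble with columns `channel` and `region` (one of `"frontal"`,
#'   `"temporal"`, `"parietal"`, `"occipital"`), 41 rows.
#' @export
#' @examples
#' m <- montage_subset()
#' nrow(m)                 # 41
#' table(m$region)
montage_subset <- function(path = NULL) {
  if (!is.null(path)) {
    m <- readr::read_csv(path, show_col_types = FALSE)
    return(validate_montage(as_tibble(m)))
  }
  m <- tibble(
    channel = c(
      "Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
      "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
      "FT7", "FT8", "T7", "T8", "TP7", "TP8", "TP9", "TP10",
      "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
      "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2"
    ),
    region = c(
      rep("frontal", 16),
      rep("temporal", 8),
      rep("parietal", 9),
      rep("occipital", 8)
    )
  )
  validate_montage(m)
}

validate_montage <- function(m) {
  stopifnot(all(c("channel", "region") %in% names(m)))
  if (nrow(m) != 41L) {
    abort(sprintf("analysis montage must have exactly 41 channels, got %d", nrow(m)))
  }
  if (anyDuplicated(m$channel)) abort("montage channels must be unique")
  banned <- grepl("^(C[0-9z]|FC|CP)", m$channel) | m$channel %in% c("FCz", "FPz", "Fpz")
  if (any(banned)) {
    abort(paste0(
      "montage must exclude the central strip and reference/ground: ",
      paste(m$channel[banned], collapse = ", ")
    ))
  }
  ok_regions <- c("frontal", "temporal", "parietal", "occipital")
  if (!all(m$region %in% ok_regions)) {
    abort("montage regions must be frontal/temporal/parietal/occipital")
  }
  m
}

# region lookup for the full recording montage, used by the generator to
# weight oscillation amplitudes; central-strip channels get their own label.
full_montage_regions <- function() {
  m41 <- montage_subset()
  chans <- montage_full()
  region <- ifelse(chans %in% m41$channel,
    m41$region[match(chans, m41$channel)], "central"
  )
  region[chans == "Iz"] <- "occipital"
  tibble(channel = chans, region = region)
}
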