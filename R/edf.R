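# Minimal EDF (European Data Format) writer/reader pair plus the sessions
# CSV, the on-disk interchange format of the synthetic cohort generator.
# 16-bit samples, physical units microvolt, 1-s data records; the final
# partial record is zero-padded and trimmed again on read via the session
# table. Header fields that would break byte-identical reruns (dates) are
# fixed constants.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a signal matrix to an EDF file
#'
#' @param signal Numeric matrix (samples x channels), physical unit
#'   microvolt.
#' @param fs Sampling rate in Hz (samples per 1-s data record).
#' @param channel_labels Channel names (defaults to the matrix column
#'   names).
#' @param path Output file path.
#' @param patient_id Free-text patient identification field.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, fs, path, channel_labels = colnames(signal),
                      patient_id = "X") {
  ns <- ncol(signal)
  n <- nrow(signal)
  n_rec <- as.integer(ceiling(n / fs))
  if (n_rec * fs > n) {
    signal <- rbind(signal, matrix(0, n_rec * fs - n, ns))
  }
  # per-channel symmetric integer physical range covering the data (integer
  # so the header string is exact and the reader recovers the same scale)
  pmax_ <- ceiling(pmax(1, apply(abs(signal), 2, max)))
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient_id, 80),
    edf_pad("Startdate 01-JAN-2000", 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  field <- function(values, width) {
    writeChar(paste0(vapply(values, edf_pad, character(1), width = width),
      collapse = ""
    ), con, nchars = ns * width, eos = NULL)
  }
  field(channel_labels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.0f", -pmax_), 8)
  field(sprintf("%.0f", pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  # digital conversion per channel, then interleave records
  dig <- matrix(0L, nrow(signal), ns)
  for (j in seq_len(ns)) {
    dig[, j] <- as.integer(round((signal[, j] + pmax_[j]) / (2 * pmax_[j]) *
      (dmax - dmin) + dmin))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' A minimal reader for 16-bit EDF with equal sampling rate across
#' channels.
#'
#' @param path EDF file path.
#' @return List with `signal` (samples x channels, physical units), `fs`,
#'   `channel_labels` and `patient_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8)) # samples per record
  fields(32)

  raw <- readBin(con, "integer",
    n = n_rec * sum(spr), size = 2,
    endian = "little", signed = TRUE
  )
  signal <- matrix(0, n_rec * spr[1], ns)
  idx <- 0
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      rows <- ((r - 1) * spr[j] + 1):(r * spr[j])
      signal[rows, j] <- raw[idx + seq_len(spr[j])]
      idx <- idx + spr[j]
    }
  }
  for (j in seq_len(ns)) {
    signal[, j] <- (signal[, j] - dig_min[j]) / (dig_max[j] - dig_min[j]) *
      (phys_max[j] - phys_min[j]) + phys_min[j]
  }
  colnames(signal) <- labels
  list(
    signal = signal, fs = spr[1] / rec_dur,
    channel_labels = labels, patient_id = patient_id
  )
}

#' Write a synthetic cohort to EDF + sessions CSV
#'
#' One EDF file per participant (`<participant_id>.edf`) plus a single
#' `sessions.csv` holding the segment table and behavior of every
#' participant — the columns `participant_id`, `segment_kind`,
#' `trial_index`, `baseline_index`, `block_index`, `start_sample`,
#' `end_sample`, `certainty_rating`, `trial_time_s`, `ideal_time_s`.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(session) {
    write_edf(session$signal, session$sampling_rate,
      file.path(dir, paste0(session$participant_id, ".edf")),
      channel_labels = session$channel_labels,
      patient_id = session$participant_id
    )
    session$segments %>%
      dplyr::mutate(participant_id = session$participant_id, .before = 1) %>%
      dplyr::left_join(
        session$behavior %>%
          dplyr::select(-"block_index"),
        by = "trial_index"
      ) %>%
      dplyr::mutate(
        is_responder = session$is_responder,
        gain_profile = session$gain_profile,
        sampling_rate = session$sampling_rate
      )
  })
  readr::write_csv(dplyr::bind_rows(rows), file.path(dir, "sessions.csv"))
  invisible(dir)
}

#' Read a cohort back from EDF + sessions CSV
#'
#' Inverse of [write_cohort()]: reconstructs the list of `eeg_session`
#' objects (signal values carry 16-bit quantization error; segment indices
#' and behavior round-trip exactly).
#'
#' @param dir Directory written by [write_cohort()].
#' @return An `eeg_cohort`.
#' @export
read_cohort <- function(dir) {
  tab <- readr::read_csv(file.path(dir, "sessions.csv"), show_col_types = FALSE)
  ids <- unique(tab$participant_id)
  sessions <- lapply(ids, function(id) {
    st <- tab[tab$participant_id == id, ]
    edf <- read_edf(file.path(dir, paste0(id, ".edf")))
    n <- max(st$end_sample)
    beh <- st %>%
      dplyr::filter(.data$segment_kind == "navigation") %>%
      dplyr::select(
        "trial_index", "block_index", "certainty_rating",
        "trial_time_s", "ideal_time_s"
      )
    structure(list(
      participant_id = id,
      is_responder = st$is_responder[1],
      gain_profile = st$gain_profile[1],
      sampling_rate = st$sampling_rate[1],
      channel_labels = edf$channel_labels,
      iaf_true = NA_real_,
      signal = edf$signal[seq_len(n), , drop = FALSE],
      segments = st %>% dplyr::select(
        "segment_kind", "trial_index", "baseline_index",
        "block_index", "start_sample", "end_sample"
      ),
      behavior = beh
    ), class = "eeg_session")
  })
  structure(sessions, class = "eeg_cohort")
}
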