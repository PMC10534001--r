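# Plain-text readers/writers for recordings, manifests and feature tables:
# one delimited file per participant (time column plus one column per
# channel) and CSV side tables, so cohorts round-trip through ordinary
# columnar text.

#' Write / read one PPG recording as delimited text
#'
#' One CSV per participant: a `time` column (seconds) plus one column per
#' channel (a.u.). Channel gains, class label, sampling rate and phase
#' boundaries travel in the cohort manifest, not in the signal file.
#'
#' @param recording A `ppg_recording`.
#' @param dir Output directory (created if missing).
#' @return The file path, invisibly.
#' @export
write_recording <- function(recording, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(recording$participant_id, ".csv"))
  d <- data.frame(time = (seq_len(nrow(recording$signals)) - 1) /
                    recording$fs)
  for (ch in colnames(recording$signals)) d[[ch]] <- recording$signals[, ch]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param path Signal CSV written by [write_recording()].
#' @param manifest_row One-row slice of the cohort manifest for this
#'   participant.
#' @param protocol The acquisition [ppg_protocol()].
#' @export
read_recording <- function(path, manifest_row, protocol) {
  d <- utils::read.csv(path)
  channels <- setdiff(colnames(d), "time")
  sig <- as.matrix(d[, channels])
  gains <- sapply(channels, function(ch) {
    g <- manifest_row[[paste0("gain_", ch)]]
    if (is.null(g)) 1 else g
  })
  structure(list(participant_id = manifest_row$participant_id,
                 class_label = manifest_row$class_label,
                 signals = sig, fs = protocol$fs,
                 channel_gains = as.list(gains),
                 protocol = protocol, normalized = FALSE),
            class = "ppg_recording")
}

#' Write a cohort to a directory
#'
#' Writes `manifest.csv` plus one signal CSV per participant.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (rec in cohort$recordings) write_recording(rec, dir)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param protocol The acquisition [ppg_protocol()].
#' @return List with `recordings` and `manifest`.
#' @export
read_cohort <- function(dir, protocol) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, paste0(manifest$participant_id[i], ".csv")),
                   manifest[i, ], protocol)
  })
  list(recordings = recs, manifest = manifest)
}
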