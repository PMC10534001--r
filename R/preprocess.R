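#' Gain-normalise a multi-site PPG recording
#'
#' Divides each channel by its amplifier gain setting, the only
#' pre-processing the pipeline applies to the raw signals (no digital
#' filtering). After normalisation the stored gains are reset to 1, so the
#' operation is idempotent.
#'
#' @param recording A `ppg_recording`.
#' @return The recording with each channel divided by its gain and
#'   `normalized = TRUE`.
#' @export
gain_normalize <- function(recording) {
  g <- recording$channel_gains[colnames(recording$signals)]
  if (any(!is.finite(unlist(g))) || any(unlist(g) <= 0))
    stop("channel gains must be positive")
  recording$signals <- sweep(recording$signals, 2, unlist(g), "/")
  recording$channel_gains[] <- 1
  recording$normalized <- TRUE
  recording
}

#' Detect amplifier saturation (electronic clipping) in a PPG channel
#'
#' A trace is unusable when it rails against the amplifier limits: samples
#' pile up on a flat plateau at the channel maximum (or minimum). The check
#' slides a `span_seconds` window over the trace and fails the channel when
#' the fraction of samples within `tol` (as a fraction of the signal range)
#' of either extreme exceeds `clip_fraction_threshold` in any window. A
#' constant trace has zero range and fails outright.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param clip_fraction_threshold Maximum tolerated plateau fraction within
#'   any window (default 0.02).
#' @param span_seconds Sliding-window length (default 10 s).
#' @param tol Plateau tolerance as a fraction of the signal range
#'   (default 1e-4).
#' @return List with `pass` (logical), `worst_fraction`, `worst_start`
#'   (seconds) and `side` (`"max"` or `"min"`).
#' @export
detect_saturation <- function(x, fs,
                              clip_fraction_threshold = 0.02,
                              span_seconds = 10,
                              tol = 1e-4) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  rng <- max(x) - min(x)
  if (rng == 0)
    return(list(pass = FALSE, worst_fraction = 1, worst_start = 0,
                side = "max"))
  w <- min(max(round(span_seconds * fs), 1L), n)
  worst <- list(fraction = -1, start = 0, side = "max")
  for (side in c("max", "min")) {
    mask <- if (side == "max") x >= max(x) - tol * rng
            else x <= min(x) + tol * rng
    cs <- c(0, cumsum(mask))
    frac <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    i <- which.max(frac)
    if (frac[i] > worst$fraction)
      worst <- list(fraction = frac[i], start = (i - 1) / fs, side = side)
  }
  list(pass = worst$fraction <= clip_fraction_threshold,
       worst_fraction = worst$fraction,
       worst_start = worst$start,
       side = worst$side)
}

#' Quality-check every channel of a cohort
#'
#' Applies [detect_saturation()] per channel and flags participants (rather
#' than silently dropping them) whose any-channel check fails; exclusion
#' decisions stay visible in the returned table.
#'
#' @param cohort A cohort as returned by [generate_cohort()].
#' @param ... Passed to [detect_saturation()].
#' @return Data frame with one row per participant x channel and a logical
#'   `pass` column.
#' @export
qc_cohort <- function(cohort, ...) {
  rows <- list()
  for (rec in cohort$recordings) {
    for (ch in colnames(rec$signals)) {
      r <- detect_saturation(rec$signals[, ch], rec$fs, ...)
      rows[[length(rows) + 1]] <-
        data.frame(participant_id = rec$participant_id,
                   class_label = rec$class_label, channel = ch,
                   pass = r$pass, worst_fraction = r$worst_fraction,
                   worst_start = r$worst_start,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Split a recording into consecutive non-overlapping windows
#'
#' Each channel is divided into consecutive `window_seconds` windows; a
#' trailing partial window is discarded so every window has identical time
#' support. Windows inherit the participant's class label.
#'
#' @param recording A `ppg_recording`.
#' @param window_seconds Window length in seconds (default 30).
#' @return List of `signal_window` objects, each with `participant_id`,
#'   `class_label`, `channel`, `window_index` (1-based, per channel),
#'   `start_time` (seconds), `fs` and `samples`.
#' @export
window_signal <- function(recording, window_seconds = 30) {
  fs <- recording$fs
  wlen <- round(window_seconds * fs)
  n <- nrow(recording$signals)
  n_win <- n %/% wlen
  if (n_win < 1)
    stop("recording shorter than one window")
  out <- vector("list", n_win * ncol(recording$signals))
  k <- 0
  for (ch in colnames(recording$signals)) {
    for (w in seq_len(n_win)) {
      k <- k + 1
      i0 <- (w - 1) * wlen
      out[[k]] <- structure(
        list(participant_id = recording$participant_id,
             class_label = recording$class_label,
             channel = ch,
             window_index = w,
             start_time = i0 / fs,
             fs = fs,
             samples = recording$signals[(i0 + 1):(i0 + wlen), ch]),
        class = "signal_window")
    }
  }
  out
}
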