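#' Three-phase multi-site PPG measurement protocol
#'
#' Describes the acquisition protocol used throughout the package: a supine
#' baseline phase, a unilateral arm-cuff occlusion phase (cuff at 300 mmHg
#' stopping arterial inflow to the left arm), and a post-release reactive
#' hyperaemia ("flush") phase, recorded simultaneously from six symmetrical
#' body sites.
#'
#' The clinical protocol runs 20 minutes at 2000 Hz with phase boundaries at
#' 600 s and 900 s; [desk_protocol()] gives a shorter, lower-rate variant with
#' the same 2:1:1 phase structure for fast desk-scale experiments.
#'
#' @param fs Sampling rate in Hz. Must exceed 40 Hz so the 20 Hz upper band
#'   edge of the PPG amplifiers sits below Nyquist.
#' @param duration Total recording length in seconds.
#' @param baseline_end End of the baseline phase (seconds).
#' @param occlusion_end End of the occlusion phase (seconds); the flush phase
#'   runs from here to `duration`.
#' @param channels Ordered measurement-site names.
#' @param occluded_channels Subset of `channels` distal to the arm cuff. Only
#'   the left index finger is distal to a left-arm cuff among the six default
#'   sites.
#' @return An object of class `ppg_protocol`.
#' @export
#' @examples
#' p <- ppg_protocol()
#' p$fs
ppg_protocol <- function(fs = 2000,
                         duration = 1200,
                         baseline_end = 600,
                         occlusion_end = 900,
                         channels = c("right_ear", "left_ear",
                                      "right_finger", "left_finger",
                                      "right_toe", "left_toe"),
                         occluded_channels = "left_finger") {
  stopifnot(is.numeric(fs), length(fs) == 1, is.numeric(duration),
            length(duration) == 1)
  if (fs <= 40)
    stop("fs must exceed 40 Hz (Nyquist above the 20 Hz band edge)")
  if (duration <= 0)
    stop("duration must be positive")
  if (!(0 < baseline_end && baseline_end < occlusion_end &&
        occlusion_end < duration))
    stop("phase boundaries must satisfy 0 < baseline_end < occlusion_end < duration")
  channels <- as.character(channels)
  if (anyDuplicated(channels))
    stop("channel names must be unique")
  if (!all(occluded_channels %in% channels))
    stop("occluded_channels must be a subset of channels")
  structure(list(fs = fs,
                 duration = duration,
                 baseline_end = baseline_end,
                 occlusion_end = occlusion_end,
                 channels = channels,
                 occluded_channels = occluded_channels),
            class = "ppg_protocol")
}

#' @rdname ppg_protocol
#' @export
desk_protocol <- function(fs = 200, duration = 300) {
  ppg_protocol(fs = fs, duration = duration,
               baseline_end = duration / 2,
               occlusion_end = 3 * duration / 4)
}

#' @export
print.ppg_protocol <- function(x, ...) {
  cat("Three-phase PPG protocol\n")
  cat(sprintf("  fs: %g Hz, duration: %g s\n", x$fs, x$duration))
  cat(sprintf("  phases: baseline 0-%g s, occlusion %g-%g s, flush %g-%g s\n",
              x$baseline_end, x$baseline_end, x$occlusion_end,
              x$occlusion_end, x$duration))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  occluded:", paste(x$occluded_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-participant phenotype profile for the synthetic cohort generator
#'
#' Bundles the vascular phenotype parameters that drive one synthetic
#' participant's recording: pulse amplitude per site, reactive-hyperaemia
#' overshoot and recovery kinetics, pulse morphology, heart rate, measurement
#' noise and per-channel amplifier gains.
#'
#' @param participant_id Character scalar identifier.
#' @param class_label `"SSc"` or `"Control"`.
#' @param heart_rate Heart rate in Hz; must lie in (0.7, 2).
#' @param amplitude Named per-channel baseline pulse amplitude in arbitrary
#'   units (a.u.); names must match the protocol channels. All values must be
#'   non-negative.
#' @param flush_overshoot Ratio of the post-release peak beat amplitude to the
#'   baseline amplitude on occluded channels. Controls typically exceed 1
#'   (clear hyperaemic overshoot); SSc typically at or below 1 (attenuated
#'   flush).
#' @param flush_tau Recovery time constant of the flush transient (seconds).
#' @param amplitude_heterogeneity Coefficient of variation of pulse amplitude
#'   across the finger channels (recorded for provenance; applied when the
#'   profile is sampled).
#' @param noise_sd Standard deviation of the additive, band-limited
#'   measurement noise (a.u.).
#' @param channel_gains Named per-channel amplifier gain settings (> 0).
#' @param beat_width Width of the systolic bump as a fraction of the beat
#'   period.
#' @param dicrotic_ratio Relative amplitude of the diastolic (dicrotic) bump.
#' @param jitter Coefficient of variation of the beat-to-beat interval.
#' @param drift_amp Slow baseline-drift bound on the amplitude envelope
#'   (fractional).
#' @param occlusion_tau Time constant of the amplitude collapse after cuff
#'   inflation (seconds).
#' @return An object of class `ppg_profile`.
#' @export
participant_profile <- function(participant_id,
                                class_label = c("Control", "SSc"),
                                heart_rate = 1.2,
                                amplitude,
                                flush_overshoot = 1.8,
                                flush_tau = 15,
                                amplitude_heterogeneity = 0.05,
                                noise_sd = 1,
                                channel_gains,
                                beat_width = 0.10,
                                dicrotic_ratio = 0.4,
                                jitter = 0.02,
                                drift_amp = 0.02,
                                occlusion_tau = 5) {
  class_label <- match.arg(class_label)
  if (!(heart_rate > 0.7 && heart_rate < 2.0))
    stop("heart_rate must lie in (0.7, 2.0) Hz")
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  if (flush_tau <= 0) stop("flush_tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(channel_gains <= 0)) stop("channel gains must be positive")
  structure(list(participant_id = as.character(participant_id),
                 class_label = class_label,
                 heart_rate = heart_rate,
                 amplitude = amplitude,
                 flush_overshoot = flush_overshoot,
                 flush_tau = flush_tau,
                 amplitude_heterogeneity = amplitude_heterogeneity,
                 noise_sd = noise_sd,
                 channel_gains = channel_gains,
                 beat_width = beat_width,
                 dicrotic_ratio = dicrotic_ratio,
                 jitter = jitter,
                 drift_amp = drift_amp,
                 occlusion_tau = occlusion_tau),
            class = "ppg_profile")
}
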