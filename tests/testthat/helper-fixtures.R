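# Shared fixtures: tiny protocols and deterministic profiles/recordings so
# the signal-level tests run in seconds.

tiny_protocol <- function(fs = 50, duration = 90) {
  ppg_protocol(fs = fs, duration = duration,
               baseline_end = duration / 2,
               occlusion_end = 3 * duration / 4)
}

fixed_profile <- function(protocol,
                          class_label = "Control",
                          heart_rate = 1.2,
                          amplitude = 50,
                          flush_overshoot = 1.8,
                          flush_tau = 15,
                          noise_sd = 0,
                          gains = 1,
                          ...) {
  amps <- rep(amplitude, length.out = length(protocol$channels))
  names(amps) <- protocol$channels
  gg <- rep(gains, length.out = length(protocol$channels))
  names(gg) <- protocol$channels
  participant_profile("P001", class_label,
                      heart_rate = heart_rate, amplitude = amps,
                      flush_overshoot = flush_overshoot,
                      flush_tau = flush_tau, noise_sd = noise_sd,
                      channel_gains = gg, ...)
}

fixed_recording <- function(protocol = tiny_protocol(), seed = 7, ...) {
  set.seed(seed)
  simulate_recording(fixed_profile(protocol, ...), protocol)
}

# a plain ppg_recording wrapper around arbitrary channel data
recording_from_matrix <- function(sig, fs, gains = NULL,
                                  participant_id = "PX",
                                  class_label = "Control") {
  if (is.null(gains)) {
    gains <- rep(1, ncol(sig))
    names(gains) <- colnames(sig)
  }
  structure(list(participant_id = participant_id,
                 class_label = class_label,
                 signals = sig, fs = fs,
                 channel_gains = as.list(gains),
                 protocol = NULL, normalized = FALSE),
            class = "ppg_recording")
}
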