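test_that("pulse train follows the envelope and the configured heart rate", {
  proto <- tiny_protocol(fs = 100, duration = 10)
  prof <- fixed_profile(proto, heart_rate = 1.2, amplitude = 10,
                        noise_sd = 0)
  env0 <- rep(0, 1000)

  # zero envelope, zero noise: exactly silent
  set.seed(1)
  expect_equal(generate_pulse_train(prof, env0, 100, 10), rep(0, 1000))

  # zero envelope with noise: zero-mean noise at the configured level
  prof_n <- fixed_profile(proto, heart_rate = 1.2, amplitude = 10,
                          noise_sd = 0.5)
  set.seed(1)
  x <- generate_pulse_train(prof_n, env0, 100, 10)
  expect_lt(abs(mean(x)), 0.2)
  expect_lt(stats::sd(x), 3 * 0.5)

  # beat count by peak detection: ~12 beats in 10 s at 1.2 Hz
  set.seed(2)
  x <- generate_pulse_train(prof, rep(1, 1000), 100, 10)
  above <- x > 10 / 2
  peaks <- sum(diff(above) == 1)
  expect_true(peaks %in% 11:13)

  # seeded determinism
  set.seed(42)
  a <- generate_pulse_train(prof, rep(1, 1000), 100, 10)
  set.seed(42)
  b <- generate_pulse_train(prof, rep(1, 1000), 100, 10)
  expect_identical(a, b)

  expect_error(generate_pulse_train(prof, env0, -1, 10), "positive")
  expect_error(generate_pulse_train(prof, rep(1, 10), 100, 10), "length")
})

test_that("phase envelope encodes baseline, occlusion and flush dynamics", {
  proto <- ppg_protocol(fs = 50)  # clinical phase boundaries, light rate
  prof <- fixed_profile(proto, flush_overshoot = 1.8, flush_tau = 15)

  env <- phase_envelope(prof, proto, "right_finger")
  expect_true(max(abs(env - 1)) <= prof$drift_amp + 1e-12)

  env_occ <- phase_envelope(prof, proto, "left_finger")
  i750 <- round(750 * proto$fs) + 1
  expect_lt(env_occ[i750], 0.05)

  i_flush <- round(proto$occlusion_end * proto$fs) + 1
  expect_lt(abs(env_occ[i_flush] - 1.8) / 1.8, 0.01)

  # flush relaxes monotonically towards 1 with the configured time constant
  i_late <- round((proto$occlusion_end + 3 * prof$flush_tau) * proto$fs)
  expect_lt(abs(env_occ[i_late] - 1), 0.2 * (1.8 - 1))

  expect_error(phase_envelope(prof, proto, "left_elbow"), "unknown channel")
})

test_that("occluded-channel beat amplitude collapses below 5% of baseline", {
  # occlusion phase long relative to the 5 s collapse time constant, as in
  # the clinical protocol's 300 s occlusion
  proto <- tiny_protocol(fs = 50, duration = 240)
  set.seed(3)
  prof <- fixed_profile(proto, noise_sd = 0)
  rec <- simulate_recording(prof, proto)
  x <- rec$signals[, "left_finger"]
  t <- (seq_along(x) - 1) / proto$fs
  rms <- function(v) sqrt(mean(v^2))
  base <- rms(x[t >= 10 & t < proto$baseline_end])
  occ <- rms(x[t >= proto$baseline_end + 20 & t < proto$occlusion_end])
  expect_lt(occ, 0.05 * base)
})

test_that("cohort generation is seeded, labelled and fully manifested", {
  proto <- tiny_protocol()

  one <- generate_cohort(0, 1, proto, seed = 5)
  expect_length(one$recordings, 1)
  expect_equal(nrow(one$manifest), 1)
  expect_equal(one$manifest$class_label, "Control")

  coh <- generate_cohort(3, 5, proto, seed = 5)
  expect_length(coh$recordings, 8)
  expect_equal(sum(coh$manifest$class_label == "SSc"), 3)
  expect_true(all(sapply(coh$recordings,
                         function(r) all(is.finite(r$signals)))))

  coh2 <- generate_cohort(3, 5, proto, seed = 5)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$recordings[[1]]$signals, coh2$recordings[[1]]$signals)

  coh3 <- generate_cohort(3, 5, proto, seed = 6)
  expect_false(identical(coh$recordings[[1]]$signals,
                         coh3$recordings[[1]]$signals))

  expect_error(generate_cohort(-1, 5, proto), "non-negative")
})

test_that("Control flush overshoot stochastically dominates SSc", {
  proto <- tiny_protocol()
  phen <- phenotype_defaults("literature")
  set.seed(11)
  ctrl <- replicate(100, sample_profile("c", "Control", proto,
                                        phen$Control)$flush_overshoot)
  ssc <- replicate(100, sample_profile("s", "SSc", proto,
                                       phen$SSc)$flush_overshoot)
  expect_true(all(sort(ctrl) >= sort(ssc)))
  expect_gt(stats::median(ctrl), stats::median(ssc))
  # class convention: Controls overshoot, SSc attenuated
  expect_true(all(ctrl > 1))
  expect_true(all(ssc <= 1))
})

test_that("generated signals pass the saturation quality check", {
  proto <- tiny_protocol()
  coh <- generate_cohort(2, 2, proto, seed = 9)
  qc <- qc_cohort(coh)
  expect_true(all(qc$pass))
  expect_equal(nrow(qc), 4 * length(proto$channels))
})

test_that("cohorts round-trip through the plain-text store", {
  proto <- tiny_protocol(fs = 50, duration = 60)
  coh <- generate_cohort(1, 1, proto, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, proto)
  expect_equal(back$manifest$participant_id, coh$manifest$participant_id)
  expect_equal(back$recordings[[1]]$signals[, 1],
               coh$recordings[[1]]$signals[, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})
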