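# Reference values computed independently with PyWavelets (wavedec, db4,
# periodization mode) and frozen here.

test_that("single-level db4 periodized step matches the reference transform", {
  d <- dwt_decompose(as.numeric(1:8), fs = 8, levels = 1)
  expect_equal(d$coefficients$ap,
               c(11.2022548075565, 3.26486322444049, 4.33504705699606,
                 6.65367903372268), tolerance = 1e-12)
  expect_equal(d$coefficients$d1,
               c(-0.101112252931148, -0.0847792142805519, 1.84302250647117,
                 1.17129608548672), tolerance = 1e-12)
})

test_that("ten-level decomposition reproduces reference band energies exactly", {
  n <- 1024; fs <- 64
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 1.2 * t) + 0.4 * sin(2 * pi * 5 * t + 0.3) +
    0.1 * cos(2 * pi * 17 * t) + 0.05 * (t %% 1)
  d <- dwt_decompose(x, fs)
  E <- sapply(d$coefficients, function(cf) sum(cf^2))
  ref <- c(d1 = 3.22819420860562, d2 = 5.84445999281967,
           d3 = 66.6941812026181, d4 = 27.697169238384,
           d5 = 376.199894928387, d6 = 113.518078128963,
           d7 = 0.269497591720892, d8 = 0.255361774572375,
           d9 = 0.0648426826713934, d10 = 0.0544566758408961,
           ap = 0.913394289940987)
  expect_equal(E[names(ref)], ref, tolerance = 1e-10)
  # coefficient counts halve exactly per level
  expect_equal(sapply(d$coefficients[paste0("d", 1:10)], length),
               512 / 2^(0:9), ignore_attr = TRUE)
})

test_that("Parseval energy conservation holds to machine precision", {
  set.seed(21)
  x <- stats::rnorm(4096)
  d <- dwt_decompose(x, fs = 200)
  total <- sum(sapply(d$coefficients, function(cf) sum(cf^2)))
  expect_lt(abs(total - sum(x^2)) / sum(x^2), 1e-8)
  expect_error(dwt_decompose(stats::rnorm(512), fs = 200, levels = 10),
               "too short")
})

test_that("band edges follow the dyadic formula at the clinical rate", {
  e <- dwt_band_edges(2000)
  r2 <- function(v) round_half_up(v, 2)
  expect_equal(r2(e$d6), c(15.63, 31.25))
  expect_equal(r2(e$d7), c(7.81, 15.63))
  expect_equal(r2(e$d8), c(3.91, 7.81))
  expect_equal(r2(e$d9), c(1.95, 3.91))
  expect_equal(r2(e$d10), c(0.98, 1.95))
  expect_equal(r2(e$ap), c(0, 0.98))
})

test_that("band selection keeps d6-d10 and ap in fixed order", {
  d <- dwt_decompose(stats::rnorm(2048), fs = 200)
  sel <- select_bands(d)
  expect_equal(names(sel$coefficients),
               c("d6", "d7", "d8", "d9", "d10", "ap"))
  shallow <- dwt_decompose(stats::rnorm(2048), fs = 200, levels = 5)
  expect_error(select_bands(shallow), "levels >= 10")
})

test_that("band features match closed-form values on degenerate inputs", {
  f <- band_features(c(1, 2, 3))
  expect_equal(unname(f["energy"]), 14)

  f2 <- band_features(c(-1, 1))
  expect_equal(unname(f2["mav"]), 0)
  expect_equal(unname(f2["skewness"]), 0)
  expect_equal(unname(f2["entropy"]), 1)   # two equal-energy coefficients

  expect_equal(unname(band_features(c(3, 0, 0, 0))["entropy"]), 0)
  expect_equal(unname(band_features(c(3, 3, 3, 3))["entropy"]), 2)

  expect_warning(fz <- band_features(c(2, 2, 2)), "skewness")
  expect_equal(unname(fz["skewness"]), 0)

  # mean-of-absolutes convention available behind the switch
  expect_equal(unname(band_features(c(-1, 1), mav_method = "mean_abs")["mav"]),
               1)
  expect_error(band_features(numeric(0)), "empty")
})

test_that("entropy is scale-invariant while energy scales quadratically", {
  set.seed(31)
  x <- stats::rnorm(64)
  f1 <- band_features(x)
  f5 <- band_features(5 * x)
  expect_equal(f5[["entropy"]], f1[["entropy"]], tolerance = 1e-12)
  expect_equal(f5[["energy"]], 25 * f1[["energy"]], tolerance = 1e-12)
})

test_that("participant feature vectors have 144 pinned, finite entries", {
  proto <- tiny_protocol(fs = 64, duration = 32)
  rec <- fixed_recording(proto, noise_sd = 0.5, gains = 2)
  f <- participant_features(rec)
  expect_length(f, 6 * 6 * 4)
  expect_true(all(is.finite(f)))
  # ordering pinned: channels x bands x (energy, entropy, mav, skewness)
  expect_equal(names(f)[1:4],
               paste("right_ear_d6", c("energy", "entropy", "mav",
                                       "skewness"), sep = "_"))
  expect_equal(names(f)[141:144],
               paste("left_toe_ap", c("energy", "entropy", "mav",
                                      "skewness"), sep = "_"))

  # identical recording, identical vector
  rec2 <- fixed_recording(proto, noise_sd = 0.5, gains = 2)
  expect_identical(participant_features(rec2), f)

  # scaling one channel: its energies x c^2, entropies unchanged
  rec3 <- gain_normalize(rec)
  rec3$signals[, "left_finger"] <- 2 * rec3$signals[, "left_finger"]
  f3 <- participant_features(rec3)
  lf <- grep("^left_finger_.*_energy$", names(f))
  expect_equal(unname(f3[lf]), unname(4 * participant_features(
    gain_normalize(rec))[lf]), tolerance = 1e-10)
  le <- grep("^left_finger_.*_entropy$", names(f))
  expect_equal(f3[le], participant_features(gain_normalize(rec))[le],
               tolerance = 1e-10)
})
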