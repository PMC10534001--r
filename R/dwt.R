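# Daubechies db4 (8-tap, 4 vanishing moments) orthonormal decomposition
# filters.
.db4_lo <- c(-0.010597401785069032, 0.032883011666885197,
             0.030841381835560764, -0.18703481171909309,
             -0.027983769416859854, 0.63088076792985892,
             0.71484657055291567, 0.23037781330889651)
.db4_hi <- c(-0.23037781330889651, 0.71484657055291567,
             -0.63088076792985892, -0.027983769416859854,
             0.18703481171909309, 0.030841381835560764,
             -0.032883011666885197, -0.010597401785069032)

# One periodized analysis step: circular convolution with the time-reversed
# filter, downsampled by two. Orthonormal, so energy is conserved exactly
# and coefficient counts halve per level.
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2
  f <- rev(filt)
  out <- numeric(half)
  k <- 0:(half - 1)
  for (m in seq_along(f)) {
    idx <- ((2 * k - 3 + (m - 1)) %% n) + 1
    out <- out + f[m] * x[idx]
  }
  out
}

#' Multi-level discrete wavelet transform of one PPG channel
#'
#' Ten-level dyadic decomposition with the Daubechies db4 mother wavelet and
#' periodized boundary handling, so the transform is orthonormal: coefficient
#' counts halve exactly at each level and Parseval's identity holds to
#' machine precision. The signal is truncated to the largest multiple of
#' `2^levels` samples so every level has an even length. Detail level `j`
#' covers the dyadic band `(fs/2^(j+1), fs/2^j)` Hz; the final approximation
#' covers `(0, fs/2^(levels+1))` Hz.
#'
#' @param x Numeric sample vector; length must be at least `2^levels`.
#' @param fs Sampling rate (Hz), used only to label the band edges.
#' @param levels Decomposition depth (default 10).
#' @param wavelet Mother wavelet; only `"db4"` is provided.
#' @return Object of class `ppg_dwt`: `coefficients` (named list `d1` ...
#'   `d<levels>`, `ap`), `band_edges` (named list of `(low, high)` Hz),
#'   `fs`, `levels`, `wavelet`.
#' @export
#' @examples
#' d <- dwt_decompose(sin(2 * pi * 1.2 * (0:2047) / 64), fs = 64)
#' d$band_edges$d5
dwt_decompose <- function(x, fs, levels = 10, wavelet = "db4") {
  if (wavelet != "db4") stop("only the db4 wavelet is provided")
  n <- length(x)
  if (n < 2^levels)
    stop("signal too short: need at least 2^levels samples")
  keep <- (n %/% 2^levels) * 2^levels
  x <- x[seq_len(keep)]
  coefs <- list()
  a <- x
  for (j in seq_len(levels)) {
    coefs[[paste0("d", j)]] <- dwt_step(a, .db4_hi)
    a <- dwt_step(a, .db4_lo)
  }
  coefs$ap <- a
  edges <- lapply(seq_len(levels), function(j) c(fs / 2^(j + 1), fs / 2^j))
  names(edges) <- paste0("d", seq_len(levels))
  edges$ap <- c(0, fs / 2^(levels + 1))
  structure(list(coefficients = coefs, band_edges = edges, fs = fs,
                 levels = levels, wavelet = wavelet,
                 n_used = keep),
            class = "ppg_dwt")
}

#' Band edges of a dyadic DWT decomposition
#'
#' Closed-form edges, `(fs/2^(j+1), fs/2^j)` Hz for detail level `j` and
#' `(0, fs/2^(levels+1))` for the final approximation. At the 2000 Hz
#' clinical sampling rate the selected bands are d6 (15.63-31.25 Hz) down to
#' d10 (0.98-1.95 Hz) plus ap (0-0.98 Hz), jointly covering the 0.5-20 Hz
#' PPG passband.
#'
#' @param fs Sampling rate (Hz).
#' @param levels Decomposition depth.
#' @return Named list of numeric `(low, high)` pairs.
#' @export
dwt_band_edges <- function(fs, levels = 10) {
  edges <- lapply(seq_len(levels), function(j) c(fs / 2^(j + 1), fs / 2^j))
  names(edges) <- paste0("d", seq_len(levels))
  edges$ap <- c(0, fs / 2^(levels + 1))
  edges
}

#' Select the PPG-relevant frequency bands
#'
#' Keeps, in fixed order, the detail levels d6-d10 and the final
#' approximation - the bands containing the analogue passband of the PPG
#' front end.
#'
#' @param bc A `ppg_dwt` from [dwt_decompose()].
#' @return A `ppg_dwt` restricted to the six selected bands.
#' @export
select_bands <- function(bc) {
  wanted <- c("d6", "d7", "d8", "d9", "d10", "ap")
  if (!all(wanted %in% names(bc$coefficients)))
    stop("decomposition does not contain levels d6-d10 and ap; use levels >= 10")
  bc$coefficients <- bc$coefficients[wanted]
  bc$band_edges <- bc$band_edges[wanted]
  bc
}

#' Per-band summary features of DWT coefficients
#'
#' Computes the four features used by the comparator feature pipeline:
#'
#' * energy: the sum of squared coefficients;
#' * entropy: Shannon entropy (bits) of the normalised squared-coefficient
#'   distribution `p_i = x_i^2 / sum(x^2)` - 0 when all energy sits in one
#'   coefficient, `log2(N)` when spread uniformly. The
#'   `entropy_method = "log_energy"` alternative uses the unnormalised
#'   `-sum(x^2 * log2(x^2))` convention;
#' * mav: the absolute value of the mean coefficient (literal reading);
#'   `mav_method = "mean_abs"` switches to the conventional mean of
#'   absolute values;
#' * skewness: the population third standardised moment
#'   `E[(x - mu)^3] / sigma^3`, defined as 0 (with a warning) when
#'   `sigma = 0`.
#'
#' @param x Numeric coefficient vector (non-empty).
#' @param entropy_method `"shannon_normalized"` (default) or `"log_energy"`.
#' @param mav_method `"abs_mean"` (default) or `"mean_abs"`.
#' @return Named numeric vector `(energy, entropy, mav, skewness)`.
#' @export
#' @examples
#' band_features(c(1, 2, 3))["energy"]  # 14
band_features <- function(x,
                          entropy_method = c("shannon_normalized",
                                             "log_energy"),
                          mav_method = c("abs_mean", "mean_abs")) {
  entropy_method <- match.arg(entropy_method)
  mav_method <- match.arg(mav_method)
  if (length(x) == 0) stop("empty coefficient array")
  e <- x^2
  energy <- sum(e)
  if (energy == 0) {
    entropy <- 0
  } else if (entropy_method == "shannon_normalized") {
    p <- e / energy
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  } else {
    nz <- e[e > 0]
    entropy <- -sum(nz * log2(nz))
  }
  mav <- if (mav_method == "abs_mean") abs(mean(x)) else mean(abs(x))
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    warning("zero-variance coefficients: skewness defined as 0")
    skewness <- 0
  } else {
    skewness <- mean((x - mu)^3) / sigma^3
  }
  c(energy = energy, entropy = entropy, mav = mav, skewness = skewness)
}

#' Full 144-element DWT feature vector for one participant
#'
#' Decomposes each gain-normalised channel of the entire recording (the
#' feature branch does not window the signal), selects bands d6-d10 and ap,
#' and computes the four band features, giving `channels x 6 bands x 4
#' features = 144` named values for the six-channel protocol. Ordering is
#' pinned: channels in protocol order, bands d6, d7, d8, d9, d10, ap,
#' features energy, entropy, mav, skewness.
#'
#' @param recording A `ppg_recording`; gain-normalised automatically if not
#'   already (the operation is idempotent).
#' @param levels Decomposition depth (default 10).
#' @param ... Passed to [band_features()].
#' @return Named numeric vector of length `6 * ncol * 4` with attributes
#'   `participant_id` and `class_label`.
#' @export
participant_features <- function(recording, levels = 10, ...) {
  if (!isTRUE(recording$normalized))
    recording <- gain_normalize(recording)
  out <- numeric(0)
  for (ch in colnames(recording$signals)) {
    bc <- select_bands(dwt_decompose(recording$signals[, ch],
                                     recording$fs, levels = levels))
    for (band in names(bc$coefficients)) {
      f <- band_features(bc$coefficients[[band]], ...)
      names(f) <- paste(ch, band, names(f), sep = "_")
      out <- c(out, f)
    }
  }
  attr(out, "participant_id") <- recording$participant_id
  attr(out, "class_label") <- recording$class_label
  out
}

#' Feature table for a whole cohort
#'
#' @param cohort A cohort from [generate_cohort()], or a list of
#'   `ppg_recording` objects.
#' @param ... Passed to [participant_features()].
#' @return Data frame: `participant_id`, `class_label`, then one column per
#'   feature.
#' @export
cohort_features <- function(cohort, ...) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  rows <- lapply(recs, function(rec) {
    f <- participant_features(rec, ...)
    d <- as.data.frame(as.list(f))
    cbind(data.frame(participant_id = rec$participant_id,
                     class_label = rec$class_label,
                     stringsAsFactors = FALSE), d)
  })
  do.call(rbind, rows)
}
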