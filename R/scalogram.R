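#' Continuous wavelet transform with the generalized Morse wavelet
#'
#' Analytic CWT computed in the frequency domain. The wavelet is the
#' generalized Morse wavelet with symmetry parameter `gamma = 3` and
#' time-bandwidth product `P^2 = beta * gamma = 60` (the common analytic
#' default), peak-normalised so that a unit-amplitude tone yields unit
#' coefficient magnitude at the matching scale regardless of frequency.
#' Scales are spaced logarithmically with `voices_per_octave` voices per
#' frequency doubling. The window is reflection-padded before the FFT to
#' suppress circular wrap-around at the low-frequency scales.
#'
#' @param window A `signal_window` from [window_signal()], or a numeric
#'   vector (then `fs` must be given).
#' @param fs Sampling rate (Hz); taken from the window if omitted.
#' @param voices_per_octave Voices per octave (default 12).
#' @param freq_range Frequency span (Hz) covered by the scales. The default
#'   spans 0.3 Hz to min(25, fs/2.1) Hz, covering the 0.5-20 Hz PPG band.
#' @param gamma Morse symmetry parameter.
#' @param time_bandwidth Morse time-bandwidth product `P^2`.
#' @return Object of class `ppg_cwt`: list with `coefficients` (complex
#'   matrix, frequencies x time, frequency rows descending), `frequencies`
#'   (Hz), `fs` and `provenance`.
#' @export
cwt_morse <- function(window, fs = NULL, voices_per_octave = 12,
                      freq_range = NULL, gamma = 3, time_bandwidth = 60) {
  prov <- NULL
  if (inherits(window, "signal_window")) {
    prov <- window[c("participant_id", "class_label", "channel",
                     "window_index")]
    fs <- window$fs
    x <- window$samples
  } else {
    x <- as.numeric(window)
    if (is.null(fs)) stop("fs must be supplied for a plain numeric window")
  }
  n <- length(x)
  if (n < 2 * fs) stop("window must span at least 2 seconds")
  if (fs / 2 < 20) stop("fs too low to reach the 20 Hz band edge")
  if (is.null(freq_range)) freq_range <- c(0.3, min(25, fs / 2.1))
  if (freq_range[2] > fs / 2) stop("freq_range exceeds Nyquist")
  v <- voices_per_octave
  n_oct <- floor(v * log2(freq_range[2] / freq_range[1]))
  freqs <- freq_range[2] * 2^(-(0:n_oct) / v)

  # reflection padding to the next power of two
  m <- stats::nextn(ceiling(1.3 * n), 2)
  pad <- m - n
  pl <- pad %/% 2
  pr <- pad - pl
  refl <- function(k, len) {
    if (k == 0) return(integer(0))
    idx <- rep(c(seq(len, 1), seq(1, len)), length.out = k + len)
    idx[seq_len(k)]
  }
  xp <- c(x[rev(refl(pl, n))], x, x[n + 1 - refl(pr, n)])
  xf <- stats::fft(xp)

  bank_key <- sprintf("morse_%d_%g_%d_%g_%g_%g_%g", m, fs, v,
                      freq_range[1], freq_range[2], gamma, time_bandwidth)
  bank <- cached(bank_key, {
    beta <- time_bandwidth / gamma
    wp <- (beta / gamma)^(1 / gamma)        # peak angular frequency
    log_peak <- beta * log(wp) - wp^gamma   # peak normalisation constant
    w <- 2 * pi * (0:(m - 1)) / m
    pos <- seq(2, m %/% 2 + 1)              # positive, non-zero frequencies
    psis <- matrix(0, length(freqs), m)
    for (j in seq_along(freqs)) {
      s <- wp * fs / (2 * pi * freqs[j])
      sw <- s * w[pos]
      psis[j, pos] <- 2 * exp(beta * log(sw) - sw^gamma - log_peak)
    }
    psis
  })

  coefs <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    row <- stats::fft(xf * bank[j, ], inverse = TRUE) / m
    coefs[j, ] <- row[(pl + 1):(pl + n)]
  }
  structure(list(coefficients = coefs, frequencies = freqs, fs = fs,
                 provenance = prov),
            class = "ppg_cwt")
}

#' Percent-energy scalogram of CWT coefficients
#'
#' Squares the coefficient magnitudes (`|coef|^2`, the energy of the complex
#' analytic coefficients) and normalises the matrix so its grand total is
#' 100: each cell is the percentage of window energy at that
#' frequency-and-time. An identically zero window has no energy to
#' distribute; it is flagged degenerate (returns `NULL` with a warning) and
#' should be excluded upstream.
#'
#' @param cwt A `ppg_cwt` from [cwt_morse()].
#' @return Object of class `ppg_scalogram` (`values`, `frequencies`, `times`,
#'   `provenance`), or `NULL` for a degenerate window.
#' @export
to_scalogram <- function(cwt) {
  s <- Mod(cwt$coefficients)^2
  tot <- sum(s)
  if (!is.finite(tot) || tot == 0) {
    warning("degenerate (zero-energy) window excluded from scalogram stage")
    return(NULL)
  }
  structure(list(values = 100 * s / tot,
                 frequencies = cwt$frequencies,
                 times = (seq_len(ncol(s)) - 1) / cwt$fs,
                 provenance = cwt$provenance),
            class = "ppg_scalogram")
}

# Cubic convolution kernel (Keys, a = -0.5), the classic bicubic
# interpolation kernel.
cubic_kernel <- function(u) {
  u <- abs(u)
  ifelse(u <= 1, 1.5 * u^3 - 2.5 * u^2 + 1,
         ifelse(u < 2, -0.5 * u^3 + 2.5 * u^2 - 4 * u + 2, 0))
}

# Session cache for resize weight matrices, colour maps and CWT filter
# banks (all pure functions of their parameters).
.ppg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ppg_cache))
    assign(key, force(expr), envir = .ppg_cache)
  get(key, envir = .ppg_cache)
}

# Weight matrix (n_in x n_out) for separable bicubic resizing with
# antialiasing when shrinking (kernel stretched by the inverse scale).
resize_weights_build <- function(n_in, n_out) {
  scale <- n_out / n_in
  kw <- if (scale < 1) 2 / scale else 2
  W <- matrix(0, n_in, n_out)
  for (j in seq_len(n_out)) {
    centre <- (j - 0.5) / scale + 0.5
    lo <- floor(centre - kw)
    hi <- ceiling(centre + kw)
    idx <- lo:hi
    u <- centre - idx
    wts <- if (scale < 1) cubic_kernel(u * scale) else cubic_kernel(u)
    idx <- pmin(pmax(idx, 1), n_in)        # clamp at the borders
    wts <- wts / sum(wts)
    for (t in seq_along(idx)) W[idx[t], j] <- W[idx[t], j] + wts[t]
  }
  W
}

resize_weights <- function(n_in, n_out) {
  cached(sprintf("rw_%d_%d", n_in, n_out), resize_weights_build(n_in, n_out))
}

bicubic_resize <- function(mat, out_rows, out_cols) {
  Wr <- resize_weights(nrow(mat), out_rows)
  Wc <- resize_weights(ncol(mat), out_cols)
  t(Wr) %*% mat %*% Wc
}

#' Colour map used to render scalogram images
#'
#' Fixed 256-level perceptually uniform map (viridis family: dark blue
#' through green to yellow, brighter colours meaning higher energy), pinned
#' so rendered images are reproducible across runs.
#'
#' @param name Palette name understood by [grDevices::hcl.colors()].
#' @return 256 x 3 integer matrix of RGB values in 0-255.
#' @export
scalogram_colormap <- function(name = "viridis") {
  cached(paste0("cmap_", name),
         t(grDevices::col2rgb(grDevices::hcl.colors(256, name))))
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Crops the frequency axis to `freq_range`, resizes the percent-energy
#' matrix to `size` with bicubic interpolation (antialiased when shrinking),
#' min-max scales the result per image, and maps it through a fixed monotone
#' colour map. Row 1 of the image is the highest frequency. No axes or
#' colour-bar pixels are added. Because the scalogram is already
#' amplitude-normalised and the colour scaling is per-image min-max, the
#' rendered image is invariant to positive scaling of the source signal.
#'
#' @param sm A `ppg_scalogram`.
#' @param colormap Palette name (see [scalogram_colormap()]).
#' @param freq_range Frequency crop in Hz (default 0-20, matching the PPG
#'   amplifier band).
#' @param size Output height and width in pixels (default 224 x 224).
#' @return Object of class `ppg_scalogram_image`: integer array
#'   `size[1] x size[2] x 3` with values in 0-255, plus provenance.
#' @export
render_image <- function(sm, colormap = "viridis", freq_range = c(0, 20),
                         size = c(224, 224)) {
  keep <- sm$frequencies >= freq_range[1] & sm$frequencies <= freq_range[2]
  if (!any(keep)) stop("frequency crop leaves no scalogram rows")
  vals <- sm$values[keep, , drop = FALSE]
  img <- bicubic_resize(vals, size[1], size[2])
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
         else matrix(0, size[1], size[2])
  idx <- pmin(pmax(floor(img * 256) + 1L, 1L), 256L)
  cmap <- scalogram_colormap(colormap)
  px <- array(0L, c(size[1], size[2], 3L))
  for (c3 in 1:3) px[, , c3] <- matrix(cmap[idx, c3], size[1], size[2])
  structure(list(pixels = px, provenance = sm$provenance,
                 colormap = colormap, freq_range = freq_range),
            class = "ppg_scalogram_image")
}

#' Write a scalogram image to a PNG file
#'
#' @param img A `ppg_scalogram_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG files")
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
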