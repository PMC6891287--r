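# Calibrated scale-cutoff constant for the automatic scale-bound rule:
# s_max = n_samples / (k * sigma_t). Frozen so that the default analysis
# configuration (gamma = 3, P^2 = 60, 10 voices/octave, 400-sample window at
# 500 Hz) yields exactly 69 scales.
MORSE_SCALE_CUTOFF <- 1.9803

# Gamma-function moment of the Morse spectrum: I(p) = integral over omega of
# omega^p exp(-2 omega^gamma).
morse_moment <- function(p, gam) {
  (1 / gam) * 2^(-(p + 1) / gam) * gamma((p + 1) / gam)
}

# Time standard deviation of the mother wavelet, from closed-form frequency-
# domain moments: var_t = ||Psi'||^2 / ||Psi||^2 with Psi = w^beta e^{-w^gamma}.
morse_sigma_t <- function(gam, beta) {
  num <- beta^2 * morse_moment(2 * beta - 2, gam) -
    2 * beta * gam * morse_moment(2 * beta - 2 + gam, gam) +
    gam^2 * morse_moment(2 * beta - 2 + 2 * gam, gam)
  sqrt(num / morse_moment(2 * beta, gam))
}

#' Analytic Morse wavelet filter bank
#'
#' Builds a bank of analytic generalized Morse wavelets
#' `Psi(w) = a w^beta exp(-w^gamma)` for `w > 0` (exactly zero at negative
#' frequencies), with symmetry parameter `gamma = 3` and time-bandwidth
#' product `P^2 = 60` (so `beta = P^2 / gamma = 20`) by default. The peak
#' (center) angular frequency of the mother wavelet is
#' `w_p = (beta/gamma)^(1/gamma)`.
#'
#' Scales form a geometric grid with `voices_per_octave` scales per octave.
#' The bounds follow the energy-spread rule: the smallest scale places the
#' wavelet peak at the Nyquist frequency (`s_min = w_p / pi`), and the
#' largest scale limits the wavelet's time support to the window,
#' `s_max = n_samples / (k * sigma_t)` where `sigma_t` is the mother
#' wavelet's time standard deviation and `k` is a calibrated cutoff constant
#' frozen in the package (see `MORSE_SCALE_CUTOFF` in the sources). With the
#' defaults and a 400-sample window at 500 Hz this yields 69 scales, i.e.
#' 69 x 400 scalograms. Rows are ordered small scale (high frequency) first.
#'
#' @param fs Sampling rate in Hz.
#' @param n_samples Window length in samples (>= 32).
#' @param gamma Symmetry parameter.
#' @param time_bandwidth Time-bandwidth product `P^2` (`beta = P^2/gamma`,
#'   which must exceed 1 for analyticity and zero mean).
#' @param voices_per_octave Scales per octave of the geometric grid.
#' @return An object of class `"morse_bank"`: list with `scales`,
#'   `frequencies` (Hz, descending), `filters` (n_scales x n_samples matrix
#'   of frequency responses on the DFT grid), and the parameters.
#' @export
morse_bank <- function(fs, n_samples, gamma = 3, time_bandwidth = 60,
                       voices_per_octave = 10) {
  stopifnot(gamma > 0, time_bandwidth > gamma)
  if (n_samples < 32) stop("window too short for a filter bank (need >= 32)")
  beta <- time_bandwidth / gamma
  wp <- (beta / gamma)^(1 / gamma)
  s_min <- wp / pi
  s_max <- n_samples / (MORSE_SCALE_CUTOFF * morse_sigma_t(gamma, beta))
  if (s_max <= s_min * 2)
    stop("window too short: fewer than one octave of usable scales")
  n_scales <- floor(voices_per_octave * log2(s_max / s_min)) + 1
  scales <- s_min * 2^((seq_len(n_scales) - 1) / voices_per_octave)
  # DFT angular frequency grid; keep only non-negative bins (analytic bank)
  w <- 2 * pi * (0:(n_samples - 1)) / n_samples
  pos <- w <= pi  # include Nyquist bin for even n
  filters <- matrix(0, n_scales, n_samples)
  for (i in seq_len(n_scales)) {
    sw <- scales[i] * w[pos]
    filters[i, pos] <- ifelse(sw > 0, 2 * exp(beta * log(sw / wp) -
                                                sw^gamma + wp^gamma), 0)
  }
  structure(list(scales = scales, frequencies = wp / (2 * pi * scales) * fs,
                 filters = filters, fs = fs, n_samples = n_samples,
                 gamma = gamma, beta = beta,
                 time_bandwidth = time_bandwidth,
                 voices_per_octave = voices_per_octave, peak_omega = wp),
            class = "morse_bank")
}

#' @export
print.morse_bank <- function(x, ...) {
  cat(sprintf("<morse_bank> gamma=%g, P^2=%g (beta=%g), %d voices/octave\n",
              x$gamma, x$time_bandwidth, x$beta, x$voices_per_octave))
  cat(sprintf("  %d scales for %d samples @ %g Hz; center freqs %.2f-%.2f Hz\n",
              length(x$scales), x$n_samples, x$fs,
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Continuous wavelet transform scalogram
#'
#' Computes the magnitude scalogram of a real segment: the absolute value of
#' its continuous wavelet transform coefficients at every scale of a
#' [morse_bank()], evaluated by frequency-domain multiplication (one FFT of
#' the segment, one inverse FFT per scale).
#'
#' @param x Real numeric vector whose length matches the bank's `n_samples`.
#' @param bank A [morse_bank()].
#' @return An object of class `"scalogram"`: list with `magnitudes`
#'   (nonnegative n_scales x n_samples matrix, high frequency in row 1),
#'   `scales` and `frequencies` (Hz).
#' @export
cwt_scalogram <- function(x, bank) {
  stopifnot(inherits(bank, "morse_bank"))
  x <- as.numeric(x)
  if (length(x) != bank$n_samples)
    stop("segment length (", length(x), ") does not match bank n_samples (",
         bank$n_samples, ")")
  X <- fft(x)
  spec <- bank$filters * matrix(X, nrow(bank$filters), length(x), byrow = TRUE)
  coefs <- t(mvfft(t(spec), inverse = TRUE)) / length(x)
  structure(list(magnitudes = Mod(coefs), scales = bank$scales,
                 frequencies = bank$frequencies),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d samples, %.2f-%.2f Hz\n",
              nrow(x$magnitudes), ncol(x$magnitudes),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}
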