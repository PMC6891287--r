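#' Band-pass filter specification for the mu/beta band
#'
#' Frequency template of the equiripple FIR band-pass used before spatial
#' filtering: passband 7--30 Hz (covering the mu rhythm at 8--13 Hz and the
#' beta band at 13--30 Hz), stopbands below 5 Hz and above 33 Hz with at
#' least 65 dB attenuation. This band excludes the dominant artifact
#' components: eye blink (< 4 Hz), heartbeat (about 1.2 Hz), mains hum
#' (60 Hz) and muscle activity (> 30 Hz).
#'
#' @param f_pass_lo,f_pass_hi Passband edges in Hz.
#' @param f_stop_lo,f_stop_hi Stopband edges in Hz.
#' @param stop_atten_db Minimum stopband attenuation in dB (positive).
#' @param pass_ripple_db Maximum passband deviation from 0 dB, in dB.
#' @param fs Sampling rate in Hz.
#' @return An object of class `"bandpass_spec"`.
#' @export
bandpass_spec <- function(f_pass_lo = 7, f_pass_hi = 30,
                          f_stop_lo = 5, f_stop_hi = 33,
                          stop_atten_db = 65, pass_ripple_db = 0.5,
                          fs = 500) {
  if (!(f_stop_lo < f_pass_lo && f_pass_lo < f_pass_hi &&
        f_pass_hi < f_stop_hi && f_stop_hi < fs / 2))
    stop("infeasible band-pass spec: need f_stop_lo < f_pass_lo < ",
         "f_pass_hi < f_stop_hi < fs/2")
  if (stop_atten_db <= 0 || pass_ripple_db <= 0)
    stop("stop_atten_db and pass_ripple_db must be positive")
  structure(list(f_pass_lo = f_pass_lo, f_pass_hi = f_pass_hi,
                 f_stop_lo = f_stop_lo, f_stop_hi = f_stop_hi,
                 stop_atten_db = stop_atten_db,
                 pass_ripple_db = pass_ripple_db, fs = fs),
            class = "bandpass_spec")
}

# Magnitude response (linear) of an FIR filter at frequencies f (Hz).
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(fr) Mod(sum(h * exp(-2i * pi * fr / fs * k))), 0)
}

# Herrmann/Kaiser order estimate for an equiripple FIR with passband
# deviation dp, stopband deviation ds and narrowest transition df (Hz).
estimate_order <- function(dp, ds, df, fs) {
  ceiling((-10 * log10(dp * ds) - 13) / (14.6 * df / fs))
}

#' Design the equiripple band-pass filter
#'
#' Designs a linear-phase equiripple (Parks-McClellan) FIR band-pass meeting
#' a [bandpass_spec]. The order is chosen automatically by the standard
#' equiripple order estimator, rounded up to even (odd length, integer group
#' delay), then verified against the measured magnitude response at 64 probe
#' frequencies per band and increased until the template is met.
#'
#' @param spec A [bandpass_spec].
#' @param probes Probe frequencies per band used for verification.
#' @return Numeric vector of filter coefficients, with the spec attached as
#'   attribute `"spec"`.
#' @export
design_bandpass <- function(spec = bandpass_spec(), probes = 64) {
  stopifnot(inherits(spec, "bandpass_spec"))
  nyq <- spec$fs / 2
  dp <- 10^(spec$pass_ripple_db / 20) - 1
  ds <- 10^(-spec$stop_atten_db / 20)
  df <- min(spec$f_pass_lo - spec$f_stop_lo, spec$f_stop_hi - spec$f_pass_hi)
  ord <- estimate_order(dp, ds, df, spec$fs)
  if (ord %% 2 == 1) ord <- ord + 1
  bands <- c(0, spec$f_stop_lo, spec$f_pass_lo, spec$f_pass_hi,
             spec$f_stop_hi, nyq) / nyq
  for (attempt in 1:8) {
    h <- signal::remez(ord, bands, c(0, 0, 1, 1, 0, 0),
                       w = c(dp / ds, 1, dp / ds), density = 20)
    if (bandpass_meets_spec(h, spec, probes)) {
      attr(h, "spec") <- spec
      return(h)
    }
    ord <- ord + 2 * ceiling(0.05 * ord)
  }
  stop("equiripple design failed to meet the template; spec may be infeasible")
}

# Check the measured response of h against the spec at `probes` frequencies
# per band.
bandpass_meets_spec <- function(h, spec, probes = 64) {
  fp <- seq(spec$f_pass_lo, spec$f_pass_hi, length.out = probes)
  fs1 <- seq(0, spec$f_stop_lo, length.out = probes)
  fs2 <- seq(spec$f_stop_hi, spec$fs / 2, length.out = probes)
  hp <- 20 * log10(fir_response(h, fp, spec$fs))
  hs <- 20 * log10(pmax(fir_response(h, c(fs1, fs2), spec$fs), 1e-300))
  all(abs(hp) <= spec$pass_ripple_db) && all(hs <= -spec$stop_atten_db)
}

#' Apply an FIR band-pass to a recording
#'
#' Filters each channel independently (overlap-add FFT filtering) and
#' compensates the linear-phase group delay by shifting the output left by
#' `(L-1)/2` samples and zero-padding the tail, so the output is time-aligned
#' with the input and has the same length. Filtering is causal; no
#' forward-backward pass is applied, so the realized attenuation equals the
#' designed one.
#'
#' @param rec An [eeg_recording].
#' @param h FIR coefficients from [design_bandpass()].
#' @return The filtered [eeg_recording].
#' @export
apply_bandpass <- function(rec, h = design_bandpass()) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- length(h)
  n <- ncol(rec$data)
  if (n <= 3L * L)
    stop("signal too short: need more than 3 x filter length (",
         3L * L, ") samples, got ", n)
  delay <- (L - 1) %/% 2
  out <- t(apply(rec$data, 1, function(x) {
    y <- signal::fftfilt(h, c(x, numeric(delay)))
    y[(delay + 1):(delay + n)]
  }))
  eeg_recording(out, fs = rec$fs, channel_names = rec$channel_names,
                subject_id = rec$subject_id, series_id = rec$series_id)
}

#' Z-score normalize each channel
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation, computed over the whole recording. A channel with zero standard
#' deviation is an error (named in the message), not a silent NaN.
#'
#' @param rec An [eeg_recording].
#' @return The normalized [eeg_recording] (each channel mean 0, SD 1).
#' @export
zscore_normalize <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  mu <- rowMeans(rec$data)
  sdv <- apply(rec$data, 1, sd)
  bad <- sdv == 0
  if (any(bad))
    stop("degenerate channel(s) with zero standard deviation: ",
         paste(rec$channel_names[bad], collapse = ", "))
  eeg_recording((rec$data - mu) / sdv, fs = rec$fs,
                channel_names = rec$channel_names,
                subject_id = rec$subject_id, series_id = rec$series_id)
}
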