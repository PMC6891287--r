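# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, envir = .fixture_env)
}

# The default equiripple band-pass (547 taps) -- designed once.
fx_filter <- function() memo("bp_filter", function() design_bandpass())

# Default Morse bank for 400-sample windows at 500 Hz.
fx_bank <- function() memo("bank400", function() morse_bank(500, 400))

# A small strong-separation recording, band-passed and epoched, with its
# scenario and one-vs-rest CSP fits.
fx_strong <- function() memo("strong", function() {
  scen <- standard_scenario("strong", seed = 3, n_trials = 20)
  sim <- generate_eeg(scen, seed = 4)
  filt <- zscore_normalize(apply_bandpass(sim$recording, fx_filter()))
  epochs <- extract_epochs(filt, sim$events)
  list(scenario = scen, sim = sim, filtered = filt, epochs = epochs,
       models = one_vs_rest_fit(epochs, seed = 5))
})

# A toy 32-channel recording with named channels.
fx_rec32 <- function() memo("rec32", function() {
  set.seed(11)
  names32 <- c(gal_channels,
               paste0("X", sprintf("%02d", 1:26)))
  eeg_recording(matrix(rnorm(32 * 600), 32), fs = 500,
                channel_names = names32)
})

# Epochs with all six classes from random data (for structural tests that do
# not need a separable signal).
fx_epochs6 <- function(n_per_class = 8, n_ch = 6, win = 64) {
  set.seed(21)
  n <- 6 * n_per_class
  structure(list(epochs = array(rnorm(n_ch * win * n), c(n_ch, win, n)),
                 labels = rep(1:6, each = n_per_class),
                 starts = seq(0, by = win, length.out = n),
                 window_length = win, step = win, fs = 500,
                 channel_names = paste0("ch", 1:n_ch)),
            class = "epoch_set")
}

# Random symmetric positive-definite matrix with unit trace.
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  R <- crossprod(A) + 0.1 * diag(n)
  R / sum(diag(R))
}

# Epochs whose trace-normalized covariance equals R exactly (single epoch,
# X = chol factor, so X X' = R).
epochs_with_cov <- function(R) list(t(chol(R)))
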