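test_that("generation is deterministic under a fixed seed", {
  scen <- standard_scenario("strong", seed = 2, n_trials = 2)
  a <- generate_eeg(scen, seed = 5)
  b <- generate_eeg(scen, seed = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
  c <- generate_eeg(scen, seed = 6)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("a single noiseless source stays inside its band", {
  scen <- sim_scenario(mixing = diag(6) + 0.01,
                       source_freqs = c(15, 9, 12, 18, 21, 25),
                       source_bw = 2,
                       class_variances = matrix(rep(c(1, 0, 0, 0, 0, 0),
                                                    each = 6), 6),
                       noise_sd = 0, n_trials = 3)
  sim <- generate_eeg(scen, seed = 9)
  for (ch in 1:6) {
    x <- sim$recording$data[ch, ]
    if (sd(x) == 0) next
    spec <- Mod(fft(x))^2
    f <- (seq_along(spec) - 1) / length(spec) * 500
    half <- f <= 250
    inband <- half & f >= 13 & f <= 17
    expect_gte(sum(spec[inband]) / sum(spec[half]), 0.99)
  }
})

test_that("annotations partition each trial into six ordered event blocks", {
  scen <- standard_scenario("strong", seed = 2, n_trials = 4)
  sim <- generate_eeg(scen, seed = 7)
  ann <- sim$events
  # every sample belongs to exactly one event
  expect_true(all(colSums(ann) == 1))
  # the active-event sequence is HS,GS,LT,HD,RP,RL repeated per trial
  active <- apply(ann, 2, which.max)
  runs <- rle(active)$values
  expect_identical(runs, rep(1:6, 4))
  # block durations within the configured range
  lens <- rle(active)$lengths
  expect_true(all(lens >= 0.8 * 500 & lens <= 2.0 * 500))
})

test_that("strong and weak scenarios bracket the CSP spectra", {
  strong <- fx_strong()
  for (m in strong$models) expect_gte(max(m$Delta1), 0.8)

  weak_scen <- standard_scenario("weak", seed = 3, n_trials = 20)
  sim <- generate_eeg(weak_scen, seed = 4)
  filt <- zscore_normalize(apply_bandpass(sim$recording, fx_filter()))
  weak_models <- one_vs_rest_fit(extract_epochs(filt, sim$events), seed = 5)
  for (m in weak_models) expect_lte(max(m$Delta1), 0.65)

  # identical class profiles are inseparable
  flat <- standard_scenario("strong", seed = 3, n_trials = 12)
  flat$class_variances <- matrix(1, 6, 6)
  sim_f <- generate_eeg(flat, seed = 4)
  filt_f <- zscore_normalize(apply_bandpass(sim_f$recording, fx_filter()))
  flat_models <- one_vs_rest_fit(extract_epochs(filt_f, sim_f$events),
                                 seed = 5)
  for (m in flat_models) expect_lt(max(m$Delta1), 0.62)
})

test_that("artifact injection is additive and band-separated", {
  set.seed(71)
  rec <- eeg_recording(matrix(rnorm(6 * 6000), 6), 500, gal_channels)
  off <- inject_artifacts(rec, c(blink = 0, heartbeat = 0, line = 0,
                                 muscle = 0))
  expect_identical(off$data, rec$data)

  pgram <- function(x) {
    s <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * 500
    list(f = f[f <= 250], p = s[f <= 250])
  }
  # line artifact: sharp 60 Hz peak before filtering, gone after
  lined <- inject_artifacts(rec, c(line = 10), seed = 1)
  pg <- pgram(lined$data[1, ])
  at60 <- max(pg$p[abs(pg$f - 60) < 0.5])
  nbhd <- max(pg$p[abs(pg$f - 60) > 2 & abs(pg$f - 60) < 8])
  expect_gte(10 * log10(at60 / nbhd), 20)
  filt <- apply_bandpass(lined, fx_filter())
  pgf <- pgram(filt$data[1, ])
  at60f <- max(pgf$p[abs(pgf$f - 60) < 0.5])
  # the 60 Hz peak is attenuated by >= 40 dB (power) and sinks below the
  # in-band level: no longer a peak at all
  expect_lt(10 * log10(at60f / at60), -40)
  expect_lt(at60f, median(pgf$p[pgf$f > 10 & pgf$f < 25]))

  # blink: low-band power rises, mu/beta band nearly unchanged
  bandpow <- function(x, lo, hi) {
    pg <- pgram(x)
    sum(pg$p[pg$f >= lo & pg$f <= hi])
  }
  blinked <- inject_artifacts(rec, c(blink = 40), seed = 2)
  expect_gt(bandpow(blinked$data[1, ], 0, 4),
            2 * bandpow(rec$data[1, ], 0, 4))
  rel <- abs(bandpow(blinked$data[1, ], 7, 30) /
               bandpow(rec$data[1, ], 7, 30) - 1)
  expect_lt(rel, 0.05)
})

test_that("band-pass filtering rescues artifact-contaminated data", {
  # same underlying sources with and without artifacts: after the band-pass,
  # CSP separability and single-contrast AUROC should match closely
  run_one <- function(artifacts_on) {
    scen <- standard_scenario("strong", seed = 13, n_trials = 14,
                              artifacts_on = artifacts_on)
    sim <- generate_eeg(scen, seed = 14)
    filt <- zscore_normalize(apply_bandpass(sim$recording, fx_filter()))
    epochs <- extract_epochs(filt, sim$events)
    ovr <- one_vs_rest_fit(epochs, seed = 15)
    # fast proxy for the decoding stage: score each window by the variance
    # of its top CSP component for the HS contrast
    idx <- which(epochs$labels > 0)
    y <- as.integer(epochs$labels[idx] == 1)
    s <- vapply(idx, function(i)
      var(drop(ovr$HS$W[1, ] %*% epochs$epochs[, , i])), 0)
    roc_auroc(y, s)$auroc
  }
  expect_lt(abs(run_one(TRUE) - run_one(FALSE)), 0.05)
})

test_that("generated recordings survive the CSV round trip", {
  scen <- standard_scenario("strong", seed = 2, n_trials = 1)
  sim <- generate_eeg(scen, seed = 3)
  dp <- tempfile(fileext = ".csv")
  ep <- tempfile(fileext = ".csv")
  write_recording(sim$recording, sim$events, dp, ep)
  back <- read_recording(dp, ep)
  # equal at the written 6-decimal precision (re-parse differs only in the
  # last ulp of the binary representation)
  expect_equal(unname(back$recording$data),
               unname(round(sim$recording$data, 6)), tolerance = 1e-12)
  expect_identical(unname(back$events), unname(sim$events))
})

test_that("scenario construction rejects degenerate inputs", {
  expect_error(sim_scenario(mixing = matrix(1, 6, 6),
                            class_variances = matrix(1, 6, 6)),
               "singular")
  expect_error(sim_scenario(mixing = diag(6),
                            source_freqs = c(9, 12, 15, 18, 21, 400),
                            class_variances = matrix(1, 6, 6)),
               "fs/2")
})
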