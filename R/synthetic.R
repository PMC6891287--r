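# Synthetic grasp-and-lift EEG: band-limited sources with class-specific
# variance profiles, a fixed full-rank spatial mixing, physiological
# artifact components and additive sensor noise. The generator is the test
# bed for every pipeline stage; its band filters are 4th-order Butterworth
# (independent of the analysis FIR, so tests never check a filter against
# itself).

#' Define a simulation scenario
#'
#' A scenario fixes everything the generator needs: the spatial mixing
#' matrix, the per-source oscillator bands, the per-event source variance
#' profiles, artifact amplitudes, sensor noise and trial structure.
#'
#' @param mixing Full-rank `n_channels x n_channels` mixing matrix (columns
#'   are source topographies).
#' @param source_freqs Center frequencies (Hz) of the band-limited sources,
#'   inside (0, fs/2); default spreads six sources over the 7--30 Hz band.
#' @param source_bw Full bandwidth (Hz) of each source oscillator.
#' @param class_variances `6 x n_sources` matrix: row k gives the source
#'   variances during event k.
#' @param artifacts Named amplitudes (microvolts; 0 disables): `blink`
#'   (smoothed sub-4 Hz pulses), `heartbeat` (about 1.2 Hz periodic
#'   waveform), `line` (60 Hz sinusoid), `muscle` (band-limited noise above
#'   30 Hz).
#' @param noise_sd Additive white sensor noise SD (microvolts).
#' @param source_scale Scale (microvolts) of a unit-variance source at the
#'   sensors.
#' @param n_trials Number of grasp-and-lift trials; each trial runs the six
#'   events in their sequential order HS, GS, LT, HD, RP, RL.
#' @param block_duration Range (s) of the uniformly drawn event-block
#'   durations.
#' @param fs Sampling rate in Hz.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(mixing,
                         source_freqs = c(9, 12, 15, 18, 21, 25),
                         source_bw = 4,
                         class_variances,
                         artifacts = c(blink = 0, heartbeat = 0,
                                       line = 0, muscle = 0),
                         noise_sd = 1, source_scale = 10,
                         n_trials = 10, block_duration = c(0.8, 2.0),
                         fs = 500) {
  mixing <- as.matrix(mixing)
  n <- nrow(mixing)
  if (ncol(mixing) != n) stop("mixing must be square")
  if (abs(det(mixing)) < 1e-12) stop("scenario error: singular mixing matrix")
  if (any(source_freqs <= 0 | source_freqs >= fs / 2))
    stop("source center frequencies must lie in (0, fs/2)")
  class_variances <- as.matrix(class_variances)
  stopifnot(nrow(class_variances) == 6, ncol(class_variances) == length(source_freqs),
            length(source_freqs) == n)
  art <- c(blink = 0, heartbeat = 0, line = 0, muscle = 0)
  art[names(artifacts)] <- artifacts
  structure(list(mixing = mixing, source_freqs = source_freqs,
                 source_bw = source_bw, class_variances = class_variances,
                 artifacts = art, noise_sd = noise_sd,
                 source_scale = source_scale, n_trials = n_trials,
                 block_duration = block_duration, fs = fs,
                 n_channels = n),
            class = "sim_scenario")
}

#' Canonical strong/weak separation scenarios
#'
#' The standard fixture for pipeline testing: six events that differ by
#' which source carries elevated variance (event k boosts source k), under a
#' fixed random orthogonal mixing. `"strong"` uses a 10:1 variance ratio,
#' `"weak"` 1.5:1. Artifacts are on at representative amplitudes (blink 40,
#' heartbeat 5, line 10, muscle 3 microvolts against 10-microvolt sources
#' and 1-microvolt sensor noise).
#'
#' @param separation `"strong"` or `"weak"`.
#' @param seed Seed fixing the mixing matrix.
#' @param n_trials Trials per recording.
#' @param artifacts_on Include the artifact components.
#' @return A [sim_scenario()].
#' @export
standard_scenario <- function(separation = c("strong", "weak"), seed = 1,
                              n_trials = 10, artifacts_on = TRUE) {
  separation <- match.arg(separation)
  ratio <- if (separation == "strong") 10 else 1.5
  mixing <- with_seed(seed, qr.Q(qr(matrix(rnorm(36), 6, 6))))
  cv <- matrix(1, 6, 6)
  diag(cv) <- ratio
  sim_scenario(mixing = mixing, class_variances = cv,
               artifacts = if (artifacts_on)
                 c(blink = 40, heartbeat = 5, line = 10, muscle = 3)
               else c(blink = 0, heartbeat = 0, line = 0, muscle = 0),
               n_trials = n_trials)
}

#' Planted discriminative direction of a scenario
#'
#' The spatial filter that exactly extracts source `event` from the mixture:
#' the corresponding row of the unmixing matrix, normalized to unit length.
#' CSP parameter-recovery tests compare the fitted top filter against it.
#'
#' @param scenario A [sim_scenario()].
#' @param event Event index 1--6 or label ("HS", ...).
#' @return Unit-norm numeric vector of length `n_channels`.
#' @export
planted_direction <- function(scenario, event) {
  if (is.character(event)) event <- match(event, gal_events)
  w <- solve(scenario$mixing)[event, ]
  w / sqrt(sum(w^2))
}

# 4th-order Butterworth band filter applied forward-backward (zero phase);
# generator-internal, independent of the analysis FIR.
butter_band <- function(x, lo, hi, fs, type = "pass") {
  ny <- fs / 2
  flt <- if (type == "pass") signal::butter(4, c(lo, hi) / ny, "pass")
  else if (type == "low") signal::butter(4, hi / ny, "low")
  else signal::butter(4, lo / ny, "high")
  as.numeric(signal::filtfilt(flt, x))
}

#' Generate a synthetic recording from a scenario
#'
#' Each trial concatenates six event blocks in the sequential order HS, GS,
#' LT, HD, RP, RL, with block durations drawn uniformly from the scenario's
#' range. Within a block, band-limited Gaussian sources carry the event's
#' variance profile; the mixed signal is scaled to microvolts, artifacts are
#' added, then white sensor noise. Per-sample annotations mark the active
#' event. Fully reproducible under a fixed seed.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (NULL = current RNG stream).
#' @param subject_id,series_id Identifiers for the recording.
#' @return List with `recording` ([eeg_recording], channels named C3, Cz,
#'   C4, P3, Pz, P4 for six channels) and `events` (6 x n annotations).
#' @export
generate_eeg <- function(scenario, seed = NULL, subject_id = "sim",
                         series_id = "s1") {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(seed, {
    fs <- scenario$fs
    n_src <- length(scenario$source_freqs)
    durs <- matrix(runif(scenario$n_trials * 6, scenario$block_duration[1],
                         scenario$block_duration[2]),
                   scenario$n_trials, 6)
    lens <- round(durs * fs)
    n_total <- sum(lens)
    # continuous unit-variance band-limited carriers, then per-block gains
    S <- vapply(seq_len(n_src), function(j) {
      lo <- scenario$source_freqs[j] - scenario$source_bw / 2
      hi <- scenario$source_freqs[j] + scenario$source_bw / 2
      s <- butter_band(rnorm(n_total), lo, hi, fs)
      s / sd(s)
    }, numeric(n_total))
    gains <- matrix(0, n_total, n_src)
    ann <- matrix(0L, 6, n_total)
    pos <- 0L
    for (tr in seq_len(scenario$n_trials)) {
      for (ev in 1:6) {
        idx <- pos + seq_len(lens[tr, ev])
        gains[idx, ] <- matrix(sqrt(scenario$class_variances[ev, ]),
                               length(idx), n_src, byrow = TRUE)
        ann[ev, idx] <- 1L
        pos <- pos + lens[tr, ev]
      }
    }
    X <- scenario$mixing %*% t(S * gains) * scenario$source_scale
    ch <- if (nrow(X) == 6) gal_channels else paste0("ch", seq_len(nrow(X)))
    rec <- eeg_recording(X, fs = fs, channel_names = ch,
                         subject_id = subject_id, series_id = series_id)
    rec <- inject_artifacts(rec, scenario$artifacts)
    if (scenario$noise_sd > 0)
      rec$data <- rec$data + matrix(rnorm(length(rec$data), 0,
                                          scenario$noise_sd),
                                    nrow(rec$data))
    list(recording = rec, events = event_annotations(ann))
  })
}

#' Add physiological and line artifacts to a recording
#'
#' Adds, per enabled component: eye-blink bursts (random pulses smoothed to
#' sub-4 Hz), an approximately 1.2 Hz periodic heartbeat waveform, a 60 Hz
#' line sinusoid, and band-limited muscle noise above 30 Hz. All components
#' are additive; with every amplitude zero the recording is returned
#' unchanged. Each channel receives the artifact with a random gain in
#' `[0.5, 1]`, emulating uneven scalp spread.
#'
#' @param rec An [eeg_recording].
#' @param amplitudes Named vector (`blink`, `heartbeat`, `line`, `muscle`)
#'   of amplitudes in microvolts; missing names default to 0.
#' @param seed Integer seed (NULL = current RNG stream).
#' @return The augmented [eeg_recording].
#' @export
inject_artifacts <- function(rec, amplitudes, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  amp <- c(blink = 0, heartbeat = 0, line = 0, muscle = 0)
  amp[names(amplitudes)] <- amplitudes
  if (all(amp == 0)) return(rec)
  with_seed(seed, {
    n <- ncol(rec$data)
    nc <- nrow(rec$data)
    fs <- rec$fs
    t <- (seq_len(n) - 1) / fs
    add <- function(sig, a) {
      gains <- runif(nc, 0.5, 1)
      rec$data <<- rec$data + a * gains %o% sig
    }
    if (amp["blink"] > 0) {
      # ~0.3 blinks/s: unit impulses smoothed by a 0.1 s SD Gaussian, whose
      # spectrum is confined well below 4 Hz
      pulses <- numeric(n)
      k <- max(1, rpois(1, 0.3 * n / fs))
      pulses[sample.int(n, min(k, n))] <- 1
      kern <- dnorm(seq(-3, 3, length.out = round(0.6 * fs) + 1))
      sm <- stats::filter(pulses, kern / max(kern), circular = TRUE)
      add(as.numeric(sm), amp["blink"])
    }
    if (amp["heartbeat"] > 0) {
      # periodic raised-cosine pulse train at 1.2 Hz
      period <- 1 / 1.2
      phase <- (t %% period) / period
      beat <- ifelse(phase < 0.15, 0.5 * (1 - cos(2 * pi * phase / 0.15)), 0)
      add(beat, amp["heartbeat"])
    }
    if (amp["line"] > 0)
      add(sin(2 * pi * 60 * t), amp["line"])
    if (amp["muscle"] > 0) {
      hi <- min(0.96 * fs / 2, 110)
      mus <- butter_band(rnorm(n), 35, hi, fs)
      add(mus / sd(mus), amp["muscle"])
    }
    rec
  })
}
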