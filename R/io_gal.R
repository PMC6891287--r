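#' Construct an EEG recording
#'
#' An `eeg_recording` is the basic signal container: a channels-by-samples
#' numeric matrix (microvolts) together with its sampling rate and ordered
#' channel names.
#'
#' @param data Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of unique electrode labels, one per
#'   row of `data`.
#' @param subject_id,series_id Opaque identifiers carried through unchanged.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs, channel_names,
                          subject_id = "subj", series_id = "series") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (ncol(data) < 1L) stop("recording must contain at least one sample")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, series_id = series_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  subject:", x$subject_id, " series:", x$series_id, "\n")
  invisible(x)
}

#' Construct per-sample event annotations
#'
#' Validates a 6 x n_samples binary matrix whose rows follow the fixed event
#' order [gal_events] (HS, GS, LT, HD, RP, RL).
#'
#' @param labels Binary (0/1) matrix with 6 rows.
#' @return An integer 6 x n matrix with `gal_events` as row names.
#' @export
event_annotations <- function(labels) {
  labels <- as.matrix(labels)
  if (nrow(labels) != 6L)
    stop("annotations must have exactly 6 rows (one per event)")
  if (!all(labels %in% c(0, 1)))
    stop("annotation entries must be 0 or 1")
  storage.mode(labels) <- "integer"
  rownames(labels) <- gal_events
  labels
}

#' Read a grasp-and-lift CSV pair
#'
#' Reads the two-file CSV dialect: a data file with columns `id,<electrode>...`
#' (samples in microvolts, one row per sample) and a parallel events file with
#' columns `id,HS,GS,LT,HD,RP,RL` of per-sample binary annotations. Rows are
#' matched positionally and the two files must agree on their `id` strings.
#' Gzip-compressed files (`.gz`) are handled transparently.
#'
#' @param data_path,events_path Paths to the data and events CSV files.
#' @param fs Sampling rate in Hz; the format itself does not record it.
#' @param subject_id,series_id Identifiers attached to the recording.
#' @return A list with elements `recording` ([eeg_recording]) and `events`
#'   (6 x n annotation matrix).
#' @export
read_recording <- function(data_path, events_path, fs = 500,
                           subject_id = "subj", series_id = "series") {
  for (p in c(data_path, events_path))
    if (!file.exists(p)) stop("file not found: ", p)
  dat <- data.table::fread(data_path, data.table = FALSE)
  evt <- data.table::fread(events_path, data.table = FALSE)
  if (names(dat)[1] != "id" || names(evt)[1] != "id")
    stop("format error: first column of both CSVs must be 'id'")
  if (nrow(dat) != nrow(evt))
    stop("alignment error: data has ", nrow(dat), " rows but events has ",
         nrow(evt))
  if (!identical(as.character(dat$id), as.character(evt$id)))
    stop("alignment error: id columns of the data and events files differ")
  if (!identical(sort(names(evt)[-1]), sort(gal_events)))
    stop("format error: unknown event columns: ",
         paste(setdiff(names(evt)[-1], gal_events), collapse = ", "))
  rec <- eeg_recording(t(as.matrix(dat[, -1, drop = FALSE])), fs = fs,
                       channel_names = names(dat)[-1],
                       subject_id = subject_id, series_id = series_id)
  ann <- event_annotations(t(as.matrix(evt[, gal_events, drop = FALSE])))
  list(recording = rec, events = ann)
}

#' Write a grasp-and-lift CSV pair
#'
#' Inverse of [read_recording()]. Sample values are written with 6 decimal
#' places, so a write/read round trip is exact at that precision.
#'
#' @param rec An [eeg_recording].
#' @param ann A 6 x n annotation matrix (see [event_annotations()]).
#' @param data_path,events_path Output paths (`.gz` suffix compresses).
#' @param digits Decimal places for sample values.
#' @return Invisibly, `c(data_path, events_path)`.
#' @export
write_recording <- function(rec, ann, data_path, events_path, digits = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- event_annotations(ann)
  if (ncol(ann) != ncol(rec$data))
    stop("alignment error: annotations and recording differ in sample count")
  ids <- paste0(rec$subject_id, "_", rec$series_id, "_", seq_len(ncol(rec$data)) - 1L)
  dat <- data.frame(id = ids,
                    as.data.frame(round(t(rec$data), digits)),
                    check.names = FALSE)
  names(dat)[-1] <- rec$channel_names
  evt <- data.frame(id = ids, as.data.frame(t(ann)), check.names = FALSE)
  data.table::fwrite(dat, data_path)
  data.table::fwrite(evt, events_path)
  invisible(c(data_path, events_path))
}

#' Select and reorder channels
#'
#' Returns a recording restricted to the requested channels, rows reordered to
#' the requested order. The default selects the six motor/parietal electrodes
#' used for grasp-and-lift decoding.
#'
#' @param rec An [eeg_recording].
#' @param names Channel labels to keep, in the desired output order.
#' @return An [eeg_recording] with `length(names)` channels.
#' @export
select_channels <- function(rec, names = gal_channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(names, rec$channel_names)
  if (length(missing))
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  eeg_recording(rec$data[names, , drop = FALSE], fs = rec$fs,
                channel_names = names,
                subject_id = rec$subject_id, series_id = rec$series_id)
}

#' Cut a recording into labeled sliding windows
#'
#' Windows of `window_length` samples are taken at starts 0, `step`,
#' `2*step`, ... (0-based, half-open) while they fit inside the recording.
#' Each window is labeled with the event that is active on a strict majority
#' of its samples (> half); if no event reaches a majority the window is
#' labeled 0 (non-event). Ties are broken by the fixed order HS > GS > LT >
#' HD > RP > RL. The defaults, 400-sample windows with 100-sample overlap
#' (step 300), are the configuration used throughout the pipeline.
#'
#' @param rec An [eeg_recording].
#' @param ann A 6 x n annotation matrix aligned with `rec`.
#' @param window_length Window length in samples.
#' @param step Hop between window starts in samples.
#' @return An object of class `"epoch_set"`: list with `epochs` (array
#'   `n_channels x window_length x n_epochs`), `labels` (integer, 0 = rest,
#'   1--6 = HS..RL), `starts` (0-based), `window_length`, `step`, `fs`,
#'   `channel_names`.
#' @export
extract_epochs <- function(rec, ann, window_length = 400, step = 300) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- event_annotations(ann)
  n <- ncol(rec$data)
  if (ncol(ann) != n)
    stop("alignment error: annotations and recording differ in sample count")
  if (window_length > n)
    stop("window_length (", window_length, ") exceeds signal length (", n, ")")
  if (step <= 0 || step > window_length)
    stop("step must satisfy 0 < step <= window_length")
  starts <- seq.int(0L, n - window_length, by = step)
  k <- length(starts)
  epochs <- array(0, dim = c(nrow(rec$data), window_length, k))
  labels <- integer(k)
  half <- window_length / 2
  for (i in seq_len(k)) {
    idx <- (starts[i] + 1L):(starts[i] + window_length)
    epochs[, , i] <- rec$data[, idx, drop = FALSE]
    counts <- rowSums(ann[, idx, drop = FALSE])
    top <- which.max(counts)  # first index wins ties: the fixed event order
    labels[i] <- if (counts[top] > half) top else 0L
  }
  structure(list(epochs = epochs, labels = labels, starts = starts,
                 window_length = window_length, step = step, fs = rec$fs,
                 channel_names = rec$channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (step %d)\n",
              dim(x$epochs)[3], dim(x$epochs)[1], x$window_length, x$step))
  tab <- table(factor(x$labels, levels = 0:6,
                      labels = c("rest", gal_events)))
  print(tab)
  invisible(x)
}

# Subset an epoch_set by epoch index, preserving metadata.
subset_epochs <- function(es, idx) {
  structure(list(epochs = es$epochs[, , idx, drop = FALSE],
                 labels = es$labels[idx], starts = es$starts[idx],
                 window_length = es$window_length, step = es$step,
                 fs = es$fs, channel_names = es$channel_names),
            class = "epoch_set")
}
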