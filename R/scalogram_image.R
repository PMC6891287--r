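# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Convert a scalogram to an 8-bit grayscale image
#'
#' Maps the magnitude matrix to integer pixel values 0--255 (round-half-up).
#' Without a reference the mapping is the per-image min-max; with `ref` it is
#' the shared linear map `[0, ref] -> [0, 255]` (values above `ref` clip),
#' which keeps pixel intensities comparable across a whole image dataset so
#' that class-dependent amplitude differences survive quantization. Either
#' mapping is monotone: a larger magnitude never maps to a smaller pixel.
#' A constant scalogram (degenerate range) maps to all-zero pixels.
#'
#' @param sg A [cwt_scalogram()] result, or a nonnegative magnitude matrix.
#' @param ref Optional positive reference magnitude for dataset-level
#'   (global) normalization; `NULL` selects per-image min-max.
#' @return Integer matrix of the same shape with values in 0--255.
#' @export
to_grayscale <- function(sg, ref = NULL) {
  m <- if (inherits(sg, "scalogram")) sg$magnitudes else as.matrix(sg)
  if (!is.null(ref)) {
    stopifnot(is.numeric(ref), length(ref) == 1L, ref > 0)
    px <- round_half_up(pmin(m / ref, 1) * 255)
    storage.mode(px) <- "integer"
    return(px)
  }
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) {
    px <- matrix(0L, nrow(m), ncol(m))
  } else {
    px <- round_half_up((m - rng[1]) / (rng[2] - rng[1]) * 255)
    storage.mode(px) <- "integer"
  }
  px
}

#' Bicubic image resize
#'
#' Resizes a grayscale matrix or an RGB array to `height x width` using
#' separable bicubic (cubic convolution) interpolation without antialias
#' prefiltering; values are clipped to `[0, 255]` and rounded half-up.
#'
#' @param img Numeric matrix (grayscale) or `H x W x 3` array (RGB).
#' @param height,width Output dimensions; defaults 224 x 224.
#' @return Integer matrix or array of the requested size, values 0--255.
#' @export
resize_bicubic <- function(img, height = 224, width = 224) {
  resize_plane <- function(m) {
    if (nrow(m) < 4 || ncol(m) < 4)
      stop("source image too small for bicubic interpolation (need >= 4x4)")
    out <- resize_bicubic_cpp(m, height, width)
    out <- round_half_up(pmin(pmax(out, 0), 255))
    storage.mode(out) <- "integer"
    out
  }
  if (is.matrix(img)) return(resize_plane(img))
  if (is.array(img) && length(dim(img)) == 3) {
    out <- array(0L, dim = c(height, width, dim(img)[3]))
    for (c in seq_len(dim(img)[3])) out[, , c] <- resize_plane(img[, , c])
    return(out)
  }
  stop("img must be a matrix or a 3-d array")
}

#' Stack three grayscale images into an RGB image
#'
#' Concatenates three equal-shape grayscale scalogram images into the R, G
#' and B planes of one RGB image. The convention pairs electrode triads with
#' channels: R gets C3 (or P3), G gets Cz (Pz), B gets C4 (P4). Stacking is
#' lossless; each plane is recoverable as `rgb[, , k]`.
#'
#' @param img1,img2,img3 Integer matrices of identical shape (values 0--255).
#' @return Integer array `H x W x 3`.
#' @export
stack_rgb <- function(img1, img2, img3) {
  if (!identical(dim(img1), dim(img2)) || !identical(dim(img1), dim(img3)))
    stop("the three grayscale planes must have identical shape")
  out <- array(0L, dim = c(dim(img1), 3))
  out[, , 1] <- img1
  out[, , 2] <- img2
  out[, , 3] <- img3
  out
}

# write an integer 0-255 RGB array (or grayscale matrix) as PNG
write_image_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# read a PNG back to an integer 0-255 array
read_image_png <- function(path) {
  x <- png::readPNG(path)
  out <- round_half_up(x * 255)
  storage.mode(out) <- "integer"
  out
}

#' Generate the scalogram image dataset for one-vs-rest training
#'
#' For every CSP contrast and every epoch: project the epoch through the
#' contrast's spatial filter, compute one Morse scalogram per component row,
#' convert each to grayscale, resize to 224 x 224, and stack two RGB images
#' per epoch -- the motor triad (rows 1-3, identified with C3/Cz/C4) and the
#' parietal triad (rows 4-6, identified with P3/Pz/P4). Images are written
#' as PNG under `out_dir` and listed in a manifest.
#'
#' @param models A `"csp_ovr"` set (or a named list of `"csp"` fits; any
#'   subset of contrasts is accepted).
#' @param epochs An `epoch_set`.
#' @param bank A [morse_bank()] matching the epoch window length; default
#'   builds one from the epoch metadata.
#' @param out_dir Output directory (created if needed).
#' @param size Output image side length (pixels).
#' @param normalize Grayscale normalization: `"global"` (default) maps all
#'   magnitudes of the dataset against their common maximum, preserving
#'   amplitude differences between images; `"per_image"` applies the
#'   per-image min-max of [to_grayscale()]. The mode and reference are
#'   recorded in the manifest.
#' @return The manifest as a data.frame with columns `path`, `contrast`,
#'   `label` (1 = epoch belongs to the contrast's event, 0 otherwise),
#'   `triad` (`"motor"` or `"parietal"`), `window_start`, `epoch_label`,
#'   `normalize`, `norm_ref`. The manifest is also written to
#'   `out_dir/manifest.csv`.
#' @export
make_dataset <- function(models, epochs, bank = NULL, out_dir, size = 224,
                         normalize = c("global", "per_image")) {
  stopifnot(inherits(epochs, "epoch_set"))
  normalize <- match.arg(normalize)
  if (inherits(models, "csp")) models <- stats::setNames(list(models),
                                                         models$contrast[1])
  if (is.null(bank)) bank <- morse_bank(epochs$fs, epochs$window_length)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_ep <- dim(epochs$epochs)[3]
  ref <- NULL
  if (normalize == "global" && n_ep > 0) {
    # first pass: common reference magnitude over the whole dataset
    ref <- 0
    for (ev in names(models)) {
      model <- models[[ev]]
      for (i in seq_len(n_ep)) {
        Z <- csp_project(model, epochs$epochs[, , i])
        for (r in seq_len(nrow(Z)))
          ref <- max(ref, cwt_scalogram(Z[r, ], bank)$magnitudes)
      }
    }
    if (ref <= 0) ref <- 1
  }
  rows <- vector("list", length(models) * max(n_ep, 1) * 2)
  ri <- 0L
  triads <- list(motor = 1:3, parietal = 4:6)
  for (ev in names(models)) {
    model <- models[[ev]]
    ev_code <- match(ev, gal_events)
    for (i in seq_len(n_ep)) {
      Z <- csp_project(model, epochs$epochs[, , i])
      gray <- lapply(seq_len(nrow(Z)), function(r)
        resize_bicubic(to_grayscale(cwt_scalogram(Z[r, ], bank), ref = ref),
                       height = size, width = size))
      for (tn in names(triads)) {
        tr <- triads[[tn]]
        if (max(tr) > length(gray)) next
        img <- stack_rgb(gray[[tr[1]]], gray[[tr[2]]], gray[[tr[3]]])
        path <- file.path(out_dir, sprintf("%s_w%05d_%s.png", ev,
                                           epochs$starts[i], tn))
        write_image_png(img, path)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(path = path, contrast = ev,
                                 label = as.integer(!is.na(ev_code) &&
                                                      epochs$labels[i] == ev_code),
                                 triad = tn,
                                 window_start = epochs$starts[i],
                                 epoch_label = epochs$labels[i],
                                 normalize = normalize,
                                 norm_ref = if (is.null(ref)) NA_real_ else ref)
      }
    }
  }
  manifest <- if (ri) do.call(rbind, rows[seq_len(ri)]) else
    data.frame(path = character(), contrast = character(),
               label = integer(), triad = character(),
               window_start = integer(), epoch_label = integer(),
               normalize = character(), norm_ref = numeric())
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
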