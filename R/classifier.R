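#' Training configuration for the image classification stage
#'
#' Defaults follow the training protocol used throughout the pipeline:
#' stratified train/validation/test split of 0.8:0.1:0.1, at most 30 epochs,
#' mini-batch size 10. The optimizer (stochastic gradient descent, momentum
#' 0.9, learning rate 0.05) and the early-stopping patience are
#' backend-level settings of the reference CNN.
#'
#' @param max_epochs Maximum training epochs (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param split Train/validation/test proportions; must be positive and sum
#'   to 1.
#' @param seed Integer seed controlling the split, weight initialization and
#'   batch order.
#' @param backend `"reference_cnn"`, or a list with elements `train(x, y,
#'   x_val, y_val, config)` and `predict(model, x)` for an external model.
#' @param learning_rate,momentum SGD hyperparameters.
#' @param input_size Side length the reference CNN pools the 224 x 224 input
#'   down to before the first convolution; must divide 224.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(max_epochs = 30, batch_size = 10,
                         split = c(0.8, 0.1, 0.1), seed = 1,
                         backend = "reference_cnn",
                         learning_rate = 0.05, momentum = 0.9,
                         input_size = 32, patience = 5) {
  stopifnot(max_epochs >= 1, batch_size >= 1, length(split) == 3)
  if (any(split <= 0) || abs(sum(split) - 1) > 1e-9)
    stop("split proportions must be positive and sum to 1")
  if (224 %% input_size != 0)
    stop("input_size must divide 224")
  structure(list(max_epochs = max_epochs, batch_size = batch_size,
                 split = split, seed = seed, backend = backend,
                 learning_rate = learning_rate, momentum = momentum,
                 input_size = input_size, patience = patience),
            class = "train_config")
}

#' Stratified train/validation/test split of an image manifest
#'
#' Splits a manifest into disjoint train, validation and test subsets,
#' stratified by `label`, with per-class proportions within one image of the
#' requested ratios. Deterministic under a fixed seed. With `group_by`, all
#' rows sharing a value of that column (e.g. the two triad images of one
#' window, via `"window_start"`) are assigned to the same fold, so no
#' decoding unit leaks across folds; proportions then apply to groups.
#'
#' @param manifest Data frame with a `label` column (e.g. from
#'   [make_dataset()]).
#' @param config A [train_config()] (supplies `split` and `seed`), or NULL to
#'   use `split`/`seed` directly.
#' @param split,seed Used when `config` is NULL.
#' @param group_by Optional column name whose values define inseparable
#'   groups of rows.
#' @return Named list of data frames: `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, config = NULL,
                          split = c(0.8, 0.1, 0.1), seed = 1,
                          group_by = NULL) {
  if (!is.null(config)) {
    split <- config$split
    seed <- config$seed
  }
  counts <- table(manifest$label)
  if (any(counts < 10))
    stop("stratification error: class(es) with fewer than 10 images: ",
         paste(names(counts)[counts < 10], collapse = ", "))
  group <- if (is.null(group_by)) seq_len(nrow(manifest))
  else manifest[[group_by]]
  units <- !duplicated(group)
  assign_split <- function(idx) {
    n <- length(idx)
    n_val <- max(1L, round(split[2] * n))
    n_test <- max(1L, round(split[3] * n))
    idx <- sample(idx)
    list(val = idx[seq_len(n_val)],
         test = idx[n_val + seq_len(n_test)],
         train = idx[-seq_len(n_val + n_test)])
  }
  parts <- with_seed(seed, lapply(split(which(units),
                                        manifest$label[units]), assign_split))
  take <- function(which) {
    rows <- unlist(lapply(parts, `[[`, which), use.names = FALSE)
    manifest[group %in% group[rows], , drop = FALSE]
  }
  list(train = take("train"), val = take("val"), test = take("test"))
}

# Load a manifest's PNGs as a list of [0,1] tensors for the reference CNN,
# block-averaged to input_size.
load_image_tensors <- function(paths, input_size) {
  factor <- 224 %/% input_size
  lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
    out <- array(0, dim = c(input_size, input_size, dim(img)[3]))
    for (c in seq_len(dim(img)[3]))
      out[, , c] <- downsample_avg_cpp(img[, , c], factor)
    out
  })
}

# Standardize tensors by a scalar mean/SD (computed on the training set and
# stored with the model): scalograms are mostly near-black, so a fixed -0.5
# shift would leave the class signal buried in a constant background.
standardize_tensors <- function(xs, center, scale) {
  lapply(xs, function(x) (x - center) / scale)
}

#' Train the scalogram image classifier
#'
#' Trains the configured backend on a training manifest with per-epoch
#' validation, and returns the parameters that achieved the best validation
#' accuracy together with the full training history. The reference backend
#' is a small CNN (two 3x3 convolution + ReLU + max-pool stages, global
#' average pooling, softmax output) trained by mini-batch SGD with momentum.
#'
#' @param train_manifest,val_manifest Manifest data frames with `path` and
#'   `label` columns; both non-empty.
#' @param config A [train_config()].
#' @return An object of class `"trained_model"`: list with `backend`,
#'   `params`, `classes` (sorted unique labels), `history` (per-epoch
#'   train/val loss and accuracy) and `input_size`.
#' @export
train_classifier <- function(train_manifest, val_manifest,
                             config = train_config()) {
  stopifnot(inherits(config, "train_config"),
            nrow(train_manifest) > 0, nrow(val_manifest) > 0)
  classes <- sort(unique(c(train_manifest$label, val_manifest$label)))
  x_train <- load_image_tensors(train_manifest$path, config$input_size)
  x_val <- load_image_tensors(val_manifest$path, config$input_size)
  center <- mean(vapply(x_train, mean, 0))
  scale <- max(sqrt(mean(vapply(x_train, function(x) mean((x - center)^2), 0))),
               1e-6)
  x_train <- standardize_tensors(x_train, center, scale)
  x_val <- standardize_tensors(x_val, center, scale)
  y_train <- match(train_manifest$label, classes)
  y_val <- match(val_manifest$label, classes)
  fit <- with_seed(config$seed, {
    if (identical(config$backend, "reference_cnn"))
      cnn_train_backend(x_train, y_train, x_val, y_val, config)
    else
      config$backend$train(x_train, y_train, x_val, y_val, config)
  })
  structure(list(backend = if (is.character(config$backend)) config$backend
                 else "external",
                 backend_fns = if (is.list(config$backend)) config$backend,
                 params = fit$params, classes = classes,
                 history = fit$history, input_size = config$input_size,
                 center = center, scale = scale),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> backend %s, classes: %s\n", x$backend,
              paste(x$classes, collapse = ", ")))
  if (nrow(x$history))
    cat(sprintf("  %d epochs; best val accuracy %.3f\n", nrow(x$history),
                max(x$history$val_acc)))
  invisible(x)
}

#' Score images with a trained classifier
#'
#' Computes per-image class scores (softmax probabilities summing to one per
#' image). Inference is deterministic for a fixed model.
#'
#' @param model A [train_classifier()] result.
#' @param manifest Manifest data frame with a `path` column.
#' @return The manifest with one `score_<class>` column per class appended.
#' @export
predict_scores <- function(model, manifest) {
  stopifnot(inherits(model, "trained_model"))
  for (p in manifest$path)
    if (!file.exists(p)) stop("cannot read image: ", p)
  xs <- standardize_tensors(load_image_tensors(manifest$path,
                                               model$input_size),
                            model$center, model$scale)
  scores <- if (model$backend == "reference_cnn")
    cnn_predict_backend(model$params, xs)
  else model$backend_fns$predict(model$params, xs)
  scores <- scores[, seq_along(model$classes), drop = FALSE]
  scores <- scores / rowSums(scores)
  colnames(scores) <- paste0("score_", model$classes)
  cbind(manifest, as.data.frame(scores))
}
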