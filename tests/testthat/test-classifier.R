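# Build a tiny labeled PNG image set: class 1 has a bright center square.
make_toy_manifest <- function(n_per_class, dir, size = 224, sd = 0.06,
                              seed = 61) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    rows <- lapply(seq_len(2 * n_per_class), function(i) {
      label <- as.integer(i > n_per_class)
      x <- array(pmin(pmax(rnorm(size * size * 3, 0.3, sd), 0), 1),
                 c(size, size, 3))
      if (label == 1) {
        mid <- (size %/% 3):(2 * size %/% 3)
        x[mid, mid, ] <- pmin(x[mid, mid, ] + 0.4, 1)
      }
      p <- file.path(dir, sprintf("img%03d.png", i))
      png::writePNG(x, p)
      data.frame(path = p, label = label)
    })
    do.call(rbind, rows)
  })
}

test_that("stratified split partitions the manifest at the stated ratios", {
  man <- data.frame(path = sprintf("img%03d", 1:200),
                    label = rep(0:1, each = 100))
  parts <- split_dataset(man, split = c(0.8, 0.1, 0.1), seed = 9)
  for (lb in 0:1) {
    expect_identical(sum(parts$train$label == lb), 80L)
    expect_identical(sum(parts$val$label == lb), 10L)
    expect_identical(sum(parts$test$label == lb), 10L)
  }
  all_paths <- c(parts$train$path, parts$val$path, parts$test$path)
  expect_setequal(all_paths, man$path)
  expect_identical(anyDuplicated(all_paths), 0L)
  # deterministic under the same seed
  parts2 <- split_dataset(man, split = c(0.8, 0.1, 0.1), seed = 9)
  expect_identical(parts$train$path, parts2$train$path)
  expect_identical(parts$test$path, parts2$test$path)

  expect_error(split_dataset(data.frame(path = "a", label = 1)),
               "stratification")
})

test_that("grouped split keeps all views of a window in one fold", {
  man <- data.frame(path = sprintf("img%03d", 1:200),
                    label = rep(rep(0:1, each = 50), 2),
                    window_start = rep(1:100, 2))
  parts <- split_dataset(man, split = c(0.8, 0.1, 0.1), seed = 4,
                         group_by = "window_start")
  folds <- rep(c("train", "val", "test"),
               c(nrow(parts$train), nrow(parts$val), nrow(parts$test)))
  win_fold <- split(folds, c(parts$train$window_start, parts$val$window_start,
                             parts$test$window_start))
  expect_true(all(vapply(win_fold, function(f) length(unique(f)) == 1, TRUE)))
  # both views of every window present, partition preserved
  expect_setequal(c(parts$train$path, parts$val$path, parts$test$path),
                  man$path)
  expect_identical(sum(parts$val$label == 1), 10L)   # 5 windows x 2 views
  expect_identical(sum(parts$test$label == 0), 10L)
})

test_that("reference CNN learns a separable image set and stays at chance on shuffled labels", {
  man <- make_toy_manifest(40, tempfile("toy"))
  cfg <- train_config(max_epochs = 10, seed = 5, patience = 10)
  parts <- split_dataset(man, cfg)
  model <- train_classifier(parts$train, parts$val, cfg)
  expect_gte(max(model$history$val_acc), 0.9)
  expect_lte(nrow(model$history), 30)

  # shuffled labels carry no signal: validation accuracy near chance
  sh_train <- parts$train
  sh_train$label <- with_seed(7, sample(sh_train$label))
  sh_val <- parts$val
  sh_val$label <- with_seed(8, sample(sh_val$label))
  cfg_sh <- train_config(max_epochs = 5, seed = 5, patience = 2)
  model_sh <- train_classifier(sh_train, sh_val, cfg_sh)
  expect_lt(abs(tail(model_sh$history$val_acc, 1) - 0.5), 0.35)

  # scoring: deterministic, normalized, argmax consistent with labels
  sc1 <- predict_scores(model, parts$test)
  sc2 <- predict_scores(model, parts$test)
  expect_identical(sc1$score_1, sc2$score_1)
  expect_equal(sc1$score_0 + sc1$score_1, rep(1, nrow(sc1)),
               tolerance = 1e-12)
  acc <- mean((sc1$score_1 >= 0.5) == (sc1$label == 1))
  expect_gte(acc, 0.8)
  expect_error(predict_scores(model, data.frame(path = "nope.png")),
               "nope.png")
})

test_that("forward pass is finite on an all-zero image", {
  params <- with_seed(3, cspcwt:::cnn_init(32, 3, 2))
  z <- array(0, c(32, 32, 3))
  pr <- cspcwt:::cnn_forward(params, z)$probs
  expect_true(all(is.finite(pr)))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("train config validates its protocol parameters", {
  cfg <- train_config()
  expect_identical(cfg$max_epochs, 30)
  expect_identical(cfg$batch_size, 10)
  expect_equal(cfg$split, c(0.8, 0.1, 0.1))
  expect_error(train_config(split = c(0.8, 0.2, 0.1)), "sum to 1")
  expect_error(train_config(max_epochs = 0), "max_epochs")
  expect_error(train_config(input_size = 30), "divide")
})
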