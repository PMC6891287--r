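# Reference CNN backend: a deliberately small, self-contained convolutional
# network trainable on one CPU in minutes. Architecture:
#   avgpool(p) -> conv(3x3, 16) + ReLU + maxpool(2)
#              -> conv(3x3, 32) + ReLU + maxpool(2)
#              -> global average pool -> dense(n_classes) + softmax
# The fixed initial average-pooling layer reduces the 224x224x3 input to
# input_size x input_size x 3 before the first convolution; the on-disk data
# contract (224x224x3 RGB scalograms) is unchanged.

cnn_init <- function(input_size = 32, in_channels = 3, n_classes = 2) {
  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)),
                                     dim = dims)
  list(w1 = he(c(3, 3, in_channels, 16), 9 * in_channels),
       b1 = numeric(16),
       w2 = he(c(3, 3, 16, 32), 9 * 16),
       b2 = numeric(32),
       wd = matrix(rnorm(32 * n_classes, 0, sqrt(1 / 32)), 32, n_classes),
       bd = numeric(n_classes))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# forward pass; returns class probabilities and, if keep = TRUE, the
# intermediate activations needed by the backward pass
cnn_forward <- function(p, x, keep = FALSE) {
  c1 <- conv2d_fwd_cpp(x, p$w1, p$b1, dim(x), dim(p$w1))
  r1 <- pmax(c1, 0); dim(r1) <- dim(c1)
  m1 <- maxpool2_fwd_cpp(r1, dim(r1))
  c2 <- conv2d_fwd_cpp(m1$out, p$w2, p$b2, dim(m1$out), dim(p$w2))
  r2 <- pmax(c2, 0); dim(r2) <- dim(c2)
  m2 <- maxpool2_fwd_cpp(r2, dim(r2))
  g <- apply(m2$out, 3, mean)
  logits <- drop(crossprod(p$wd, g)) + p$bd
  probs <- softmax(logits)
  if (!keep) return(list(probs = probs))
  list(probs = probs, x = x, c1 = c1, r1 = r1, m1 = m1, c2 = c2, r2 = r2,
       m2 = m2, g = g)
}

# gradient of the cross-entropy loss for one sample (y is a class index)
cnn_backward <- function(p, cache, y) {
  dlogit <- cache$probs
  dlogit[y] <- dlogit[y] - 1
  dwd <- cache$g %o% dlogit
  dbd <- dlogit
  dg <- drop(p$wd %*% dlogit)
  dm2 <- dim(cache$m2$out)
  dpool2 <- array(rep(dg / (dm2[1] * dm2[2]), each = dm2[1] * dm2[2]),
                  dim = dm2)
  dr2 <- maxpool2_bwd_cpp(cache$m2$argmax, dpool2, dim(cache$r2))
  dc2 <- dr2 * (cache$c2 > 0); dim(dc2) <- dim(dr2)
  g2 <- conv2d_bwd_cpp(cache$m1$out, p$w2, dc2, dim(cache$m1$out), dim(p$w2))
  dr1 <- maxpool2_bwd_cpp(cache$m1$argmax, g2$dx, dim(cache$r1))
  dc1 <- dr1 * (cache$c1 > 0); dim(dc1) <- dim(dr1)
  g1 <- conv2d_bwd_cpp(cache$x, p$w1, dc1, dim(cache$x), dim(p$w1))
  list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db, wd = dwd, bd = dbd)
}

# SGD with momentum over a list of (images, class-index) pairs
cnn_train_backend <- function(x_train, y_train, x_val, y_val, config) {
  n_classes <- length(unique(c(y_train, y_val)))
  params <- cnn_init(input_size = dim(x_train[[1]])[1],
                     in_channels = dim(x_train[[1]])[3],
                     n_classes = max(2L, n_classes))
  vel <- lapply(params, function(w) w * 0)
  best <- list(acc = -Inf, params = params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  lr <- config$learning_rate
  mom <- config$momentum
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(x_train))
    tl <- 0; tc <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      grad <- NULL
      for (i in b) {
        fw <- cnn_forward(params, x_train[[i]], keep = TRUE)
        pr <- fw$probs[y_train[i]]
        tl <- tl - log(max(pr, 1e-12))
        tc <- tc + (which.max(fw$probs) == y_train[i])
        g <- cnn_backward(params, fw, y_train[i])
        grad <- if (is.null(grad)) g else Map(`+`, grad, g)
      }
      if (!all(vapply(grad, function(g) all(is.finite(g)), TRUE)))
        stop("training diverged (non-finite gradient) at epoch ", epoch)
      for (nm in names(params)) {
        vel[[nm]] <- mom * vel[[nm]] - lr * grad[[nm]] / length(b)
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    if (!is.finite(tl)) stop("training diverged (NaN loss) at epoch ", epoch)
    ev <- cnn_evaluate(params, x_val, y_val)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = tl / length(x_train),
                                   train_acc = tc / length(x_train),
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (ev$acc > best$acc) {
      best <- list(acc = ev$acc, params = params)
      stall <- 0L
    } else stall <- stall + 1L
    if (ev$acc >= 1 || stall >= config$patience) break
  }
  list(params = best$params, history = hist)
}

cnn_evaluate <- function(params, xs, ys) {
  loss <- 0; correct <- 0L
  for (i in seq_along(xs)) {
    pr <- cnn_forward(params, xs[[i]])$probs
    loss <- loss - log(max(pr[ys[i]], 1e-12))
    correct <- correct + (which.max(pr) == ys[i])
  }
  list(loss = loss / length(xs), acc = correct / length(xs))
}

cnn_predict_backend <- function(params, xs) {
  t(vapply(xs, function(x) cnn_forward(params, x)$probs,
           numeric(ncol(params$wd))))
}
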