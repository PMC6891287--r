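test_that("spatial covariance is the trace-normalized outer product", {
  expect_equal(spatial_covariance(diag(2)), diag(2) / 2)
  # XX' = [[2,2],[2,2]], trace 4
  expect_equal(spatial_covariance(matrix(1, 2, 2)),
               matrix(0.5, 2, 2))
  set.seed(2)
  for (n in c(2, 4, 6)) {
    R <- spatial_covariance(matrix(rnorm(n * 50), n))
    expect_equal(sum(diag(R)), 1, tolerance = 1e-12)
    expect_equal(R, t(R), tolerance = 1e-12)
  }
  expect_error(spatial_covariance(matrix(0, 2, 5)), "degenerate")
  expect_error(spatial_covariance(matrix(1, 5, 2)), "samples")
})

test_that("covariance averaging is the element-wise mean", {
  A <- diag(2) / 2
  B <- matrix(0.25, 2, 2)
  expect_equal(average_covariance(list(A)), A)
  expect_equal(average_covariance(list(B, B)), B)
  expect_equal(average_covariance(list(A, B)),
               matrix(c(0.375, 0.125, 0.125, 0.375), 2))
  expect_error(average_covariance(list()), "empty")
})

test_that("whitening maps the composite covariance to the identity", {
  wt <- whitening_transform(diag(c(4, 1)))
  expect_equal(wt$Delta, c(4, 1))
  expect_equal(abs(wt$Pw), diag(c(0.5, 1)), tolerance = 1e-12)

  expect_equal(whitening_transform(diag(3))$Pw %*% diag(3) %*%
                 t(whitening_transform(diag(3))$Pw), diag(3))

  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    Rc <- random_spd(n)
    wt <- whitening_transform(Rc)
    expect_lt(max(abs(wt$Pw %*% Rc %*% t(wt$Pw) - diag(n))), 1e-8)
    expect_true(all(diff(wt$Delta) <= 1e-12))  # descending
  }
  expect_error(whitening_transform(matrix(c(1, 0, 0, 0), 2)), "rank")
})

test_that("csp_fit recovers constructed diagonal spectra", {
  set.seed(4)
  mkep <- function(v, n = 60) lapply(seq_len(n), function(i)
    diag(sqrt(v)) %*% matrix(rnorm(2 * 400), 2))
  m <- csp_fit(mkep(c(0.8, 0.2)), mkep(c(0.2, 0.8)))
  expect_equal(m$Delta1, c(0.8, 0.2), tolerance = 0.03)
  # W is the identity up to row sign/permutation
  P <- abs(m$W)
  expect_equal(P[P > 0.5], c(1, 1), tolerance = 0.05)
  expect_lt(max(P[P <= 0.5]), 0.1)

  # identical classes are inseparable
  same <- mkep(c(1, 1))
  m2 <- csp_fit(same, same)
  expect_equal(m2$Delta1, c(0.5, 0.5), tolerance = 1e-10)

  # variance ratio of projected class-1 epochs matches the spectra
  Z <- predict(m, mkep(c(0.8, 0.2), 200))
  vr <- mean(vapply(Z, function(z) var(z[1, ]) / var(z[2, ]), 0))
  expect_equal(vr, 4, tolerance = 0.8)
})

test_that("csp spectra match a brute-force generalized eigensolver", {
  set.seed(6)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    R1 <- random_spd(n)
    R2 <- random_spd(n)
    m <- csp_fit(epochs_with_cov(R1), epochs_with_cov(R2))
    # oracle: eigenvalues of (R1+R2)^-1 R1, i.e. R1 v = lambda (R1+R2) v
    oracle <- sort(Re(eigen(solve(R1 + R2) %*% R1)$values),
                   decreasing = TRUE)
    expect_equal(m$Delta1, oracle, tolerance = 1e-8)
    expect_equal(m$Delta1 + m$Delta2, rep(1, n), tolerance = 1e-8)
    expect_lt(max(abs(m$W %*% m$W_inv - diag(n))), 1e-8)
    expect_lt(max(abs(m$Pw %*% (R1 + R2) %*% t(m$Pw) - diag(n))), 1e-8)
  }
})

test_that("top CSP filter is the Rayleigh-quotient extremum", {
  set.seed(8)
  n <- 5
  R1 <- random_spd(n)
  R2 <- random_spd(n)
  m <- csp_fit(epochs_with_cov(R1), epochs_with_cov(R2))
  rq <- function(w) drop(w %*% R1 %*% w / (w %*% (R1 + R2) %*% w))
  hi <- rq(m$W[1, ])
  lo <- rq(m$W[n, ])
  rand <- matrix(rnorm(1e4 * n), ncol = n)
  vals <- apply(rand, 1, rq)
  expect_true(all(vals <= hi + 1e-10))
  expect_true(all(vals >= lo - 1e-10))
})

test_that("fit is invariant to a global amplitude scale", {
  set.seed(9)
  e1 <- lapply(1:10, function(i) matrix(rnorm(4 * 100), 4))
  e2 <- lapply(1:10, function(i) matrix(rnorm(4 * 100), 4))
  m <- csp_fit(e1, e2)
  ms <- csp_fit(lapply(e1, `*`, 17.3), lapply(e2, `*`, 17.3))
  expect_equal(ms$Delta1, m$Delta1, tolerance = 1e-10)
  expect_equal(ms$W, m$W, tolerance = 1e-8)
})

test_that("projection and reconstruction are mutual inverses", {
  set.seed(10)
  e1 <- lapply(1:8, function(i) matrix(rnorm(6 * 80), 6))
  e2 <- lapply(1:8, function(i) matrix(rnorm(6 * 80), 6))
  m <- csp_fit(e1, e2)
  X <- matrix(rnorm(6 * 80), 6)
  Z <- csp_project(m, X)
  expect_lt(max(abs(csp_reconstruct(m, Z) - X)), 1e-8)
  expect_equal(csp_reconstruct(m, matrix(0, 6, 10)), matrix(0, 6, 10))
  expect_equal(coef(m), m$W)
  # identity filter passes data through
  mI <- m
  mI$W <- diag(6)
  expect_equal(csp_project(mI, X), X)
  expect_error(csp_project(m, matrix(0, 5, 10)), "channels")
})

test_that("one-vs-rest produces six valid models over balanced rest pools", {
  es <- fx_epochs6(n_per_class = 10)
  ovr <- one_vs_rest_fit(es, seed = 42)
  expect_identical(names(ovr), c("HS", "GS", "LT", "HD", "RP", "RL"))
  expect_length(ovr, 6)
  for (k in 1:6) {
    m <- ovr[[k]]
    expect_equal(m$Delta1 + m$Delta2, rep(1, 6), tolerance = 1e-8)
    expect_lt(max(abs(m$W %*% m$W_inv - diag(6))), 1e-8)
    expect_true(all(diff(m$Delta1) <= 1e-12))
    # rest pool draws from exactly the five other classes, balanced
    contrib <- m$rest_classes[m$rest_classes > 0]
    expect_identical(names(contrib), setdiff(gal_events, gal_events[k]))
    expect_true(max(contrib) - min(contrib) <= 1)
  }
  # reproducible under the same seed
  ovr2 <- one_vs_rest_fit(es, seed = 42)
  expect_equal(ovr[["HS"]]$W, ovr2[["HS"]]$W)

  es_missing <- es
  es_missing$labels[es_missing$labels == 3] <- 2L
  expect_error(one_vs_rest_fit(es_missing, seed = 1), "LT")
})

test_that("singular energy profile concentrates in the leading vectors", {
  expect_equal(singular_energy_profile(outer(1:4, 1:5)), rep(1, 4))
  expect_equal(singular_energy_profile(diag(3)), c(1, 2, 3) / 3)
  # six-channel CSP output: all energy inside the first six singular vectors
  strong <- fx_strong()
  Z <- do.call(cbind, predict(strong$models$HS, strong$epochs))
  prof <- singular_energy_profile(Z)
  expect_gte(prof[6], 0.99)
  expect_true(all(diff(prof) >= -1e-12))
  expect_error(singular_energy_profile(matrix(0, 3, 3)), "degenerate")
})

test_that("CSP projection compresses the event-class scatter", {
  set.seed(12)
  # event class near-spherical, rest class anisotropic under distinct
  # mixing: whitening by the composite imprints the discriminative
  # anisotropy on the projected event scatter
  A1 <- qr.Q(qr(matrix(rnorm(9), 3)))
  A2 <- qr.Q(qr(matrix(rnorm(9), 3)))
  mk <- function(A, v) lapply(1:50, function(i)
    A %*% (sqrt(v) * matrix(rnorm(3 * 200), 3)))
  e1 <- mk(A1, c(1, 1, 1))
  e2 <- mk(A2, c(4, 0.5, 0.5))
  m <- csp_fit(e1, e2)
  X <- do.call(cbind, e1)
  Zp <- do.call(cbind, predict(m, e1))
  norm_cov <- function(M) {
    C <- tcrossprod(M) / ncol(M)
    C / sum(diag(C))  # equal total variance
  }
  expect_lt(det(norm_cov(Zp)), det(norm_cov(X)))
})

test_that("top filter recovers the planted discriminative direction", {
  strong <- fx_strong()
  for (ev in c("HS", "HD", "RL")) {
    w <- strong$models[[ev]]$W[1, ]
    d <- planted_direction(strong$scenario, ev)
    cosine <- abs(sum(w * d)) / sqrt(sum(w^2))
    expect_gte(cosine, 0.95)
  }
})
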