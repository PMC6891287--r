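#' Trace-normalized spatial covariance of one epoch
#'
#' For an `N x T` epoch `X`, returns `R = X X' / trace(X X')`, the
#' scale-invariant spatial covariance with unit trace that CSP operates on.
#'
#' @param X Numeric matrix, channels x samples, `T >= N`.
#' @return Symmetric positive semi-definite `N x N` matrix with trace 1.
#' @export
spatial_covariance <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < nrow(X))
    stop("epoch must have at least as many samples as channels")
  C <- tcrossprod(X)
  tr <- sum(diag(C))
  if (tr <= 0) stop("degenerate epoch: zero energy")
  C / tr
}

#' Average a list of spatial covariances
#'
#' Element-wise mean of trace-normalized covariances; the result again has
#' unit trace.
#'
#' @param covs Non-empty list of equal-dimension covariance matrices.
#' @return The mean covariance matrix.
#' @export
average_covariance <- function(covs) {
  if (!length(covs)) stop("empty covariance list")
  dims <- vapply(covs, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[, 1])) stop("covariance dimensions differ")
  Reduce(`+`, lapply(covs, as.matrix)) / length(covs)
}

#' Whitening transform of a composite covariance
#'
#' Eigendecomposes `Rc = U diag(Delta) U'` with eigenvalues in descending
#' order and returns the whitening matrix `Pw = diag(Delta^-1/2) U'`, which
#' maps the composite covariance to the identity: `Pw Rc Pw' = I`.
#'
#' @param Rc Symmetric positive-definite matrix (typically the sum of two
#'   class-average covariances).
#' @param eig_floor_factor Relative eigenvalue floor; an eigenvalue below
#'   `eig_floor_factor * max(eigenvalue)` signals rank deficiency.
#' @return List with `U` (eigenvectors), `Delta` (descending eigenvalues) and
#'   `Pw` (whitening matrix).
#' @export
whitening_transform <- function(Rc, eig_floor_factor = 1e-10) {
  Rc <- as.matrix(Rc)
  if (max(abs(Rc - t(Rc))) > 1e-8 * max(abs(Rc)))
    stop("composite covariance is not symmetric")
  e <- eigen((Rc + t(Rc)) / 2, symmetric = TRUE)  # descending by default
  if (any(e$values < eig_floor_factor * e$values[1]))
    stop("rank-deficient composite covariance (eigenvalue below floor); ",
         "consider shrinkage regularization")
  Pw <- diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  list(U = e$vectors, Delta = e$values, Pw = Pw)
}

# Normalize epochs argument to a list of N x T matrices.
as_epoch_list <- function(epochs) {
  if (is.list(epochs)) return(lapply(epochs, as.matrix))
  if (is.array(epochs) && length(dim(epochs)) == 3)
    return(lapply(seq_len(dim(epochs)[3]), function(i) epochs[, , i]))
  if (is.matrix(epochs)) return(list(epochs))
  stop("epochs must be a list of matrices or a 3-d array")
}

# Shrinkage toward the scaled identity: (1-lambda) R + lambda tr(R)/N I.
shrink_cov <- function(R, lambda) {
  if (lambda == 0) return(R)
  (1 - lambda) * R + lambda * (sum(diag(R)) / nrow(R)) * diag(nrow(R))
}

#' Fit a common spatial pattern (CSP) filter
#'
#' Fits the two-class CSP decomposition. Per-epoch trace-normalized spatial
#' covariances are averaged within each class (`R1`, `R2`); the composite
#' `Rc = R1 + R2` is whitened (`Pw`), and the whitened class covariances
#' `Q1 = Pw R1 Pw'` and `Q2 = Pw R2 Pw'` -- which share common eigenvectors
#' `V` with eigenvalue pairs summing to one -- are jointly diagonalized. The
#' spatial filter is `W = V' Pw`, rows ordered by descending class-1
#' eigenvalue, so the first row maximizes class-1 variance relative to the
#' composite and the last row minimizes it. Columns of `W^-1` are the spatial
#' patterns (scalp-space signatures) of the components.
#'
#' Eigenvector signs are fixed by making the largest-magnitude component of
#' each column of `V` positive, and eigenvalue ties are broken by original
#' index, so the fit is deterministic.
#'
#' @param epochs_event,epochs_rest Epochs of the two classes: lists of
#'   channels-x-samples matrices or 3-d arrays (channels x samples x epochs).
#' @param contrast Length-2 character labels for the two classes.
#' @param shrinkage Shrinkage weight `lambda` in `[0, 1]` pulling each class
#'   covariance toward the scaled identity before whitening; default 0 (off).
#' @param eig_floor_factor Passed to [whitening_transform()].
#' @return An object of class `"csp"` with components `W`, `W_inv`, `V`,
#'   `Pw`, `U`, `Delta` (composite eigenvalues), `Delta1`, `Delta2` (paired
#'   class eigenvalues, `Delta1` descending, `Delta1 + Delta2 = 1`),
#'   `contrast`, `n_event`, `n_rest`.
#' @seealso [predict.csp()], [csp_project()], [csp_reconstruct()],
#'   [one_vs_rest_fit()]
#' @export
csp_fit <- function(epochs_event, epochs_rest,
                    contrast = c("event", "rest"), shrinkage = 0,
                    eig_floor_factor = 1e-10) {
  e1 <- as_epoch_list(epochs_event)
  e2 <- as_epoch_list(epochs_rest)
  if (!length(e1) || !length(e2)) stop("need at least one epoch per class")
  n <- nrow(e1[[1]])
  if (any(vapply(c(e1, e2), nrow, 0L) != n))
    stop("all epochs must have the same number of channels")
  R1 <- shrink_cov(average_covariance(lapply(e1, spatial_covariance)), shrinkage)
  R2 <- shrink_cov(average_covariance(lapply(e2, spatial_covariance)), shrinkage)
  wt <- whitening_transform(R1 + R2, eig_floor_factor)
  Q1 <- wt$Pw %*% R1 %*% t(wt$Pw)
  Q1 <- (Q1 + t(Q1)) / 2
  eg <- eigen(Q1, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)  # stable: ties keep orig index
  V <- eg$vectors[, ord, drop = FALSE]
  Delta1 <- eg$values[ord]
  # sign convention: largest-magnitude entry of each common eigenvector > 0
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  Q2 <- wt$Pw %*% R2 %*% t(wt$Pw)
  Delta2 <- diag(t(V) %*% ((Q2 + t(Q2)) / 2) %*% V)
  W <- t(V) %*% wt$Pw
  structure(list(W = W, W_inv = solve(W), V = V, Pw = wt$Pw,
                 U = wt$U, Delta = wt$Delta,
                 Delta1 = Delta1, Delta2 = Delta2,
                 contrast = contrast, n_event = length(e1),
                 n_rest = length(e2), channel_names = rownames(e1[[1]])),
            class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("<csp> %s vs %s: %d components (%d/%d epochs)\n",
              x$contrast[1], x$contrast[2], nrow(x$W), x$n_event, x$n_rest))
  cat("  Delta1:", paste(sprintf("%.3f", x$Delta1), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.csp <- function(object, ...) {
  out <- list(contrast = object$contrast,
              n_components = nrow(object$W),
              n_event = object$n_event, n_rest = object$n_rest,
              spectra = data.frame(component = seq_along(object$Delta1),
                                   Delta1 = object$Delta1,
                                   Delta2 = object$Delta2),
              discriminability = max(object$Delta1))
  class(out) <- "summary.csp"
  out
}

#' @export
print.summary.csp <- function(x, ...) {
  cat(sprintf("CSP fit: %s vs %s (%d + %d epochs)\n",
              x$contrast[1], x$contrast[2], x$n_event, x$n_rest))
  cat("Paired eigenvalue spectra (Delta1 + Delta2 = 1):\n")
  print(x$spectra, row.names = FALSE, digits = 4)
  cat(sprintf("Top-component discriminability (max Delta1): %.4f\n",
              x$discriminability))
  invisible(x)
}

#' @export
#' @describeIn csp_fit The spatial filter matrix `W` (rows are filters).
coef.csp <- function(object, ...) object$W

#' Project epochs through a CSP filter
#'
#' Computes the uncorrelated component signals `Z = W X` for one epoch or for
#' every epoch of an [extract_epochs()] set.
#'
#' @param object A fitted `"csp"` model.
#' @param newdata A channels-x-samples matrix, a list of such matrices, or an
#'   `epoch_set`.
#' @param ... Unused.
#' @return A matrix for matrix input, otherwise a list of projected matrices.
#' @export
predict.csp <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(csp_project(object, newdata))
  if (inherits(newdata, "epoch_set")) newdata <- newdata$epochs
  lapply(as_epoch_list(newdata), function(X) csp_project(object, X))
}

#' @rdname predict.csp
#' @param model A fitted `"csp"` model.
#' @param X Channels-x-samples epoch matrix.
#' @export
csp_project <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) != ncol(model$W))
    stop("epoch has ", nrow(X), " channels but the model expects ",
         ncol(model$W))
  model$W %*% X
}

#' Reconstruct an epoch from its CSP components
#'
#' Inverse of [csp_project()]: `X = W^-1 Z`.
#'
#' @param model A fitted `"csp"` model.
#' @param Z Component matrix with as many rows as CSP components.
#' @return The reconstructed channels-x-samples matrix.
#' @export
csp_reconstruct <- function(model, Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(model$W_inv))
    stop("component matrix has ", nrow(Z), " rows but the model expects ",
         nrow(model$W_inv))
  model$W_inv %*% Z
}

#' @export
plot.csp <- function(x, ...) {
  m <- rbind(Delta1 = x$Delta1, Delta2 = x$Delta2)
  graphics::barplot(m, beside = TRUE, names.arg = seq_along(x$Delta1),
                    xlab = "CSP component", ylab = "eigenvalue",
                    legend.text = c(x$contrast[1], x$contrast[2]),
                    main = sprintf("Paired CSP spectra: %s vs %s",
                                   x$contrast[1], x$contrast[2]), ...)
  invisible(x)
}

#' Fit one-vs-rest CSP filters for all six events
#'
#' For each grasp-and-lift event, fits a two-class CSP of that event's epochs
#' against a pooled "rest" class drawn from the other five events. Because
#' the five non-target events admit 120 distinct orderings and full pooling
#' would let the rest covariance dominate, the rest pool is a balanced random
#' subsample: an equal number of epochs from each of the five other classes,
#' totalling approximately the event-class epoch count (seeded, hence
#' reproducible).
#'
#' @param epochs An `epoch_set` whose labels cover all six events.
#' @param rest_per_class Epochs drawn per non-target class; default
#'   `ceiling(n_event / 5)`.
#' @param seed Integer seed for the rest-pool subsample (NULL = current RNG).
#' @param shrinkage Passed to [csp_fit()].
#' @return An object of class `"csp_ovr"`: a named list of six `"csp"` fits
#'   keyed HS, GS, LT, HD, RP, RL.
#' @export
one_vs_rest_fit <- function(epochs, rest_per_class = NULL, seed = NULL,
                            shrinkage = 0) {
  stopifnot(inherits(epochs, "epoch_set"))
  present <- sort(unique(epochs$labels[epochs$labels > 0]))
  if (!identical(present, 1:6))
    stop("coverage error: missing event class(es): ",
         paste(gal_events[setdiff(1:6, present)], collapse = ", "))
  models <- with_seed(seed, {
    lapply(1:6, function(k) {
      idx_event <- which(epochs$labels == k)
      per <- if (is.null(rest_per_class))
        max(1L, ceiling(length(idx_event) / 5)) else rest_per_class
      idx_rest <- unlist(lapply(setdiff(1:6, k), function(j) {
        pool <- which(epochs$labels == j)
        if (length(pool) <= per) pool else sample(pool, per)
      }))
      m <- csp_fit(epochs$epochs[, , idx_event, drop = FALSE],
                   epochs$epochs[, , idx_rest, drop = FALSE],
                   contrast = c(gal_events[k], "rest"), shrinkage = shrinkage)
      m$rest_classes <- table(factor(gal_events[epochs$labels[idx_rest]],
                                     levels = gal_events))
      m
    })
  })
  names(models) <- gal_events
  structure(models, class = "csp_ovr")
}

#' @export
print.csp_ovr <- function(x, ...) {
  cat("<csp_ovr> one-vs-rest CSP filters for 6 events\n")
  for (m in x)
    cat(sprintf("  %s: max Delta1 = %.3f (%d event / %d rest epochs)\n",
                m$contrast[1], max(m$Delta1), m$n_event, m$n_rest))
  invisible(x)
}

#' Cumulative singular-energy profile
#'
#' For a concatenated CSP component matrix `Z`, entry `k` of the profile is
#' the fraction of total squared singular-value energy captured by the first
#' `k` singular vectors. For six-channel CSP output the profile reaches 1 by
#' index 6: the six common eigenvectors span the principal subspace carrying
#' the oriented energy of the ensemble.
#'
#' @param Z Numeric matrix (components x concatenated samples).
#' @return Nondecreasing numeric vector ending at 1, length `min(dim(Z))`.
#' @export
singular_energy_profile <- function(Z) {
  Z <- as.matrix(Z)
  s2 <- svd(Z, nu = 0, nv = 0)$d^2
  tot <- sum(s2)
  if (tot <= 0) stop("degenerate input: zero matrix")
  cumsum(s2) / tot
}
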