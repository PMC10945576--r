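#' Fit a two-class linear discriminant with analytic shrinkage
#'
#' Linear discriminant analysis under the shared-covariance assumption: the
#' discriminant direction is `w = S^-1 (mu2 - mu1)` with the pooled
#' within-class covariance `S` shrunk towards the scaled identity
#' `mean(diag(S)) * I` using a Ledoit-Wolf-style analytic intensity. The
#' decision threshold is placed at the midpoint of the projected class
#' means (balanced classes).
#'
#' @param x `n x p` numeric feature matrix (trials by channels).
#' @param y Class labels with exactly two levels present.
#' @param shrinkage Either `"analytic"` (default) or a fixed value in
#'   `[0, 1]`; 0 is plain LDA, 1 is a diagonal (identity-scaled)
#'   covariance.
#' @return Object of class `lda_model` with elements `w` (direction),
#'   `threshold`, `classes`, `shrinkage` (the intensity used).
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 3), 50))
#' y <- rep(1:2, each = 50)
#' m <- fit_lda(x, y)
#' mean(predict(m, x) == y)
fit_lda <- function(x, y, shrinkage = "analytic") {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    stop("fit_lda() requires exactly 2 classes present; got ",
         length(classes), call. = FALSE)
  }
  n1 <- sum(y == classes[1])
  n2 <- sum(y == classes[2])
  if (n1 < 2 || n2 < 2) {
    stop("each class needs at least 2 trials to estimate the covariance",
         call. = FALSE)
  }
  p <- ncol(x)
  mu1 <- colMeans(x[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(x[y == classes[2], , drop = FALSE])
  xc <- x
  xc[y == classes[1], ] <- sweep(x[y == classes[1], , drop = FALSE], 2, mu1)
  xc[y == classes[2], ] <- sweep(x[y == classes[2], , drop = FALSE], 2, mu2)
  n <- nrow(x)
  S <- crossprod(xc) / n
  mbar <- mean(diag(S))
  if (identical(shrinkage, "analytic")) {
    # Ledoit-Wolf intensity for the target mbar * I, vectorised:
    # d2 = ||S - mbar I||_F^2; b2 = (1/n^2) sum_i ||x_i x_i' - S||_F^2
    d2 <- sum((S - diag(mbar, p))^2)
    q <- rowSums(xc^2)
    sum_norm4 <- sum(q^2)
    cross <- sum((xc %*% S) * xc)
    b2 <- (sum_norm4 - 2 * cross + n * sum(S^2)) / n^2
    gam <- if (d2 > 0) min(1, max(0, b2 / d2)) else 1
  } else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    gam <- shrinkage
  }
  Sreg <- (1 - gam) * S + diag(gam * mbar, p)
  w <- tryCatch(solve(Sreg, mu2 - mu1), error = function(e) {
    # singular even after shrinkage (e.g. constant features): ridge fallback
    solve(Sreg + diag(1e-8 * max(mbar, 1), p), mu2 - mu1)
  })
  structure(list(w = as.numeric(w),
                 threshold = sum(w * (mu1 + mu2)) / 2,
                 classes = classes, shrinkage = gam),
            class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  scores <- as.matrix(newdata) %*% object$w
  object$classes[1 + as.integer(scores > object$threshold)]
}

.stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- sample(which(labels == k))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Compute a temporal generalisation matrix (TGM)
#'
#' For every training time point, a shrinkage-LDA decoder is fit on the
#' training trials' channel values at that sample (standardised with
#' training-set statistics only) and tested at every time point of the
#' held-out trials; accuracies are averaged over stratified
#' cross-validation folds. Entry `(t, t')` is the proportion of held-out
#' trials classified correctly by the decoder trained at `t` and tested at
#' `t'`; the diagonal is the usual time-resolved cross-validated accuracy.
#'
#' @param data An `epoched_data` object ([sample_dataset()] or
#'   [read_epoched()]).
#' @param n_folds Number of stratified cross-validation folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param shrinkage Passed to [fit_lda()].
#' @param .resubstitute Internal validation switch: if `TRUE`, decoders are
#'   trained on *all* trials (including the ones they are then tested on),
#'   deliberately leaking train/test information. Only useful to demonstrate
#'   that the honest cross-validated path is leak-free; never use for
#'   analysis.
#' @return Object of class `tgm`: list with `accuracy` (`T x T` matrix,
#'   training time in rows, testing time in columns), `times` (seconds),
#'   `n_folds`, `n_trials`, `fs`.
#' @export
compute_tgm <- function(data, n_folds = 10, seed = 1L, shrinkage = "analytic",
                        .resubstitute = FALSE) {
  stopifnot(inherits(data, "epoched_data"), n_folds >= 2)
  d <- dim(data$data)
  N <- d[1]; Tt <- d[2]; C <- d[3]
  labels <- data$labels
  if (length(unique(labels)) != 2) {
    stop("TGM decoding is defined for 2 conditions; got ",
         length(unique(labels)), call. = FALSE)
  }
  set.seed(seed)
  folds <- .stratified_folds(labels, n_folds)
  correct <- matrix(0, Tt, Tt)
  total <- matrix(0, Tt, Tt)
  flat <- matrix(data$data, N, Tt * C)  # trials x (time,channel)
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- if (.resubstitute) seq_len(N) else which(folds != f)
    if (length(unique(labels[test_idx])) < 2 ||
        length(unique(labels[train_idx])) < 2) {
      stop("fold ", f, " does not contain both classes; reduce n_folds",
           call. = FALSE)
    }
    x_test <- flat[test_idx, , drop = FALSE]
    y_test <- labels[test_idx]
    n_test <- length(test_idx)
    # columns of `flat` are (time, channel) pairs in time-major order, so
    # the same memory reshapes to a (trial, time) x channel matrix
    test_tc <- matrix(x_test, n_test * Tt, C)
    hit_template <- rep(y_test, Tt)
    for (t in seq_len(Tt)) {
      cols <- t + Tt * (0:(C - 1))
      xtr <- flat[train_idx, cols, drop = FALSE]
      m <- colMeans(xtr)
      xtr <- sweep(xtr, 2, m)
      s <- sqrt(colSums(xtr^2) / (nrow(xtr) - 1))
      s[!is.finite(s) | s < 1e-12] <- 1
      xtr <- sweep(xtr, 2, s, "/")
      model <- fit_lda(xtr, labels[train_idx], shrinkage = shrinkage)
      # fold the training-time standardisation into the raw-space weights
      w_raw <- model$w / s
      thr_raw <- model$threshold + sum(model$w * m / s)
      # project every test trial at every test time point at once
      sc <- test_tc %*% w_raw
      pred <- model$classes[1 + (sc > thr_raw)]
      hit <- matrix(pred == hit_template, n_test, Tt)
      correct[t, ] <- correct[t, ] + colSums(hit)
      total[t, ] <- total[t, ] + n_test
    }
  }
  structure(list(accuracy = correct / total,
                 times = (0:(Tt - 1)) / data$fs,
                 n_folds = n_folds, n_trials = N, fs = data$fs,
                 seed = seed),
            class = "tgm")
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf("<tgm> %d x %d (fs = %g Hz, %d-fold CV over %d trials)\n",
              nrow(x$accuracy), ncol(x$accuracy), x$fs, x$n_folds,
              x$n_trials))
  cat(sprintf("  accuracy: mean %.3f, max %.3f (diagonal max %.3f)\n",
              mean(x$accuracy), max(x$accuracy), max(diag(x$accuracy))))
  invisible(x)
}

#' Average temporal generalisation matrices entrywise
#'
#' @param tgms A list of `tgm` objects (or several passed via `...`) with
#'   identical dimensions.
#' @param ... Additional `tgm` objects.
#' @return A `tgm` whose accuracy is the entrywise mean.
#' @export
average_tgms <- function(tgms, ...) {
  if (inherits(tgms, "tgm")) tgms <- list(tgms)
  tgms <- c(tgms, list(...))
  stopifnot(length(tgms) >= 1, all(vapply(tgms, inherits, TRUE, "tgm")))
  dims <- vapply(tgms, function(x) dim(x$accuracy), integer(2))
  if (any(dims != dims[, 1])) {
    stop("TGMs have mismatched dimensions and cannot be averaged",
         call. = FALSE)
  }
  out <- tgms[[1]]
  out$accuracy <- Reduce(`+`, lapply(tgms, `[[`, "accuracy")) / length(tgms)
  out$n_runs <- length(tgms)
  out
}
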