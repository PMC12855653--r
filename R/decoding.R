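#' Average trials into surrogate ERPs
#'
#' Raises signal-to-noise before decoding by partitioning each class's
#' trials at random into `n_per_class` near-equal groups and averaging each
#' group into one surrogate ERP. With the default race scheme this yields
#' 18 surrogates per class (36 total); the identity scheme uses 6 per
#' identity (24 total). No trial is reused within one draw.
#'
#' @param epochs an [eeg_epochs()] restricted to the trials being decoded.
#' @param class_col label column defining the classes (`"race"` or
#'   `"identity"`).
#' @param n_per_class surrogates per class.
#' @param seed integer seed.
#' @return A list of class `surrogate_set`: `data` (surrogates x channels x
#'   time array), `class` (factor), `times`, `channels`.
#' @export
average_to_surrogates <- function(epochs, class_col = "race",
                                  n_per_class = 18, seed = NULL) {
  y <- as.character(epochs$labels[[class_col]])
  classes <- sort(unique(y))
  counts <- table(y)
  if (any(counts < n_per_class)) {
    bad <- names(counts)[counts < n_per_class]
    abort(sprintf("class %s has %s trials; need >= %d per class",
                  paste(bad, collapse = ","),
                  paste(counts[bad], collapse = ","), n_per_class))
  }
  nch <- dim(epochs$data)[1]
  nt <- dim(epochs$data)[2]
  with_seed(seed, {
    out <- array(0, dim = c(n_per_class * length(classes), nch, nt))
    lab <- character(0)
    row <- 0
    for (cl in classes) {
      idx <- sample(which(y == cl))
      groups <- split(idx, sort(rep_len(seq_len(n_per_class), length(idx))))
      for (g in groups) {
        row <- row + 1
        out[row, , ] <- rowMeans(epochs$data[, , g, drop = FALSE], dims = 2)
        lab <- c(lab, cl)
      }
    }
    structure(list(data = out, class = factor(lab), times = epochs$times,
                   channels = epochs$channels),
              class = "surrogate_set")
  })
}

#' Assign surrogates to class-balanced folds
#'
#' @param surrogates a `surrogate_set`.
#' @param n_folds number of cross-validation folds (default 3, giving
#'   folds of 12 for the race scheme and 8 for the identity scheme).
#' @param seed integer seed.
#' @return Integer vector of fold ids, one per surrogate, with equal class
#'   representation in every fold.
#' @export
make_folds <- function(surrogates, n_folds = 3, seed = NULL) {
  y <- surrogates$class
  counts <- table(y)
  if (any(counts %% n_folds != 0)) {
    abort(sprintf("per-class counts (%s) not divisible by %d folds",
                  paste(counts, collapse = ","), n_folds))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Sliding-window channel features
#'
#' Downsamples surrogate ERPs to `downsample_to` Hz and averages voltage
#' within each 100 ms window, giving one feature per channel per window.
#' Windows start every `step` ms from `range[1]`; a window is the half-open
#' span `[start, start + win)` and windows extending past the epoch end are
#' dropped.
#'
#' @param surrogates a `surrogate_set`.
#' @param win window length (ms).
#' @param step window increment (ms).
#' @param range decoded time span (ms), default 0 to 996.
#' @param downsample_to target sampling rate (Hz).
#' @return A list: `features` (surrogates x channels x windows array) and
#'   `window_starts` (ms).
#' @export
window_features <- function(surrogates, win = 100, step = 8,
                            range = c(0, 996), downsample_to = 125) {
  times <- surrogates$times
  srate0 <- 1000 / median(diff(times))
  dec <- max(1L, round(srate0 / downsample_to))
  keep <- seq(1, length(times), by = dec)
  times <- times[keep]
  dat <- surrogates$data[, , keep, drop = FALSE]
  starts <- seq(range[1], range[2], by = step)
  ok <- starts + win <= max(times) + 1000 / downsample_to
  starts <- starts[ok]
  nwin <- length(starts)
  feats <- array(0, dim = c(dim(dat)[1], dim(dat)[2], nwin))
  for (w in seq_len(nwin)) {
    ti <- which(times >= starts[w] & times < starts[w] + win)
    feats[, , w] <- rowMeans(dat[, , ti, drop = FALSE], dims = 2)
  }
  list(features = feats, window_starts = starts)
}

# decision values of a fitted linear SVM, computed from the primal weights
# (avoids predict() overhead; positive margin = first factor level)
linear_svm_margin <- function(fit, Xte) {
  w <- crossprod(fit$SV, fit$coefs)
  as.numeric(Xte %*% w) - fit$rho
}

# train/test one window with z-normalization from the training folds only
svm_window_accuracy <- function(X, y, folds, scheme, cost = 1) {
  accs <- numeric(max(folds))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- sqrt(colSums(sweep(Xtr, 2, mu)^2) / (nrow(Xtr) - 1))
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
    ytr <- y[tr]
    yte <- y[!tr]
    if (length(unique(ytr)) < length(levels(y))) {
      abort(sprintf("class missing from training folds (fold %d held out)", f))
    }
    if (scheme == "ovo" || length(levels(y)) == 2) {
      fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = cost,
                        scale = FALSE)
      if (length(levels(y)) == 2) {
        d <- linear_svm_margin(fit, Xte)
        pred <- ifelse(d > 0, fit$levels[1], fit$levels[2])
      } else {
        pred <- stats::predict(fit, Xte)
      }
    } else {
      # one-versus-all: one binary SVM per class, predict by max margin
      dv <- vapply(levels(y), function(cl) {
        yy <- factor(ifelse(ytr == cl, "pos", "rest"),
                     levels = c("pos", "rest"))
        fit <- e1071::svm(Xtr, yy, kernel = "linear", cost = cost,
                          scale = FALSE)
        d <- linear_svm_margin(fit, Xte)
        if (fit$levels[1] == "pos") d else -d
      }, numeric(sum(!tr)))
      dv <- matrix(dv, ncol = length(levels(y)))
      pred <- levels(y)[max.col(dv, ties.method = "first")]
    }
    accs[f] <- mean(as.character(pred) == as.character(yte))
  }
  mean(accs)
}

#' Sliding-window decoding of race or identity
#'
#' The full decoding loop for one participant-condition: per iteration,
#' trials are re-averaged into surrogate ERPs and re-assigned to
#' class-balanced folds; per 100 ms window, features are z-normalized with
#' training-fold statistics and classified with a linear SVM (C = 1;
#' one-versus-one for the 2-class race scheme, one-versus-all for the
#' 4-class identity scheme); accuracy is averaged over the three
#' cross-validation rotations.
#'
#' @param epochs an [eeg_epochs()] restricted to the decoded condition
#'   (e.g. one mask condition for race decoding, one race x mask cell for
#'   identity decoding).
#' @param scheme `"race"` (2 classes, chance 0.5, 18 surrogates/class) or
#'   `"identity"` (4 classes, chance 0.25, 6 surrogates/class).
#' @param n_iter surrogate/fold re-draws (default 10).
#' @param seed integer seed.
#' @param n_per_class,n_folds,win,step,range,downsample_to,cost see
#'   [average_to_surrogates()], [make_folds()], [window_features()].
#' @param shuffle_labels if `TRUE` class labels are permuted independently
#'   per iteration before decoding (empirical-chance control).
#' @return A `decoding_result`: `times` (window starts, ms), `accuracy`
#'   (windows x iterations matrix), `chance`, `scheme`.
#' @export
decode_timecourse <- function(epochs, scheme = c("race", "identity"),
                              n_iter = 10, seed = NULL, n_per_class = NULL,
                              n_folds = 3, win = 100, step = 8,
                              range = c(0, 996), downsample_to = 125,
                              cost = 1, shuffle_labels = FALSE) {
  scheme <- match.arg(scheme)
  class_col <- if (scheme == "race") "race" else "identity"
  n_per_class <- n_per_class %||% if (scheme == "race") 18L else 6L
  chance <- 1 / length(unique(epochs$labels[[class_col]]))
  acc <- NULL
  with_seed(seed, {
    labels0 <- epochs$labels[[class_col]]
    for (it in seq_len(n_iter)) {
      ep <- epochs
      if (shuffle_labels) {
        ep$labels[[class_col]] <- sample(labels0)
      }
      surr <- average_to_surrogates(ep, class_col, n_per_class)
      folds <- make_folds(surr, n_folds)
      wf <- window_features(surr, win, step, range, downsample_to)
      a <- vapply(seq_along(wf$window_starts), function(w) {
        svm_window_accuracy(wf$features[, , w, drop = TRUE], surr$class,
                            folds, scheme = if (scheme == "race") "ovo" else "ova",
                            cost = cost)
      }, 0)
      acc <- cbind(acc, a)
    }
    structure(
      list(times = wf$window_starts, accuracy = unname(acc), chance = chance,
           scheme = scheme),
      class = "decoding_result"
    )
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s, %d windows x %d iterations, chance %.2f, mean acc %.3f\n",
              x$scheme, nrow(x$accuracy), ncol(x$accuracy), x$chance,
              mean(x$accuracy)))
  invisible(x)
}

#' @describeIn decode_timecourse tidy accuracy table (window_ms, iteration,
#'   accuracy).
#' @param x a `decoding_result`.
#' @param ... unused.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(
    window_ms = rep(x$times, times = ncol(x$accuracy)),
    iteration = rep(seq_len(ncol(x$accuracy)), each = length(x$times)),
    accuracy = as.numeric(x$accuracy)
  )
}

#' @describeIn decode_timecourse one-row summary with mean accuracy and
#'   peak latency.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, chance = x$chance,
                 mean_accuracy = mean(x$accuracy),
                 peak_ms = peak_latency(x))
}

#' Peak decoding latency
#'
#' Window start (ms) at which the iteration-mean accuracy is maximal; ties
#' resolve to the earliest window.
#'
#' @param result a `decoding_result`.
#' @return Latency in ms.
#' @export
peak_latency <- function(result) {
  m <- rowMeans(result$accuracy)
  result$times[which.max(m)]
}
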