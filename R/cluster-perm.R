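#' Cluster-based permutation test on accuracy time courses
#'
#' Tests participant-level decoding accuracy against chance (one-sample)
#' or between two conditions (paired) while controlling the family-wise
#' error over time. Pointwise t statistics (df = participants - 1,
#' two-tailed at `alpha` by default) are thresholded; maximal runs of
#' consecutive supra-threshold windows with a common sign form clusters
#' whose t values are summed into a cluster-level t mass. The null
#' distribution of the maximal |t mass| is built from `n_perm` seeded
#' sign flips of the per-participant deviation (equivalently,
#' within-participant condition exchange for the paired test); a cluster
#' is significant when its observed |mass| exceeds the null's
#' `1 - alpha` quantile.
#'
#' @param acc participants x windows matrix of iteration-mean accuracy, or
#'   a tidy data frame with columns `participant`, `window_ms`,
#'   `accuracy`.
#' @param chance chance level subtracted before the one-sample test
#'   (ignored when `acc_b` is given).
#' @param acc_b optional second condition (same shape as `acc`) for a
#'   paired test of `acc - acc_b`.
#' @param n_perm number of permutations (default 1000).
#' @param alpha cluster-forming and cluster-level alpha (default 0.05).
#' @param seed integer seed.
#' @param tails `"two"` (default) or `"one"` (positive deviations only).
#' @param times window positions (ms); taken from `window_ms` when `acc`
#'   is tidy.
#' @return A `cluster_result`: tibble of clusters (`start_ms`, `end_ms`,
#'   `t_mass`, `p_perm`, `significant`) plus the pointwise t curve.
#' @export
cluster_permutation_test <- function(acc, chance = 0.5, acc_b = NULL,
                                     n_perm = 1000, alpha = 0.05,
                                     seed = NULL, tails = c("two", "one"),
                                     times = NULL) {
  tails <- match.arg(tails)
  if (is.data.frame(acc)) {
    wide <- tidyr::pivot_wider(acc, id_cols = "participant",
                               names_from = "window_ms",
                               values_from = "accuracy")
    times <- times %||% as.numeric(names(wide)[-1])
    acc <- as.matrix(wide[, -1])
  }
  if (!is.null(acc_b)) {
    if (is.data.frame(acc_b)) {
      wide <- tidyr::pivot_wider(acc_b, id_cols = "participant",
                                 names_from = "window_ms",
                                 values_from = "accuracy")
      acc_b <- as.matrix(wide[, -1])
    }
    dev <- acc - acc_b
  } else {
    dev <- acc - chance
  }
  n <- nrow(dev)
  if (n < 3) abort("cluster permutation test needs at least 3 participants")
  W <- ncol(dev)
  times <- times %||% seq_len(W)
  df <- n - 1
  tcrit <- if (tails == "two") qt(1 - alpha / 2, df) else qt(1 - alpha, df)
  sumsq <- colSums(dev^2)
  t_of_means <- function(m) {
    v <- (sumsq - n * m^2) / df
    v[v < 1e-24] <- 1e-24
    m / sqrt(v / n)
  }
  tobs <- t_of_means(colMeans(dev))
  obs_clusters <- find_clusters(tobs, tcrit, tails)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tp <- t_of_means(as.numeric(s %*% dev) / n)
      cl <- find_clusters(tp, tcrit, tails)
      if (nrow(cl) == 0) 0 else max(abs(cl$t_mass))
    }, 0)
  })
  thr <- quantile(null_max, 1 - alpha, names = FALSE, type = 1)
  clusters <- obs_clusters
  if (nrow(clusters) > 0) {
    clusters$p_perm <- vapply(clusters$t_mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, 0)
    clusters$significant <- abs(clusters$t_mass) > thr
    clusters$start_ms <- times[clusters$start]
    clusters$end_ms <- times[clusters$end]
    clusters <- clusters[, c("start_ms", "end_ms", "t_mass", "p_perm",
                             "significant")]
  } else {
    clusters <- tibble::tibble(start_ms = numeric(0), end_ms = numeric(0),
                               t_mass = numeric(0), p_perm = numeric(0),
                               significant = logical(0))
  }
  structure(
    list(clusters = clusters, t = tobs, times = times, alpha = alpha,
         n_perm = n_perm, null_max = null_max),
    class = "cluster_result"
  )
}

# maximal runs of consecutive supra-threshold windows with common sign
find_clusters <- function(tvec, tcrit, tails = "two") {
  sig <- if (tails == "two") abs(tvec) > tcrit else tvec > tcrit
  lab <- sign(tvec) * sig
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    t_mass = vapply(which(keep), function(i) {
      sum(tvec[starts[i]:ends[i]])
    }, 0)
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, alpha %.2f\n",
              nrow(x$clusters), x$n_perm, x$alpha))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' Mask-by-race interaction cluster test
#'
#' For each participant forms the double-difference accuracy time course
#' `(Asian unmasked - Asian masked) - (White unmasked - White masked)` and
#' runs the one-sample cluster permutation test against zero.
#'
#' @param cells named list of participants x windows accuracy matrices
#'   with names `asian_unmasked`, `asian_masked`, `white_unmasked`,
#'   `white_masked` (aligned rows and windows).
#' @inheritParams cluster_permutation_test
#' @return A `cluster_result`.
#' @export
interaction_cluster_test <- function(cells, n_perm = 1000, alpha = 0.05,
                                     seed = NULL, times = NULL,
                                     tails = "two") {
  need <- c("asian_unmasked", "asian_masked", "white_unmasked", "white_masked")
  if (!all(need %in% names(cells))) {
    abort(paste("missing cells:", paste(setdiff(need, names(cells)),
                                        collapse = ", ")))
  }
  dd <- (cells$asian_unmasked - cells$asian_masked) -
    (cells$white_unmasked - cells$white_masked)
  cluster_permutation_test(dd, chance = 0, n_perm = n_perm, alpha = alpha,
                           seed = seed, times = times, tails = tails)
}
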