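#' Cluster scanpath HMMs into representative patterns
#'
#' Groups a set of individual `eye_hmm`s into `n_clusters` representative
#' group-level HMMs by hierarchical EM on virtual samples: each input model
#' emits `n_virtual` virtual fixation sequences of length `tau`, cluster
#' responsibilities follow the expected log-likelihood of those sequences
#' under the current group models, and each group model is re-estimated by
#' weighted Baum-Welch on the pooled virtual sequences. Deterministic given
#' `seed`; hard assignment ties go to the lowest cluster index. Clusters are
#' relabeled so cluster 1 is the vertically highest (most eyes-focused)
#' pattern.
#'
#' @param models list of [eye_hmm()] objects (>= `n_clusters`).
#' @param n_clusters number of representative patterns (default 2).
#' @param n_virtual virtual sequences sampled per input model.
#' @param tau virtual sequence length (fixations).
#' @param seed integer seed.
#' @param max_iter EM iteration cap.
#' @param K_group ROI count for the group models; defaults to the largest
#'   K among the inputs (capped at 5).
#' @return A `representative_set`: list with `models` (group HMMs),
#'   `assignment` (tibble: `model`, `cluster`) and `loglik` (virtual-sample
#'   log-likelihood matrix, models x clusters).
#' @export
cluster_hmms <- function(models, n_clusters = 2, n_virtual = 50, tau = 10,
                         seed = NULL, max_iter = 25, K_group = NULL) {
  n <- length(models)
  if (n < n_clusters) {
    abort(sprintf("cannot form %d clusters from %d models", n_clusters, n))
  }
  K_group <- K_group %||% min(5L, max(vapply(models, function(m) m$K, 0L)))
  with_seed(seed, {
    virt <- lapply(models, function(m) {
      lapply(seq_len(n_virtual), function(i) sample_hmm_positions(m, tau))
    })
    pooled <- unlist(virt, recursive = FALSE)
    wseq <- function(assign_idx) {
      # weight 1 for sequences from assigned models, 0 otherwise
      w <- rep(0, n * n_virtual)
      for (i in assign_idx) w[((i - 1) * n_virtual + 1):(i * n_virtual)] <- 1
      w
    }
    # initialize from cheap model summaries (stationary mean position,
    # dispersion, transition entropy) instead of an n x n likelihood table
    feats <- t(vapply(models, function(m) {
      w <- stationary_distribution(m$transition) %||% m$prior
      dets <- vapply(seq_len(m$K), function(k) det(m$covs[, , k]), 0)
      ent <- sum(w * apply(m$transition, 1, function(p) {
        p <- p[p > 0]; -sum(p * log(p))
      }))
      c(sum(w * m$means[, 1]), sum(w * m$means[, 2]),
        sqrt(sqrt(sum(w * dets))), 50 * ent)
    }, numeric(4)))
    cl <- if (n_clusters == 1) {
      rep(1L, n)
    } else if (n == n_clusters) {
      seq_len(n)
    } else {
      tryCatch(kmeans(feats, centers = n_clusters, nstart = 5)$cluster,
               error = function(e) {
                 cutree(hclust(dist(feats)), k = n_clusters)
               })
    }
    L <- NULL
    reps <- lapply(seq_len(n_clusters), function(j) {
      fit_hmm_weighted(pooled, wseq(which(cl == j)), K_group)
    })
    for (it in seq_len(max_iter)) {
      L <- cross_loglik_matrix(virt, reps)
      new_cl <- apply(L, 1, which.max)   # ties -> lowest index
      if (all(new_cl == cl) && it > 1) break
      cl <- new_cl
      for (j in seq_len(n_clusters)) {
        idx <- which(cl == j)
        if (length(idx) == 0) next       # empty cluster: keep current model
        reps[[j]] <- fit_hmm_weighted(pooled, wseq(idx), K_group)
      }
    }
    # order clusters top-down by stationary-weighted ROI height (small y =
    # high on screen = eyes region first)
    height <- vapply(reps, function(m) {
      w <- stationary_distribution(m$transition) %||% m$prior
      sum(w * m$means[, 2])
    }, 0)
    ord <- order(height)
    reps <- reps[ord]
    cl <- match(cl, ord)
    L <- L[, ord, drop = FALSE]
    structure(
      list(models = reps,
           assignment = tibble::tibble(model = seq_len(n), cluster = cl),
           loglik = L),
      class = "representative_set"
    )
  })
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("<representative_set> %d pattern(s), %d models\n",
              length(x$models), nrow(x$assignment)))
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' @export
tidy.representative_set <- function(x, ...) x$assignment

# positions-only forward sampling (no durations) used for virtual samples
sample_hmm_positions <- function(hmm, tau) {
  states <- integer(tau)
  states[1] <- sample.int(hmm$K, 1, prob = hmm$prior)
  if (tau > 1) {
    for (t in 2:tau) {
      states[t] <- sample.int(hmm$K, 1, prob = hmm$transition[states[t - 1], ])
    }
  }
  xy <- matrix(0, tau, 2)
  for (k in unique(states)) {
    idx <- which(states == k)
    xy[idx, ] <- rmvnorm2(length(idx), hmm$means[k, ], hmm$covs[, , k])
  }
  xy
}

# total loglik of each model's virtual set under each candidate model
# (always an n_models x n_candidates matrix, even for one candidate)
cross_loglik_matrix <- function(virt, candidates) {
  out <- vapply(virt, function(vs) {
    vapply(candidates, function(m) {
      sum(vapply(vs, function(s) forward_loglik(m, s), 0))
    }, 0)
  }, numeric(length(candidates)))
  matrix(out, nrow = length(virt), ncol = length(candidates), byrow = TRUE)
}

# weighted maximum-likelihood Baum-Welch with covariance ridge
fit_hmm_weighted <- function(seqs, weights, K, max_iter = 40, tol = 1e-6,
                             ridge = 25) {
  keep <- weights > 0
  seqs <- seqs[keep]
  weights <- weights[keep]
  X <- do.call(rbind, seqs)
  km <- if (K > 1) kmeans(X, centers = K, nstart = 3) else NULL
  means <- if (K > 1) km$centers else matrix(colMeans(X), 1)
  covs <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) {
    idx <- if (K > 1) km$cluster == k else rep(TRUE, nrow(X))
    covs[, , k] <- cov_ridged(X[idx, , drop = FALSE], ridge)
  }
  prior <- rep(1 / K, K)
  A <- matrix(1 / K, K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    first <- numeric(K)
    trans <- matrix(0, K, K)
    Gall <- NULL
    ll <- 0
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      lB <- matrix(0, nrow(s), K)
      for (k in seq_len(K)) lB[, k] <- dmvnorm2_log(s, means[k, ], covs[, , k])
      fb <- forward_backward(prior, A, lB)
      ll <- ll + weights[i] * fb$logZ
      first <- first + weights[i] * fb$gamma[1, ]
      trans <- trans + weights[i] * fb$xi
      Gall <- rbind(Gall, weights[i] * fb$gamma)
    }
    prior <- (first + 1e-6) / sum(first + 1e-6)
    A <- (trans + 1e-6)
    A <- A / rowSums(A)
    m <- soft_moments(X, Gall)
    means <- m$xbar
    for (k in seq_len(K)) {
      covs[, , k] <- (m$Sk[, , k] * m$Nk[k] + ridge * diag(2)) / (m$Nk[k] + 1)
      covs[, , k] <- (covs[, , k] + t(covs[, , k])) / 2
    }
    if (abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  eye_hmm(prior, A, means, covs, elbo = ll)
}

cov_ridged <- function(X, ridge) {
  S <- if (nrow(X) > 1) stats::cov(X) else diag(2)
  S <- (S + t(S)) / 2 + ridge * diag(2)
  S
}

#' Score participants on the eyes-nose scale and entropy
#'
#' For each participant-condition fixation set, computes log-likelihoods
#' under the two representative models, the [ab_scale()] (pattern 1 minus
#' pattern 2, i.e. eyes minus nose under the default ordering) and the
#' overall [hmm_entropy()] of the participant's own condition model.
#'
#' @param fixations tidy fixation table with columns `participant`, `race`,
#'   `mask`, `trial`, `x`, `y`.
#' @param reps a `representative_set` with two models (see [cluster_hmms()]).
#' @param models optional named list of per-participant-condition
#'   [eye_hmm()]s (names `"participant|race|mask"`) used for the entropy
#'   column; omitted entries give `NA` entropy.
#' @param normalization passed to [hmm_loglik()].
#' @return A tibble: participant, race, mask, ll_a, ll_b, ab_scale, entropy.
#' @export
score_scanpaths <- function(fixations, reps, models = NULL,
                            normalization = "total") {
  stopifnot(length(reps$models) >= 2)
  fixations |>
    dplyr::group_by(.data$participant, .data$race, .data$mask) |>
    dplyr::group_modify(function(df, key) {
      ll_a <- hmm_loglik(reps$models[[1]], df, normalization)
      ll_b <- hmm_loglik(reps$models[[2]], df, normalization)
      ent <- NA_real_
      if (!is.null(models)) {
        id <- paste(key$participant, key$race, key$mask, sep = "|")
        if (!is.null(models[[id]])) {
          e <- hmm_entropy(models[[id]])
          ent <- e$value[e$term == "overall"]
        }
      }
      tibble::tibble(ll_a = ll_a, ll_b = ll_b,
                     ab_scale = ab_scale(ll_a, ll_b), entropy = ent)
    }) |>
    dplyr::ungroup()
}
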