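#' Log-likelihood of fixation sequences under a scanpath HMM
#'
#' Scaled forward algorithm over the Gaussian-emission Markov chain; all
#' per-step quantities are renormalized so sequences of up to ~1e4
#' fixations evaluate without underflow.
#'
#' @param hmm an [eye_hmm()].
#' @param fixations a data frame with columns `x`, `y` and (if more than
#'   one trial) `trial`; each trial is one fixation sequence, ordered.
#' @param normalization `"total"` (sum of per-sequence log-likelihoods, the
#'   default used by the eyes-nose scale) or `"per-sequence-mean"`.
#' @return A single log-likelihood in nats.
#' @export
hmm_loglik <- function(hmm, fixations,
                       normalization = c("total", "per-sequence-mean")) {
  normalization <- match.arg(normalization)
  seqs <- split_fixations(fixations)
  if (length(seqs) == 0) abort("no fixation sequences supplied")
  ll <- vapply(seqs, function(s) forward_loglik(hmm, s), 0)
  if (normalization == "total") sum(ll) else mean(ll)
}

split_fixations <- function(fixations) {
  stopifnot(all(c("x", "y") %in% names(fixations)))
  xy <- cbind(fixations$x, fixations$y)
  if (!all(is.finite(xy))) abort("fixation coordinates must be finite")
  if ("trial" %in% names(fixations)) {
    lapply(split(seq_len(nrow(xy)), fixations$trial), function(i) {
      xy[i, , drop = FALSE]
    })
  } else {
    list(xy)
  }
}

# scaled forward pass for one T x 2 coordinate matrix
forward_loglik <- function(hmm, xy) {
  K <- hmm$K
  Tn <- nrow(xy)
  lB <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    lB[, k] <- dmvnorm2_log(xy, hmm$means[k, ], hmm$covs[, , k])
  }
  m1 <- max(lB[1, ])
  alpha <- hmm$prior * exp(lB[1, ] - m1)
  c1 <- sum(alpha)
  ll <- log(c1) + m1
  alpha <- alpha / c1
  if (Tn > 1) {
    for (t in 2:Tn) {
      mt <- max(lB[t, ])
      a <- as.numeric(alpha %*% hmm$transition) * exp(lB[t, ] - mt)
      ct <- sum(a)
      ll <- ll + log(ct) + mt
      alpha <- a / ct
    }
  }
  ll
}

#' Eyes-nose (A-B) scale
#'
#' Normalized contrast of the log-likelihoods of a participant's fixation
#' data under two representative models:
#' `(ll_a - ll_b) / (|ll_a| + |ll_b|)`. Positive values indicate scanpaths
#' more similar to pattern A (by convention the eyes-focused pattern, hence
#' "eyes-nose scale"). When both log-likelihoods are strictly negative the
#' value lies in (-1, 1), and swapping the two inputs flips its sign.
#'
#' @param ll_a,ll_b log-likelihoods under representative models A and B.
#' @return A numeric scalar.
#' @export
ab_scale <- function(ll_a, ll_b) {
  stopifnot(is.finite(ll_a), is.finite(ll_b))
  denom <- abs(ll_a) + abs(ll_b)
  if (denom == 0) abort("A-B scale undefined: both log-likelihoods are zero")
  (ll_a - ll_b) / denom
}

#' Overall entropy of a scanpath HMM
#'
#' Decomposes scanpath predictability into a transition term (the entropy
#' rate of the ROI chain, weighted by its stationary distribution) and an
#' emission term (stationary-weighted Gaussian differential entropy of the
#' ROIs). Lower overall entropy means more consistent eye movements. For a
#' chain without a unique stationary distribution the prior weights are
#' used instead, with a warning.
#'
#' @param hmm an [eye_hmm()].
#' @return A tibble with rows `transition`, `emission` and `overall` and
#'   columns `term`, `value` (nats) and `unit`.
#' @export
hmm_entropy <- function(hmm) {
  w <- stationary_distribution(hmm$transition)
  if (is.null(w)) {
    warn("transition chain has no unique stationary distribution; weighting by the prior")
    w <- hmm$prior
  }
  row_ent <- apply(hmm$transition, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  h_trans <- sum(w * row_ent)
  h_emit <- sum(w * vapply(seq_len(hmm$K), function(k) {
    log(2 * pi * exp(1)) + 0.5 * log(det(hmm$covs[, , k]))
  }, 0))
  tibble::tibble(
    term = c("transition", "emission", "overall"),
    value = c(h_trans, h_emit, h_trans + h_emit),
    unit = "nats"
  )
}
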