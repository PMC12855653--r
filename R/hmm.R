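#' Construct a scanpath hidden Markov model
#'
#' An `eye_hmm` describes one participant-condition scanpath model: a
#' discrete Markov chain over K regions of interest (ROIs), each ROI a 2-D
#' Gaussian over screen-pixel fixation positions (origin top-left, y
#' increasing downward).
#'
#' @param prior length-K vector of start probabilities (sums to 1).
#' @param transition K x K row-stochastic transition matrix.
#' @param means K x 2 matrix of ROI centers (px).
#' @param covs 2 x 2 x K array of ROI covariances (px^2), each symmetric
#'   positive-definite.
#' @param elbo optional variational lower bound on the marginal
#'   log-likelihood (nats) recorded by [fit_vbhmm()].
#'
#' @return An object of class `eye_hmm`.
#' @export
eye_hmm <- function(prior, transition, means, covs, elbo = NA_real_) {
  K <- length(prior)
  transition <- as.matrix(transition)
  means <- matrix(as.numeric(means), nrow = K)
  stopifnot(ncol(means) == 2, all(dim(transition) == K))
  if (length(dim(covs)) != 3) covs <- array(covs, dim = c(2, 2, K))
  check_stochastic(prior, "prior")
  for (j in seq_len(K)) {
    check_stochastic(transition[j, ], sprintf("transition row %d", j))
    if (!is_spd(covs[, , j])) {
      abort(sprintf("ROI %d covariance is not symmetric positive-definite", j))
    }
  }
  structure(
    list(K = K, prior = as.numeric(prior), transition = transition,
         means = means, covs = covs, elbo = elbo),
    class = "eye_hmm"
  )
}

#' @export
print.eye_hmm <- function(x, ...) {
  cat(sprintf("<eye_hmm> %d ROI(s), ELBO %.2f\n", x$K, x$elbo))
  for (k in seq_len(x$K)) {
    cat(sprintf("  ROI %d: mean (%.0f, %.0f) px, prior %.3f\n",
                k, x$means[k, 1], x$means[k, 2], x$prior[k]))
  }
  invisible(x)
}

#' @describeIn eye_hmm ROI-level summary: one row per ROI with its prior,
#'   mean position and covariance determinant.
#' @param x an `eye_hmm`.
#' @param ... unused.
#' @export
tidy.eye_hmm <- function(x, ...) {
  tibble::tibble(
    roi = seq_len(x$K),
    prior = x$prior,
    mean_x = x$means[, 1],
    mean_y = x$means[, 2],
    cov_det = vapply(seq_len(x$K), function(k) det(x$covs[, , k]), 0)
  )
}

#' @describeIn eye_hmm one-row model summary (K, ELBO, entropy terms).
#' @export
glance.eye_hmm <- function(x, ...) {
  ent <- hmm_entropy(x)
  tibble::tibble(K = x$K, elbo = x$elbo,
                 entropy = ent$value[ent$term == "overall"])
}

# stationary distribution of the transition chain; NULL when not unique
stationary_distribution <- function(transition, tol = 1e-8) {
  ev <- eigen(t(transition))
  idx <- which(abs(ev$values - 1) < tol)
  if (length(idx) != 1) return(NULL)
  s <- Re(ev$vectors[, idx])
  s <- s / sum(s)
  if (any(s < -tol)) return(NULL)
  pmax(s, 0) / sum(pmax(s, 0))
}

#' Archetypal scanpath models
#'
#' Returns a reference `eye_hmm` for the two scanpath archetypes seen in
#' face viewing: an eyes-focused pattern with ROIs over the two eyes, and a
#' nose-focused pattern centered on the nose with occasional excursions to
#' the eye region. Geometry assumes a face centered in a `frame` of
#' 1920 x 1080 px with eyes near y = 430 and the nose near y = 560.
#'
#' @param type `"eyes"` or `"nose"`.
#' @param frame screen size in px, `c(width, height)`.
#' @param mask_shift upward displacement (px) of ROI means applied in masked
#'   conditions, moving gaze toward the (visible) eye region.
#' @param sharpen transition-sharpening exponent (>= 1) applied in masked
#'   conditions: each transition row is raised elementwise to this power and
#'   renormalized, which never increases the transition entropy.
#' @return An `eye_hmm`.
#' @export
archetype_hmm <- function(type = c("eyes", "nose"), frame = c(1920, 1080),
                          mask_shift = 0, sharpen = 1) {
  type <- match.arg(type)
  cx <- frame[1] / 2
  sd2 <- function(sx, sy) diag(c(sx^2, sy^2))
  if (type == "eyes") {
    means <- rbind(c(cx - 85, 430), c(cx + 85, 430))
    covs <- array(c(sd2(60, 45), sd2(60, 45)), dim = c(2, 2, 2))
    prior <- c(0.55, 0.45)
    transition <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  } else {
    means <- rbind(c(cx, 560), c(cx, 430))
    covs <- array(c(sd2(70, 60), sd2(110, 50)), dim = c(2, 2, 2))
    prior <- c(0.8, 0.2)
    transition <- rbind(c(0.85, 0.15), c(0.5, 0.5))
  }
  means[, 2] <- means[, 2] - mask_shift
  if (sharpen != 1) {
    transition <- transition^sharpen
    transition <- transition / rowSums(transition)
    prior <- prior^sharpen
    prior <- prior / sum(prior)
  }
  eye_hmm(prior, transition, means, covs)
}
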