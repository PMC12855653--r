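#' Fit a scanpath HMM by variational Bayes
#'
#' Variational-Bayes EM for a hidden Markov model with 2-D Gaussian
#' emissions (the standard conjugate scheme: symmetric Dirichlet priors on
#' the start probabilities and each transition row, Normal-Wishart priors
#' on the ROI mean/precision). Hyperparameters are weakly informative: the
#' ROI mean prior sits at the frame center with a broad (~200 px) scale.
#' The variational lower bound (ELBO) is evaluated after every E step and
#' is non-decreasing across iterations; the best of `n_restarts` seeded
#' k-means initializations is returned.
#'
#' @param fixations data frame with `x`, `y` and optionally `trial`.
#' @param K number of ROIs (Gaussian emission components).
#' @param hyper list of prior hyperparameters; see [vb_hyper()].
#' @param n_restarts independent initializations (default 5).
#' @param seed integer seed making the fit deterministic.
#' @param max_iter,tol VB-EM iteration cap and relative-ELBO convergence
#'   tolerance.
#' @return An [eye_hmm()] with posterior-mean parameters and the final
#'   ELBO; the per-iteration ELBO trace is attached as attribute
#'   `"elbo_trace"`.
#' @export
fit_vbhmm <- function(fixations, K, hyper = vb_hyper(), n_restarts = 5,
                      seed = NULL, max_iter = 200, tol = 1e-5) {
  seqs <- split_fixations(fixations)
  X <- do.call(rbind, seqs)
  n <- nrow(X)
  if (n < K + 1) abort(sprintf("need at least K+1 = %d fixations, got %d", K + 1, n))
  if (all(apply(X, 2, sd) < 1e-9)) {
    warn("all fixations are identical; returning a prior-regularized fit")
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- vbhmm_once(seqs, X, K, hyper, max_iter, tol)
      if (is.null(best) || fit$elbo > best$elbo) best <- fit
    }
  })
  hmm <- posterior_mean_hmm(best$post, K)
  hmm$elbo <- best$elbo
  attr(hmm, "elbo_trace") <- best$trace
  hmm
}

#' VB prior hyperparameters
#'
#' @param alpha0 symmetric Dirichlet concentration for the start vector and
#'   each transition row.
#' @param m0 prior ROI mean (px); defaults to the center of a 1920 x 1080
#'   frame.
#' @param beta0 prior mean precision scale (small = broad).
#' @param nu0 Wishart degrees of freedom (> 1 for 2-D).
#' @param s0 prior ROI standard deviation (px) setting the Wishart scale so
#'   the prior expected precision is `diag(1/s0^2)`.
#' @return A named list.
#' @export
vb_hyper <- function(alpha0 = 1, m0 = c(960, 540), beta0 = 0.01,
                     nu0 = 3, s0 = 200) {
  W0 <- diag(2) / (nu0 * s0^2)
  list(alpha0 = alpha0, m0 = m0, beta0 = beta0, nu0 = nu0,
       W0 = W0, W0inv = solve(W0))
}

# one seeded VB-EM run; returns final posterior, elbo, trace
vbhmm_once <- function(seqs, X, K, hyper, max_iter, tol) {
  n <- nrow(X)
  # initialize responsibilities from (jittered) k-means and take an M step
  if (K == 1) {
    g <- matrix(1, n, 1)
  } else {
    km <- tryCatch(
      kmeans(X + matrix(rnorm(2 * n, 0, 1e-6), n, 2), centers = K, nstart = 1),
      error = function(e) NULL
    )
    cl <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
    g <- matrix(1e-3, n, K)
    g[cbind(seq_len(n), cl)] <- 1
    g <- g / rowSums(g)
  }
  stats0 <- list(
    first = colSums(g[cumsum(c(1, head(vapply(seqs, nrow, 0L), -1))), , drop = FALSE]),
    trans = crossprod(g[-n, , drop = FALSE], g[-1, , drop = FALSE]) + 1e-3,
    gamma_sums = soft_moments(X, g)
  )
  post <- vb_mstep(stats0, hyper, K)
  trace <- numeric(0)
  elbo <- -Inf
  for (it in seq_len(max_iter)) {
    e <- vb_estep(seqs, post, hyper, K)
    new_elbo <- e$logZ - vb_kl(post, hyper, K)
    trace <- c(trace, new_elbo)
    if (it > 1 && abs(new_elbo - elbo) <= tol * abs(elbo)) {
      elbo <- new_elbo
      break
    }
    elbo <- new_elbo
    post <- vb_mstep(e$stats, hyper, K)
  }
  list(post = post, elbo = elbo, trace = trace)
}

# weighted first/second moments per component
soft_moments <- function(X, g) {
  K <- ncol(g)
  Nk <- colSums(g) + 1e-10
  xbar <- t(vapply(seq_len(K), function(k) colSums(X * g[, k]) / Nk[k], c(0, 0)))
  Sk <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) {
    d <- sweep(X, 2, xbar[k, ])
    Sk[, , k] <- crossprod(d * g[, k], d) / Nk[k]
  }
  list(Nk = Nk, xbar = xbar, Sk = Sk)
}

vb_mstep <- function(stats, hyper, K) {
  m <- stats$gamma_sums
  Nk <- m$Nk
  beta <- hyper$beta0 + Nk
  nu <- hyper$nu0 + Nk
  mk <- matrix(0, K, 2)
  W <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) {
    mk[k, ] <- (hyper$beta0 * hyper$m0 + Nk[k] * m$xbar[k, ]) / beta[k]
    d0 <- m$xbar[k, ] - hyper$m0
    Winv <- hyper$W0inv + Nk[k] * m$Sk[, , k] +
      (hyper$beta0 * Nk[k] / (hyper$beta0 + Nk[k])) * tcrossprod(d0)
    W[, , k] <- solve((Winv + t(Winv)) / 2)
  }
  list(
    a_pi = hyper$alpha0 + stats$first,
    a_A = hyper$alpha0 + stats$trans,
    beta = beta, m = mk, W = W, nu = nu
  )
}

# expected-parameter quantities for the E step
vb_expectations <- function(post, K) {
  lpi <- digamma(post$a_pi) - digamma(sum(post$a_pi))
  lA <- matrix(0, K, K)
  for (j in seq_len(K)) {
    lA[j, ] <- digamma(post$a_A[j, ]) - digamma(sum(post$a_A[j, ]))
  }
  elogdet <- vapply(seq_len(K), function(k) {
    sum(digamma((post$nu[k] + 1 - (1:2)) / 2)) + 2 * log(2) +
      determinant(post$W[, , k])$modulus[1]
  }, 0)
  list(lpi = lpi, lA = lA, elogdet = elogdet)
}

vb_estep <- function(seqs, post, hyper, K) {
  ex <- vb_expectations(post, K)
  piS <- exp(ex$lpi)
  AS <- exp(ex$lA)
  logZ <- 0
  first <- numeric(K)
  trans <- matrix(0, K, K)
  Nk <- numeric(K)
  xsum <- matrix(0, K, 2)
  # accumulate scatter around running weighted means in a second pass
  Xall <- do.call(rbind, seqs)
  Gall <- NULL
  for (s in seqs) {
    Tn <- nrow(s)
    lB <- matrix(0, Tn, K)
    for (k in seq_len(K)) {
      d <- sweep(s, 2, post$m[k, ])
      quad <- rowSums((d %*% post$W[, , k]) * d)
      lB[, k] <- 0.5 * ex$elogdet[k] - log(2 * pi) -
        0.5 * (2 / post$beta[k] + post$nu[k] * quad)
    }
    fb <- forward_backward(piS, AS, lB)
    logZ <- logZ + fb$logZ
    first <- first + fb$gamma[1, ]
    trans <- trans + fb$xi
    Gall <- rbind(Gall, fb$gamma)
  }
  list(
    logZ = logZ,
    stats = list(first = first, trans = trans,
                 gamma_sums = soft_moments(Xall, Gall))
  )
}

# scaled forward-backward with (possibly sub-stochastic) pi/A weights
forward_backward <- function(piv, A, lB) {
  Tn <- nrow(lB)
  K <- ncol(lB)
  mshift <- apply(lB, 1, max)
  B <- exp(lB - mshift)
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- piv * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- as.numeric(alpha[t - 1, ] %*% A) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(1, Tn, K)
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      beta[t, ] <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  if (Tn > 1) {
    for (t in 1:(Tn - 1)) {
      x <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cvec[t + 1]
      xi <- xi + x / sum(x)
    }
  }
  list(logZ = sum(log(cvec)) + sum(mshift), gamma = gamma, xi = xi)
}

kl_dirichlet <- function(a, b) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(b)) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

lmvgamma2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)

# KL( NW(m,beta,W,nu) || NW(m0,beta0,W0,nu0) ) for d = 2
kl_normal_wishart <- function(m, beta, W, nu, hyper) {
  d <- 2
  elogdet <- sum(digamma((nu + 1 - (1:d)) / 2)) + d * log(2) +
    determinant(W)$modulus[1]
  dm <- m - hyper$m0
  kl_mu <- 0.5 * (d * log(beta / hyper$beta0) - d + d * hyper$beta0 / beta +
                    hyper$beta0 * nu * as.numeric(t(dm) %*% W %*% dm))
  logB <- function(W, nu) {
    -(nu / 2) * determinant(W)$modulus[1] - (nu * d / 2) * log(2) -
      lmvgamma2(nu / 2)
  }
  kl_w <- logB(W, nu) - logB(hyper$W0, hyper$nu0) +
    ((nu - hyper$nu0) / 2) * elogdet +
    (nu / 2) * (sum(diag(hyper$W0inv %*% W)) - d)
  kl_mu + kl_w
}

vb_kl <- function(post, hyper, K) {
  kl <- kl_dirichlet(post$a_pi, rep(hyper$alpha0, K))
  for (j in seq_len(K)) {
    kl <- kl + kl_dirichlet(post$a_A[j, ], rep(hyper$alpha0, K))
  }
  for (k in seq_len(K)) {
    kl <- kl + kl_normal_wishart(post$m[k, ], post$beta[k],
                                 post$W[, , k], post$nu[k], hyper)
  }
  kl
}

posterior_mean_hmm <- function(post, K) {
  prior <- post$a_pi / sum(post$a_pi)
  transition <- post$a_A / rowSums(post$a_A)
  covs <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) {
    df <- post$nu[k] - 2 - 1
    covs[, , k] <- solve(post$W[, , k]) / max(df, post$nu[k] * 0.1)
  }
  eye_hmm(prior, transition, post$m, covs)
}

#' Select the ROI count by marginal log-likelihood
#'
#' Fits [fit_vbhmm()] for each K in `K_range` and returns the model with
#' the highest ELBO; exact ties go to the smaller K.
#'
#' @inheritParams fit_vbhmm
#' @param K_range candidate ROI counts (default 1:5).
#' @return The selected [eye_hmm()].
#' @export
select_hmm <- function(fixations, K_range = 1:5, hyper = vb_hyper(),
                       n_restarts = 5, seed = NULL, max_iter = 200,
                       tol = 1e-5) {
  if (length(K_range) == 0) abort("K_range must be non-empty")
  best <- NULL
  for (K in sort(K_range)) {
    fit <- fit_vbhmm(fixations, K, hyper, n_restarts,
                     seed = child_seed(seed, K) %||% seed,
                     max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }
  best
}
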