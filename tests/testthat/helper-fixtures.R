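# shared fixture builders (all generated in code; nothing on disk)

# simple K-state model with diagonal covariances
toy_hmm <- function(prior, transition, means, sds) {
  K <- length(prior)
  covs <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) covs[, , k] <- diag(sds[k]^2, 2)
  eye_hmm(prior, transition, means, covs)
}

# brute-force HMM log-likelihood by enumerating all K^T state paths
enumerate_loglik <- function(hmm, xy) {
  K <- hmm$K
  Tn <- nrow(xy)
  lp <- sapply(seq_len(K), function(k) {
    gazerp:::dmvnorm2_log(xy, hmm$means[k, ], hmm$covs[, , k])
  })
  lp <- matrix(lp, nrow = Tn)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  tot <- apply(paths, 1, function(s) {
    v <- log(hmm$prior[s[1]]) + lp[1, s[1]]
    if (Tn > 1) {
      for (t in 2:Tn) v <- v + log(hmm$transition[s[t - 1], s[t]]) + lp[t, s[t]]
    }
    v
  })
  m <- max(tot)
  m + log(sum(exp(tot - m)))
}

# quiet noise-only effect spec
null_effect_spec <- function(n_channels = 61, noise_sd = 2) {
  effect_spec(
    race_effect = list(amplitude = 0, window = c(200, 400)),
    mask_effect = list(amplitude = 0, window = c(100, 300)),
    identity_effect = list(amplitude = 0, window = c(150, 500)),
    noise_sd = noise_sd, n_channels = n_channels
  )
}

# a balanced trial-label table covering the 4 cells and 4 identities/race
balanced_labels <- function(per_cell = 24) {
  tidyr::crossing(race = c("Asian", "White"), mask = c("masked", "unmasked")) |>
    purrr::pmap_dfr(function(race, mask) {
      tibble::tibble(
        race = race, mask = mask,
        identity = paste0(substr(race, 1, 1), rep(1:4, length.out = per_cell)),
        correct = TRUE
      )
    })
}

# least-squares oracle for a 2x2 within design: each effect F from an OLS
# intercept test on the participant contrast scores
ols_rm_oracle <- function(wide) {
  contrasts <- list(
    mask = ((wide$Asian.unmasked + wide$White.unmasked) -
              (wide$Asian.masked + wide$White.masked)) / 2,
    race = ((wide$Asian.masked + wide$Asian.unmasked) -
              (wide$White.masked + wide$White.unmasked)) / 2,
    `mask:race` = (wide$Asian.unmasked - wide$Asian.masked) -
      (wide$White.unmasked - wide$White.masked)
  )
  purrr::imap_dfr(contrasts, function(cv, nm) {
    fit <- lm(cv ~ 1)
    s <- summary(fit)$coefficients
    tibble::tibble(effect = nm, statistic = s[1, "t value"]^2,
                   p = s[1, "Pr(>|t|)"])
  })
}

random_scores <- function(n, seed) {
  set.seed(seed)
  tidyr::crossing(participant = seq_len(n),
                  race = c("Asian", "White"),
                  mask = c("masked", "unmasked")) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
}

# adjusted Rand index for clustering recovery checks
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
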