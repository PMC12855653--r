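test_that("forward log-likelihood matches closed forms and the path oracle", {
  # K = 1: equals the sum of Gaussian log-densities
  h1 <- toy_hmm(1, matrix(1), matrix(c(100, 200), 1), 40)
  set.seed(1)
  xy <- cbind(rnorm(30, 100, 40), rnorm(30, 200, 40))
  direct <- sum(gazerp:::dmvnorm2_log(xy, c(100, 200), diag(1600, 2)))
  expect_equal(hmm_loglik(h1, data.frame(x = xy[, 1], y = xy[, 2])), direct,
               tolerance = 1e-10)

  # path enumeration for K <= 3, T <= 6
  set.seed(7)
  for (K in 1:3) {
    for (Tn in c(2, 4, 6)) {
      A <- matrix(rgamma(K * K, 1), K)
      A <- A / rowSums(A)
      pr <- rgamma(K, 1)
      h <- toy_hmm(pr / sum(pr), A,
                   matrix(runif(2 * K, 0, 500), K), runif(K, 20, 80))
      xy <- cbind(runif(Tn, 0, 500), runif(Tn, 0, 500))
      expect_equal(
        hmm_loglik(h, data.frame(x = xy[, 1], y = xy[, 2])),
        enumerate_loglik(h, xy),
        tolerance = 1e-8
      )
    }
  }
})

test_that("duplicating the sequence list doubles the total log-likelihood", {
  h <- archetype_hmm("eyes")
  fx <- simulate_fixations(h, 5, c(5, 8), seed = 3)
  fx2 <- dplyr::bind_rows(fx, dplyr::mutate(fx, trial = trial + 100))
  expect_equal(hmm_loglik(h, fx2), 2 * hmm_loglik(h, fx), tolerance = 1e-10)
  # and the per-sequence mean is unchanged
  expect_equal(hmm_loglik(h, fx2, "per-sequence-mean"),
               hmm_loglik(h, fx, "per-sequence-mean"), tolerance = 1e-10)
})

test_that("loglik rejects empty input and non-finite coordinates", {
  h <- archetype_hmm("eyes")
  expect_error(hmm_loglik(h, data.frame(x = numeric(0), y = numeric(0))[0, ]))
  expect_error(hmm_loglik(h, data.frame(x = c(1, NA), y = c(1, 2))), "finite")
})

test_that("VB fit recovers planted ROIs and keeps the bound monotone", {
  truth <- toy_hmm(c(0.5, 0.5), rbind(c(0.7, 0.3), c(0.3, 0.7)),
                   rbind(c(800, 400), c(1100, 550)), c(50, 50))
  fx <- simulate_fixations(truth, 25, c(8, 8), seed = 13)
  fit <- fit_vbhmm(fx, K = 2, seed = 17)
  # match labels by nearest true mean
  perm <- apply(fit$means, 1, function(m) {
    which.min(colSums((t(truth$means) - m)^2))
  })
  expect_setequal(perm, 1:2)
  for (k in 1:2) {
    expect_lt(sqrt(sum((fit$means[k, ] - truth$means[perm[k], ])^2)), 20)
  }
  trace <- attr(fit, "elbo_trace")
  expect_true(all(diff(trace) > -1e-6 * abs(trace[-length(trace)])))
  # outputs are stochastic vectors
  expect_equal(sum(fit$prior), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$transition), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("K = 1 posterior mean tracks the sample mean under a weak prior", {
  set.seed(5)
  fx <- data.frame(x = rnorm(300, 700, 60), y = rnorm(300, 450, 60))
  fit <- fit_vbhmm(fx, K = 1, seed = 1)
  expect_lt(abs(fit$means[1, 1] - mean(fx$x)), 2)
  expect_lt(abs(fit$means[1, 2] - mean(fx$y)), 2)
})

test_that("degenerate (constant) data warns but does not crash", {
  fx <- data.frame(x = rep(500, 20), y = rep(300, 20))
  expect_warning(fit <- fit_vbhmm(fx, K = 2, seed = 1, n_restarts = 1),
                 "identical")
  expect_s3_class(fit, "eye_hmm")
})

test_that("model selection picks the planted K and breaks ties low", {
  # single tight cluster -> K = 1
  set.seed(2)
  fx1 <- data.frame(x = rnorm(150, 900, 30), y = rnorm(150, 500, 30))
  expect_equal(select_hmm(fx1, 1:3, seed = 4, n_restarts = 2)$K, 1)

  # well-separated 2-ROI data -> K = 2 in >= 90% of seeded replicates
  truth <- toy_hmm(c(0.5, 0.5), rbind(c(0.6, 0.4), c(0.4, 0.6)),
                   rbind(c(700, 400), c(1200, 650)), c(45, 45))
  ks <- vapply(1:20, function(i) {
    fx <- simulate_fixations(truth, 20, c(8, 8), seed = 300 + i)
    select_hmm(fx, 1:3, seed = 400 + i, n_restarts = 2)$K
  }, 0L)
  expect_gte(mean(ks == 2), 0.9)

  # singleton range returns that K regardless of data
  expect_equal(select_hmm(fx1, K_range = 3, seed = 6, n_restarts = 1)$K, 3)
  expect_error(select_hmm(fx1, K_range = integer(0)), "non-empty")
})

test_that("clustering recovers planted archetype groups exactly", {
  set.seed(31)
  mk <- function(type) {
    h <- archetype_hmm(type)
    h$means <- h$means + matrix(rnorm(length(h$means), 0, 15), ncol = 2)
    h
  }
  models <- c(lapply(1:10, function(i) mk("eyes")),
              lapply(1:10, function(i) mk("nose")))
  reps <- cluster_hmms(models, 2, n_virtual = 20, tau = 10, seed = 11)
  truthlab <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(reps$assignment$cluster, truthlab), 1)
  # cluster 1 is the eyes-focused (higher on screen) pattern
  expect_lt(mean(reps$models[[1]]$means[, 2]),
            mean(reps$models[[2]]$means[, 2]))
  # determinism
  reps_b <- cluster_hmms(models, 2, n_virtual = 20, tau = 10, seed = 11)
  expect_identical(reps$assignment, reps_b$assignment)
})

test_that("clustering edge cases behave", {
  models <- lapply(1:4, function(i) archetype_hmm(c("eyes", "nose")[1 + i %% 2]))
  one <- cluster_hmms(models, 1, n_virtual = 10, tau = 6, seed = 2)
  expect_true(all(one$assignment$cluster == 1))
  expect_error(cluster_hmms(models[1:2], 3, seed = 1), "3 clusters")
  # duplicating the model list leaves representatives essentially unchanged
  r1 <- cluster_hmms(models, 2, n_virtual = 15, tau = 8, seed = 5)
  r2 <- cluster_hmms(c(models, models), 2, n_virtual = 15, tau = 8, seed = 5)
  for (j in 1:2) {
    expect_lt(max(abs(sort(r1$models[[j]]$means[, 2]) -
                        sort(r2$models[[j]]$means[, 2]))), 30)
  }
})

test_that("A-B scale follows the printed formula exactly", {
  expect_equal(ab_scale(-50, -50), 0)
  expect_equal(ab_scale(-100, -300), 0.5)
  expect_equal(ab_scale(-300, -100), -0.5)
  # antisymmetry and boundedness for negative log-likelihoods
  set.seed(8)
  for (i in 1:50) {
    a <- -rexp(1, 1 / 200)
    b <- -rexp(1, 1 / 200)
    expect_equal(ab_scale(a, b), -ab_scale(b, a))
    v <- ab_scale(a, b)
    expect_gt(v, -1)
    expect_lt(v, 1)
  }
  expect_error(ab_scale(0, 0), "undefined")
})

test_that("entropy terms match closed forms and respond to sharpening", {
  # deterministic cycle: zero transition entropy
  h_cyc <- toy_hmm(c(1, 0), rbind(c(0, 1), c(1, 0)),
                   rbind(c(0, 0), c(100, 100)), c(10, 10))
  e <- hmm_entropy(h_cyc)
  expect_equal(e$value[e$term == "transition"], 0)

  # uniform 2-state chain: log 2 per step
  h_unif <- toy_hmm(c(0.5, 0.5), matrix(0.5, 2, 2),
                    rbind(c(0, 0), c(100, 100)), c(10, 10))
  e2 <- hmm_entropy(h_unif)
  expect_equal(e2$value[e2$term == "transition"], log(2), tolerance = 1e-12)

  # row-wise sharpening never increases the transition contribution
  set.seed(12)
  for (i in 1:100) {
    K <- sample(2:4, 1)
    A <- matrix(rgamma(K * K, 1), K)
    A <- A / rowSums(A)
    B <- A^runif(1, 1, 4)
    B <- B / rowSums(B)
    mk <- function(M) {
      toy_hmm(rep(1 / K, K), M, matrix(seq_len(K * 2) * 100, K), rep(10, K))
    }
    ea <- hmm_entropy(mk(A))
    eb <- hmm_entropy(mk(B))
    expect_lte(eb$value[eb$term == "transition"],
               ea$value[ea$term == "transition"] + 1e-10)
  }
})

test_that("non-ergodic chains fall back to prior weighting with a warning", {
  h <- toy_hmm(c(0.3, 0.7), diag(2), rbind(c(0, 0), c(100, 100)), c(10, 20))
  expect_warning(e <- hmm_entropy(h), "stationary")
  expect_equal(e$value[e$term == "transition"], 0)
})

test_that("scanpath scoring returns the full participant-condition table", {
  eyes <- archetype_hmm("eyes")
  nose <- archetype_hmm("nose")
  fx <- dplyr::bind_rows(
    dplyr::mutate(simulate_fixations(eyes, 6, c(6, 8), seed = 1),
                  participant = 1, race = "Asian", mask = "masked"),
    dplyr::mutate(simulate_fixations(nose, 6, c(6, 8), seed = 2),
                  participant = 1, race = "Asian", mask = "unmasked")
  )
  reps <- list(models = list(eyes, nose))
  sc <- score_scanpaths(fx, reps)
  expect_equal(nrow(sc), 2)
  # the eyes-sampled condition scores positive, the nose-sampled negative
  expect_gt(sc$ab_scale[sc$mask == "masked"], 0)
  expect_lt(sc$ab_scale[sc$mask == "unmasked"], 0)
})
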