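# small noise-only participant reused across blocks (16 channels for speed)
local_epochs <- function(per_cell = 36, n_channels = 16, noise_sd = 2,
                         seed = 5, spec = NULL) {
  labels <- balanced_labels(per_cell)
  simulate_epochs(spec %||% null_effect_spec(n_channels, noise_sd),
                  labels, seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("surrogate averaging reproduces the printed counts", {
  ep <- filter_epochs(local_epochs(36), mask == "masked")
  surr <- average_to_surrogates(ep, "race", n_per_class = 18, seed = 1)
  expect_equal(dim(surr$data)[1], 36)
  expect_equal(as.vector(table(surr$class)), c(18, 18))

  cell <- filter_epochs(ep, race == "Asian")
  si <- average_to_surrogates(cell, "identity", n_per_class = 6, seed = 2)
  expect_equal(dim(si$data)[1], 24)
  expect_equal(as.vector(table(si$class)), rep(6, 4))

  # insufficient trials error names the class
  small <- filter_epochs(ep, race == "Asian")
  expect_error(average_to_surrogates(small, "race", n_per_class = 100),
               "Asian")
})

test_that("all-identical trials give surrogates equal to the trial", {
  d <- array(rep(seq_len(301), each = 4), dim = c(4, 301, 12))
  ep <- eeg_epochs(d, seq(-200, 1000, by = 4), 250, montage_61()[1:4],
                   tibble::tibble(race = rep(c("Asian", "White"), 6)))
  surr <- average_to_surrogates(ep, "race", n_per_class = 3, seed = 3)
  for (i in seq_len(dim(surr$data)[1])) {
    expect_equal(surr$data[i, , ], d[, , 1])
  }
})

test_that("folds are class-balanced with the printed sizes", {
  ep <- filter_epochs(local_epochs(36), mask == "masked")
  surr <- average_to_surrogates(ep, "race", 18, seed = 4)
  folds <- make_folds(surr, 3, seed = 5)
  expect_equal(as.vector(table(folds)), c(12, 12, 12))
  expect_true(all(table(folds, surr$class) == 6))

  cell <- filter_epochs(ep, race == "Asian")
  si <- average_to_surrogates(cell, "identity", 6, seed = 6)
  fi <- make_folds(si, 3, seed = 7)
  expect_equal(as.vector(table(fi)), c(8, 8, 8))
  expect_true(all(table(fi, si$class) == 2))

  # determinism and divisibility error
  expect_identical(folds, make_folds(surr, 3, seed = 5))
  expect_error(make_folds(surr, 5, seed = 1), "not divisible")
})

test_that("window features follow the half-open 100 ms / 8 ms grid", {
  ep <- local_epochs(4, n_channels = 8)
  surr <- average_to_surrogates(filter_epochs(ep, mask == "masked"),
                                "race", 2, seed = 1)
  wf <- window_features(surr)
  expect_equal(wf$window_starts[1:3], c(0, 8, 16))
  expect_equal(diff(wf$window_starts), rep(8, length(wf$window_starts) - 1))
  expect_lte(max(wf$window_starts) + 100, 1000 + 8)
  expect_equal(dim(wf$features)[2], 8)  # one feature per channel

  # constant signal -> identical features at every window
  surr$data[] <- 2.5
  wfc <- window_features(surr)
  expect_true(all(abs(wfc$features - 2.5) < 1e-12))
})

test_that("decoding separates a strong planted signal and not noise", {
  spec <- effect_spec(
    race_effect = list(amplitude = 5, window = c(200, 400)),
    mask_effect = list(amplitude = 0, window = c(100, 300)),
    identity_effect = list(amplitude = 0, window = c(150, 500)),
    noise_sd = 1, n_channels = 16
  )
  ep <- filter_epochs(local_epochs(40, spec = spec, seed = 8),
                      mask == "masked")
  dr <- decode_timecourse(ep, "race", n_iter = 2, seed = 9)
  m <- rowMeans(dr$accuracy)
  inside <- dr$times >= 220 & dr$times <= 300
  outside <- dr$times >= 600
  expect_gt(mean(m[inside]), 0.9)
  expect_lt(abs(mean(m[outside]) - 0.5), 0.1)
  expect_true(all(dr$accuracy >= 0 & dr$accuracy <= 1))

  # nearest-centroid oracle agrees inside the effect window
  surr <- average_to_surrogates(ep, "race", 18, seed = 10)
  wf <- window_features(surr)
  w <- which.min(abs(wf$window_starts - 250))
  X <- wf$features[, , w]
  nc_acc <- mean(vapply(seq_len(nrow(X)), function(i) {
    mu_a <- colMeans(X[-i, , drop = FALSE][surr$class[-i] == "Asian", ])
    mu_w <- colMeans(X[-i, , drop = FALSE][surr$class[-i] == "White", ])
    pred <- if (sum((X[i, ] - mu_a)^2) < sum((X[i, ] - mu_w)^2)) "Asian" else "White"
    pred == as.character(surr$class[i])
  }, TRUE))
  expect_lt(abs(mean(m[w]) - nc_acc), 0.05)
})

test_that("label shuffling drives accuracy to chance (no leakage)", {
  ep <- filter_epochs(local_epochs(36, n_channels = 16), mask == "masked")
  dr <- decode_timecourse(ep, "race", n_iter = 6, seed = 11,
                          shuffle_labels = TRUE)
  im <- colMeans(dr$accuracy)
  se <- sd(im) / sqrt(length(im))
  expect_lt(abs(mean(im) - 0.5), 3 * se + 0.02)
})

test_that("decoding is deterministic given the seed", {
  ep <- filter_epochs(local_epochs(8, n_channels = 6), mask == "masked")
  d1 <- decode_timecourse(ep, "race", n_iter = 2, seed = 21, n_per_class = 3)
  d2 <- decode_timecourse(ep, "race", n_iter = 2, seed = 21, n_per_class = 3)
  expect_identical(d1$accuracy, d2$accuracy)
})

test_that("peak latency picks the maximum with early tie-breaking", {
  r <- structure(list(times = c(0, 8, 16, 24),
                      accuracy = cbind(c(0.5, 0.9, 0.7, 0.9)),
                      chance = 0.5, scheme = "race"),
                 class = "decoding_result")
  expect_equal(peak_latency(r), 8)
  r$accuracy <- cbind(rep(0.5, 4))
  expect_equal(peak_latency(r), 0)
  r$accuracy <- cbind(c(0.5, 0.6, 0.5, 0.9))
  expect_equal(peak_latency(r), 24)
})
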