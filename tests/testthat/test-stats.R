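test_that("behavior summaries compute cell accuracy, RT and bias", {
  trials <- dplyr::bind_rows(
    tibble::tibble(participant = 1, race = "Asian", mask = "masked",
                   correct = c(TRUE, TRUE, FALSE, TRUE),
                   own_race_response = NA, rt = c(500, 700, 900, 1600)),
    tibble::tibble(participant = 1, race = "morphed", mask = "masked",
                   correct = NA,
                   own_race_response = rep(c(TRUE, FALSE), c(12, 4)),
                   rt = 800)
  )
  s <- summarize_behavior(trials)
  expect_equal(s$cells$accuracy, 0.75)
  # the 1600 ms correct response is past the deadline -> excluded from RT
  expect_equal(s$cells$rt, mean(c(500, 700)))
  expect_equal(s$bias$bias, 0.75)   # 12 of 16 own-race
})

test_that("2x2 repeated-measures ANOVA matches the OLS oracle", {
  # known toy table
  sc <- random_scores(6, seed = 1)
  res <- rm_anova_2x2(sc)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(sc, cell = paste(race, mask, sep = ".")),
    id_cols = participant, names_from = cell, values_from = value)
  orc <- ols_rm_oracle(wide)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-6)
  expect_equal(res$p, orc$p, tolerance = 1e-6)

  # property: 100 random small tables
  for (i in 1:100) {
    sc <- random_scores(sample(4:9, 1), seed = 100 + i)
    res <- rm_anova_2x2(sc)
    wide <- tidyr::pivot_wider(
      dplyr::mutate(sc, cell = paste(race, mask, sep = ".")),
      id_cols = participant, names_from = cell, values_from = value)
    orc <- ols_rm_oracle(wide)
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-6)
  }
})

test_that("F equals the squared paired t for 2-level factors", {
  sc <- random_scores(8, seed = 7)
  res <- rm_anova_2x2(sc)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(sc, cell = paste(race, mask, sep = ".")),
    id_cols = participant, names_from = cell, values_from = value)
  tt <- paired_t_test((wide$Asian.unmasked + wide$White.unmasked) / 2,
                      (wide$Asian.masked + wide$White.masked) / 2)
  expect_equal(res$statistic[res$effect == "mask"], tt$statistic^2,
               tolerance = 1e-9)
})

test_that("degenerate zero-variance contrasts error explicitly", {
  sc <- random_scores(5, seed = 3) |> dplyr::mutate(value = 1)
  expect_error(rm_anova_2x2(sc), "zero variance")
  expect_error(rm_anova_2x2(random_scores(2, seed = 1)), "3 complete")
})

test_that("mixed 2x2x2 ANOVA matches the multivariate GLM oracle", {
  skip_if_not_installed("car")
  set.seed(11)
  n <- 12
  sc <- random_scores(n, seed = 12)
  groups <- tibble::tibble(participant = 1:n,
                           group = rep(c("eyes", "nose"), each = n / 2))
  res <- mixed_anova_2x2x2(sc, groups)

  wide <- tidyr::pivot_wider(
    dplyr::mutate(sc, cell = paste(race, mask, sep = ".")),
    id_cols = participant, names_from = cell, values_from = value) |>
    dplyr::inner_join(groups, by = "participant")
  Y <- as.matrix(wide[, c("Asian.masked", "Asian.unmasked",
                          "White.masked", "White.unmasked")])
  g <- factor(wide$group)
  fit <- lm(Y ~ g, contrasts = list(g = "contr.sum"))
  idata <- data.frame(
    race = factor(c("Asian", "Asian", "White", "White")),
    mask = factor(c("masked", "unmasked", "masked", "unmasked"))
  )
  av <- suppressWarnings(
    car::Anova(fit, idata = idata, idesign = ~ race * mask, type = 3)
  )
  s <- summary(av, multivariate = FALSE)$univariate.tests
  pick <- function(nm) unname(s[nm, "F value"])
  expect_equal(res$statistic[res$effect == "group"], pick("g"),
               tolerance = 1e-6)
  expect_equal(res$statistic[res$effect == "mask"], pick("mask"),
               tolerance = 1e-6)
  expect_equal(res$statistic[res$effect == "race"], pick("race"),
               tolerance = 1e-6)
  expect_equal(res$statistic[res$effect == "mask:group"], pick("g:mask"),
               tolerance = 1e-6)
  expect_equal(res$statistic[res$effect == "mask:race"], pick("race:mask"),
               tolerance = 1e-6)
  expect_equal(res$statistic[res$effect == "mask:race:group"],
               pick("g:race:mask"), tolerance = 1e-6)

  # identical groups: between effect ~ 0
  sc2 <- dplyr::bind_rows(
    dplyr::mutate(random_scores(6, seed = 5), participant = participant),
    dplyr::mutate(random_scores(6, seed = 5), participant = participant + 6)
  )
  res2 <- mixed_anova_2x2x2(sc2, tibble::tibble(
    participant = 1:12, group = rep(c("eyes", "nose"), each = 6)))
  expect_lt(res2$statistic[res2$effect == "group"], 1e-16)
})

test_that("paired t, correlation and Fisher z follow closed forms", {
  x <- c(5, 7, 9, 4, 8)
  y <- c(4, 6, 10, 2, 7)
  res <- paired_t_test(x, y)
  d <- x - y
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$d, mean(d) / sd(d), tolerance = 1e-12)
  # x = y -> t = 0, p = 1
  same <- paired_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # antisymmetry
  expect_equal(paired_t_test(x, y)$statistic,
               -paired_t_test(y, x)$statistic)
  expect_error(paired_t_test(x, x + 1), "zero variance")

  # Fisher r-to-z comparison
  z <- fisher_z_compare(0.5, 50, -0.5, 50)
  expect_equal(z$statistic,
               (atanh(0.5) - atanh(-0.5)) / sqrt(2 / 47), tolerance = 1e-9)
  expect_equal(fisher_z_compare(0.3, 30, 0.3, 30)$p, 0.5)
  expect_equal(fisher_z_compare(0.2, 30, 0.6, 40)$statistic,
               -fisher_z_compare(0.6, 40, 0.2, 30)$statistic)
  expect_error(fisher_z_compare(1, 30, 0.5, 30), "< 1")
})

test_that("mask effects are unmasked minus masked, per race or pooled", {
  m <- tidyr::crossing(participant = 1:3, race = c("Asian", "White"),
                       mask = c("masked", "unmasked")) |>
    dplyr::mutate(value = ifelse(mask == "unmasked", 2, 0.5))
  me <- compute_mask_effects(m)
  expect_equal(nrow(me), 6)    # participants x races
  expect_true(all(me$mask_effect == 1.5))
  # equality -> 0
  m0 <- dplyr::mutate(m, value = 3)
  expect_true(all(compute_mask_effects(m0)$mask_effect == 0))
  # pooled when race is absent
  mp <- dplyr::distinct(m, participant, mask) |> dplyr::mutate(value = ifelse(mask == "unmasked", 1, 4))
  expect_equal(compute_mask_effects(mp)$mask_effect, rep(-3, 3))
  # missing cell dropped with a message
  expect_message(
    out <- compute_mask_effects(m[-1, ]),
    "dropping 1"
  )
  expect_equal(nrow(out), 5)
})

test_that("planted morph bias is recovered within 2 SE", {
  cfg <- cohort_config(n_participants = 20, morph_trials = 40,
                       morph_bias = 0.62, seed = 9)
  b <- simulate_behavior(cfg)
  s <- summarize_behavior(b)
  est <- mean(s$bias$bias)
  se <- sd(s$bias$bias) / sqrt(nrow(s$bias))
  expect_lt(abs(est - 0.62), 2 * se + 0.02)
})

test_that("an injected eye-brain correlation is detected", {
  # entropy mask effect linearly coupled to the N170 mask effect + noise
  detected <- vapply(1:10, function(i) {
    set.seed(500 + i)
    n <- 49
    ent <- rnorm(n, -0.4, 0.3)
    n170 <- -0.8 * ent + rnorm(n, 0, 0.35)
    pearson_cor(ent, n170)$p < 0.05
  }, TRUE)
  expect_gte(mean(detected), 0.8)
})
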