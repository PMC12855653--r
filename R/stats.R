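#' Summarize behavioral categorization trials
#'
#' Per participant and race x mask cell: categorization accuracy
#' (correct / total monoracial trials), mean RT over correct in-deadline
#' trials, and (per mask condition) the own-race categorization bias --
#' the proportion of 50/50 biracial morphed faces categorized as own-race.
#'
#' @param trials tidy trial table with columns `participant`, `race`
#'   (`"Asian"`, `"White"` or `"morphed"`), `mask`, `correct` (logical;
#'   monoracial trials), `own_race_response` (logical; morph trials),
#'   `rt` (ms).
#' @param deadline response deadline (ms); later responses are excluded
#'   from the RT mean.
#' @return A list of tibbles: `cells` (accuracy and RT per race x mask)
#'   and `bias` (per mask).
#' @export
summarize_behavior <- function(trials, deadline = 1500) {
  trials <- tibble::as_tibble(trials)
  mono <- dplyr::filter(trials, .data$race %in% c("Asian", "White"))
  cells <- mono |>
    dplyr::group_by(.data$participant, .data$race, .data$mask) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      rt = mean(.data$rt[.data$correct & .data$rt <= deadline]),
      n = dplyr::n(), .groups = "drop"
    )
  bias <- trials |>
    dplyr::filter(.data$race == "morphed") |>
    dplyr::group_by(.data$participant, .data$mask) |>
    dplyr::summarise(bias = mean(.data$own_race_response),
                     n = dplyr::n(), .groups = "drop")
  list(cells = cells, bias = bias)
}

# per-participant cell means in fixed 2x2 order, complete cases only
cells_2x2 <- function(scores, value) {
  wide <- scores |>
    dplyr::mutate(cell = paste(.data$race, .data$mask, sep = ".")) |>
    tidyr::pivot_wider(id_cols = "participant", names_from = "cell",
                       values_from = dplyr::all_of(value))
  need <- c("Asian.masked", "Asian.unmasked", "White.masked", "White.unmasked")
  missing <- setdiff(need, names(wide))
  if (length(missing)) abort(paste("missing cells:", paste(missing, collapse = ", ")))
  wide <- wide[complete.cases(wide[, need]), c("participant", need)]
  wide
}

paired_f <- function(contrast, effect) {
  n <- length(contrast)
  if (sd(contrast) < 1e-12) {
    abort(sprintf("zero variance in the %s contrast; F undefined", effect))
  }
  tval <- mean(contrast) / (sd(contrast) / sqrt(n))
  Fval <- tval^2
  tibble::tibble(
    effect = effect, statistic = Fval, df1 = 1, df2 = n - 1,
    p = pt(abs(tval), n - 1, lower.tail = FALSE) * 2,
    pes = Fval / (Fval + n - 1)
  )
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject mask x race ANOVA on per-participant cell scores. With
#' two levels per factor each effect is exact: its F equals the square of
#' the paired t on the corresponding within-participant contrast, so no
#' sphericity correction is needed. Partial eta squared is reported.
#'
#' @param scores tidy table with columns `participant`, `race`
#'   (Asian/White), `mask` (masked/unmasked) and the value column.
#' @param value name of the value column (default `"value"`).
#' @return A tibble with one row per effect (`mask`, `race`,
#'   `mask:race`): `statistic` (F), `df1`, `df2`, `p`, `pes`.
#' @export
rm_anova_2x2 <- function(scores, value = "value") {
  wide <- cells_2x2(scores, value)
  if (nrow(wide) < 3) abort("need at least 3 complete participants")
  am <- wide$Asian.masked; au <- wide$Asian.unmasked
  wm <- wide$White.masked; wu <- wide$White.unmasked
  dplyr::bind_rows(
    paired_f(((au + wu) - (am + wm)) / 2, "mask"),
    paired_f(((am + au) - (wm + wu)) / 2, "race"),
    paired_f((au - am) - (wu - wm), "mask:race")
  )
}

#' Mixed 2 x 2 x 2 ANOVA (mask x race x typical pattern)
#'
#' Within factors mask and race; between factor the participant's typical
#' scanpath pattern (eyes- vs nose-focused). Implemented through the
#' contrast decomposition: each within effect (and its interaction with
#' the group) is a one-degree-of-freedom test on the corresponding
#' within-participant contrast score with unweighted group means, and the
#' between main effect is a one-way ANOVA on the participant means.
#'
#' @inheritParams rm_anova_2x2
#' @param groups tibble with `participant` and `group` (2 levels).
#' @return A tibble with one row per effect.
#' @export
mixed_anova_2x2x2 <- function(scores, groups, value = "value") {
  wide <- dplyr::inner_join(cells_2x2(scores, value),
                            tibble::as_tibble(groups), by = "participant")
  g <- factor(wide$group)
  if (nlevels(g) != 2) abort("group factor must have exactly 2 levels")
  if (any(table(g) < 2)) abort("each group needs at least 2 participants")
  am <- wide$Asian.masked; au <- wide$Asian.unmasked
  wm <- wide$White.masked; wu <- wide$White.unmasked
  subj_mean <- (am + au + wm + wu) / 4
  contrasts <- list(
    mask = ((au + wu) - (am + wm)) / 2,
    race = ((am + au) - (wm + wu)) / 2,
    `mask:race` = (au - am) - (wu - wm)
  )
  between_f <- function(yv, effect) {
    fit <- lm(yv ~ g, contrasts = list(g = "contr.sum"))
    s <- summary(fit)$coefficients
    ct <- unname(s[, "t value"])
    n <- length(yv)
    out <- tibble::tibble(
      effect = c(effect, paste0(effect, ":group")),
      statistic = ct^2, df1 = 1, df2 = n - 2,
      p = 2 * pt(abs(ct), n - 2, lower.tail = FALSE)
    )
    out$pes <- out$statistic / (out$statistic + n - 2)
    out
  }
  grp <- {
    fit <- lm(subj_mean ~ g, contrasts = list(g = "contr.sum"))
    a <- anova(fit)
    tibble::tibble(effect = "group", statistic = unname(a$`F value`[1]),
                   df1 = 1, df2 = a$Df[2], p = unname(a$`Pr(>F)`[1]),
                   pes = a$`Sum Sq`[1] / sum(a$`Sum Sq`))
  }
  within <- purrr::imap_dfr(contrasts, function(cv, nm) between_f(cv, nm))
  within$effect <- sub("mask:race:group", "mask:race:group", within$effect)
  dplyr::bind_rows(grp, within)
}

#' Paired t test with Cohen's d
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @param tails `"two"` or `"one"`.
#' @return A one-row tibble: `statistic` (t), `df`, `p`, `d`
#'   (mean difference / SD of differences).
#' @export
paired_t_test <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (sd(d) < 1e-14) {
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, df = length(d) - 1,
                            p = if (tails == "two") 1 else 0.5, d = 0))
    }
    abort("zero variance in paired differences; t undefined")
  }
  tt <- t.test(x, y, paired = TRUE,
               alternative = if (tails == "two") "two.sided" else "greater")
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = mean(d) / sd(d))
}

#' Pearson correlation
#'
#' @param x,y numeric vectors (n >= 4).
#' @return A one-row tibble: `r`, `df`, `statistic` (t), `p`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ct <- cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 statistic = unname(ct$statistic), p = ct$p.value)
}

#' Compare two correlations via Fisher's r-to-z
#'
#' Independent-samples comparison: `z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3))`, with a one-tailed p by default.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @param tails `"one"` (default) or `"two"`.
#' @return A one-row tibble: `statistic` (z), `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("|r| must be < 1")
  stopifnot(n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (tails == "one") pnorm(abs(z), lower.tail = FALSE) else
    2 * pnorm(abs(z), lower.tail = FALSE)
  tibble::tibble(statistic = z, p = p)
}

#' Mask-effect scores (unmasked minus masked)
#'
#' The within-participant mask effect on any measure: unmasked score minus
#' masked score, computed per race when `race` is present (e.g. the N170
#' per face race) or pooled otherwise (e.g. entropy, peak latency).
#' Participants missing either mask cell are dropped with a message.
#'
#' @param measures tidy table with columns `participant`, `mask`,
#'   optionally `race` and/or `measure`, and the value column.
#' @param value name of the value column.
#' @return A tibble: `participant`, (`race`,) (`measure`,) `mask_effect`.
#' @export
compute_mask_effects <- function(measures, value = "value") {
  keys <- intersect(c("participant", "race", "measure"), names(measures))
  wide <- tidyr::pivot_wider(tibble::as_tibble(measures),
                             id_cols = dplyr::all_of(keys),
                             names_from = "mask",
                             values_from = dplyr::all_of(value))
  if (!all(c("masked", "unmasked") %in% names(wide))) {
    abort("measures must contain both masked and unmasked cells")
  }
  dropped <- sum(!complete.cases(wide[, c("masked", "unmasked")]))
  if (dropped > 0) {
    rlang::inform(sprintf("dropping %d row(s) missing a mask cell", dropped))
  }
  wide |>
    dplyr::filter(!is.na(.data$masked), !is.na(.data$unmasked)) |>
    dplyr::mutate(mask_effect = .data$unmasked - .data$masked) |>
    dplyr::select(dplyr::all_of(keys), "mask_effect")
}
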