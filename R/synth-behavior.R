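#' Cohort configuration for the synthetic study
#'
#' Describes the 2 x 2 within-subject (race x mask) free-viewing cohort
#' the generator emulates: ~55 participants, a mixture of eyes- and
#' nose-focused scanpath archetypes, a mask-induced shift of gaze toward
#' the eyes with sharpened (more consistent, lower-entropy) transitions,
#' condition-dependent EEG effects and a behavioral categorization task
#' (32 monoracial + 16 biracial morphed faces per mask condition block,
#' 1500 ms response deadline).
#'
#' @param n_participants cohort size (default 55).
#' @param trials_per_cell fixation trials per race x mask cell (>= 2).
#' @param archetype_mix proportion of eyes-focused participants, in
#'   `[0, 1]`.
#' @param mask_shift upward ROI displacement (px) in masked conditions.
#' @param sharpen transition-sharpening exponent in masked conditions
#'   (> 1 lowers entropy).
#' @param accuracy named per-cell correct-response probabilities
#'   (`asian_masked` etc.), in `[0, 1]`.
#' @param rt_meanlog named per-race lognormal RT location (log-ms); Asian
#'   slower by default (other-race categorization advantage).
#' @param rt_sdlog lognormal RT scale.
#' @param morph_bias own-race response probability for morphed faces.
#' @param morph_trials morph trials per mask condition.
#' @param mono_trials monoracial trials per race x mask cell.
#' @param eeg_trials_per_cell EEG trials per race x mask cell.
#' @param effect_spec an [effect_spec()] for the EEG generator.
#' @param length_range fixations per trial, `(min, max)`.
#' @param frame screen size (px), origin top-left, y downward.
#' @param seed integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 55, trials_per_cell = 32,
                          archetype_mix = 0.5, mask_shift = 60,
                          sharpen = 2,
                          accuracy = c(asian_masked = 0.95,
                                       asian_unmasked = 0.93,
                                       white_masked = 0.89,
                                       white_unmasked = 0.93),
                          rt_meanlog = c(Asian = log(700), White = log(640)),
                          rt_sdlog = 0.25, morph_bias = 0.62,
                          morph_trials = 8, mono_trials = 8,
                          eeg_trials_per_cell = 24,
                          effect_spec = gazerp::effect_spec(),
                          length_range = c(5, 12),
                          frame = c(1920, 1080), seed = 1L) {
  stopifnot(trials_per_cell >= 2,
            archetype_mix >= 0, archetype_mix <= 1,
            all(accuracy >= 0 & accuracy <= 1),
            morph_bias >= 0, morph_bias <= 1)
  structure(
    list(n_participants = n_participants, trials_per_cell = trials_per_cell,
         archetype_mix = archetype_mix, mask_shift = mask_shift,
         sharpen = sharpen, accuracy = accuracy, rt_meanlog = rt_meanlog,
         rt_sdlog = rt_sdlog, morph_bias = morph_bias,
         morph_trials = morph_trials, mono_trials = mono_trials,
         eeg_trials_per_cell = eeg_trials_per_cell,
         effect_spec = effect_spec, length_range = length_range,
         frame = frame, seed = seed),
    class = "cohort_config"
  )
}

#' Simulate behavioral categorization trials
#'
#' Monoracial trials draw correctness from the per-cell accuracy; RTs are
#' lognormal truncated at the 1500 ms deadline; morphed-face trials draw
#' an own-race response from the bias probability.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (defaults to the config's).
#' @return A tibble: `participant`, `race`, `mask`, `trial`, `correct`,
#'   `own_race_response`, `rt`.
#' @export
simulate_behavior <- function(config, seed = NULL) {
  seed <- seed %||% child_seed(config$seed, "behavior")
  deadline <- 1500
  rlnorm_trunc <- function(n, meanlog, sdlog) {
    qlnorm(runif(n) * plnorm(deadline, meanlog, sdlog), meanlog, sdlog)
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(config$n_participants), function(p) {
      mono <- purrr::map_dfr(
        expand.grid(race = c("Asian", "White"),
                    mask = c("masked", "unmasked"),
                    stringsAsFactors = FALSE) |> purrr::transpose(),
        function(cell) {
          acc <- config$accuracy[[tolower(paste(cell$race, cell$mask, sep = "_"))]]
          tibble::tibble(
            participant = p, race = cell$race, mask = cell$mask,
            trial = seq_len(config$mono_trials),
            correct = runif(config$mono_trials) < acc,
            own_race_response = NA,
            rt = rlnorm_trunc(config$mono_trials,
                              config$rt_meanlog[[cell$race]], config$rt_sdlog)
          )
        })
      morph <- purrr::map_dfr(c("masked", "unmasked"), function(mk) {
        tibble::tibble(
          participant = p, race = "morphed", mask = mk,
          trial = seq_len(config$morph_trials),
          correct = NA,
          own_race_response = runif(config$morph_trials) < config$morph_bias,
          rt = rlnorm_trunc(config$morph_trials, mean(config$rt_meanlog),
                            config$rt_sdlog)
        )
      })
      dplyr::bind_rows(mono, morph)
    })
  })
}

# the participant-condition scanpath model implied by the config
condition_hmm <- function(config, archetype, mask) {
  archetype_hmm(
    archetype, frame = config$frame,
    mask_shift = if (mask == "masked") config$mask_shift else 0,
    sharpen = if (mask == "masked") config$sharpen else 1
  )
}

#' Generate a full synthetic cohort on disk
#'
#' Writes, under `dir`: one fixation CSV per participant x condition
#' (`fix_p<participant>_<race>_<mask>.csv`), one epochs container per
#' participant ([write_epochs()]), a behavior CSV, and a JSON manifest of
#' every ground-truth parameter (seeds, archetype assignment, condition
#' models). Byte-identical manifests for identical configs.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @param eeg whether to generate EEG epochs (the slowest part).
#' @return The manifest, invisibly.
#' @export
generate_cohort <- function(config, dir, eeg = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory %s", dir))
  conds <- expand.grid(race = c("Asian", "White"),
                       mask = c("masked", "unmasked"),
                       stringsAsFactors = FALSE)
  arch <- with_seed(child_seed(config$seed, "archetypes"), {
    ifelse(runif(config$n_participants) < config$archetype_mix,
           "eyes", "nose")
  })
  fix_files <- character(0)
  for (p in seq_len(config$n_participants)) {
    for (ci in seq_len(nrow(conds))) {
      hmm <- condition_hmm(config, arch[p], conds$mask[ci])
      fx <- simulate_fixations(
        hmm, config$trials_per_cell, config$length_range,
        seed = child_seed(config$seed, paste("fix", p, ci))
      )
      fx <- dplyr::mutate(fx, participant = p, race = conds$race[ci],
                          mask = conds$mask[ci], .before = 1)
      f <- file.path(dir, sprintf("fix_p%03d_%s_%s.csv", p,
                                  conds$race[ci], conds$mask[ci]))
      readr::write_csv(fx, f)
      fix_files <- c(fix_files, basename(f))
    }
  }
  epoch_files <- character(0)
  if (eeg) {
    for (p in seq_len(config$n_participants)) {
      labels <- purrr::map_dfr(seq_len(nrow(conds)), function(ci) {
        ids <- paste0(substr(conds$race[ci], 1, 1),
                      rep(1:4, length.out = config$eeg_trials_per_cell))
        tibble::tibble(race = conds$race[ci], mask = conds$mask[ci],
                       identity = ids, correct = TRUE)
      })
      ep <- simulate_epochs(config$effect_spec, labels,
                            seed = child_seed(config$seed, paste("eeg", p)))
      base <- file.path(dir, sprintf("epochs_p%03d", p))
      write_epochs(ep, base)
      epoch_files <- c(epoch_files, basename(base))
    }
  }
  behavior <- simulate_behavior(config)
  readr::write_csv(behavior, file.path(dir, "behavior.csv"))
  manifest <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    conditions = conds,
    trials_per_cell = config$trials_per_cell,
    coordinate_convention = "screen px, origin top-left, y downward",
    frame = config$frame,
    archetype = as.list(setNames(arch, sprintf("p%03d", seq_along(arch)))),
    mask_shift = config$mask_shift,
    sharpen = config$sharpen,
    accuracy = as.list(config$accuracy),
    morph_bias = config$morph_bias,
    fixation_files = fix_files,
    epoch_files = epoch_files,
    behavior_file = "behavior.csv"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort's fixation files into one tidy table
#'
#' @param dir cohort directory written by [generate_cohort()].
#' @return A tibble with all fixations (`participant`, `race`, `mask`,
#'   `trial`, `fix_index`, `x`, `y`, `duration`).
#' @export
read_cohort_fixations <- function(dir) {
  files <- list.files(dir, pattern = "^fix_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no fixation files under %s", dir))
  purrr::map_dfr(files, readr::read_csv, show_col_types = FALSE)
}
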