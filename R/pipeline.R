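#' Pipeline configuration
#'
#' Bundles a cohort source with stage toggles and per-stage seeds. The
#' configuration round-trips losslessly through JSON and every seed is
#' recorded in the output manifest.
#'
#' @param cohort a [cohort_config()] (the cohort is generated) or an
#'   existing cohort directory.
#' @param out_dir output directory for tables and the manifest.
#' @param stages character subset of
#'   `c("scanpath", "erp", "decoding", "stats")`.
#' @param seed master seed; per-stage seeds derive from it.
#' @param K_range ROI-count search range for model selection.
#' @param n_restarts VB restarts per fit.
#' @param n_iter decoding iterations.
#' @param n_perm cluster-test permutations.
#' @param n_virtual,tau virtual-sample settings for [cluster_hmms()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir,
                            stages = c("scanpath", "erp", "decoding", "stats"),
                            seed = 1L, K_range = 1:3, n_restarts = 2,
                            n_iter = 10, n_perm = 1000, n_virtual = 20,
                            tau = 10) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(cohort = cohort, out_dir = out_dir, stages = stages, seed = seed,
         K_range = K_range, n_restarts = n_restarts, n_iter = n_iter,
         n_perm = n_perm, n_virtual = n_virtual, tau = tau),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Generates (or ingests) a cohort, then runs the enabled stages in order:
#' scanpath HMM fitting + clustering + eyes-nose/entropy scoring; ERP
#' artifact rejection and component quantification; race decoding per mask
#' condition with vs-chance cluster tests; and the group-level behavioral
#' and mask-effect statistics. Each stage writes tidy CSVs under
#' `config$out_dir`; a `pipeline_manifest.json` records seeds and counts.
#' A stage that needs a disabled upstream stage fails fast, naming the
#' missing dependency.
#'
#' @param config a [pipeline_config()].
#' @return A named list of stage outputs, invisibly.
#' @export
run_pipeline <- function(config) {
  out <- list()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_dir <- if (inherits(config$cohort, "cohort_config")) {
    d <- file.path(config$out_dir, "cohort")
    generate_cohort(config$cohort, d)
    d
  } else {
    config$cohort
  }
  manifest <- list(seed = config$seed, stages = config$stages,
                   cohort_dir = cohort_dir, counts = list())
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }
  if ("scanpath" %in% config$stages) {
    out$scanpath <- stage("scanpath", {
      fix <- read_cohort_fixations(cohort_dir)
      keys <- dplyr::distinct(fix, .data$participant, .data$race, .data$mask)
      models <- purrr::pmap(keys, function(participant, race, mask) {
        df <- dplyr::filter(fix, .data$participant == !!participant,
                            .data$race == !!race, .data$mask == !!mask)
        select_hmm(df, K_range = config$K_range,
                   n_restarts = config$n_restarts,
                   seed = child_seed(config$seed,
                                     paste(participant, race, mask)))
      })
      names(models) <- paste(keys$participant, keys$race, keys$mask, sep = "|")
      reps <- cluster_hmms(models, n_clusters = 2,
                           n_virtual = config$n_virtual, tau = config$tau,
                           seed = child_seed(config$seed, "vhem"))
      scores <- score_scanpaths(fix, reps, models)
      readr::write_csv(scores, file.path(config$out_dir, "scanpath_scores.csv"))
      manifest$counts$n_models <- length(models)
      list(models = models, reps = reps, scores = scores)
    })
  }
  epochs_by_p <- NULL
  load_epochs <- function() {
    files <- list.files(cohort_dir, pattern = "^epochs_p[0-9]+\\.rds$")
    if (length(files) == 0) {
      abort("dependency missing: no epochs in cohort (EEG stage disabled?)")
    }
    lapply(sub("\\.rds$", "", files), function(b) {
      read_epochs(file.path(cohort_dir, b))
    })
  }
  if ("erp" %in% config$stages) {
    out$erp <- stage("erp", {
      epochs_by_p <- load_epochs()
      tabs <- purrr::imap_dfr(epochs_by_p, function(ep, p) {
        kept <- reject_artifacts(ep, threshold = 100, participant = p)$epochs
        comps <- erp_components()
        present <- vapply(comps$channels,
                          function(ch) all(ch %in% kept$channels), TRUE)
        if (!any(present)) return(tibble::tibble())
        dplyr::mutate(component_amplitude(kept, comps[present, ]),
                      participant = p, .before = 1)
      })
      readr::write_csv(tabs, file.path(config$out_dir, "erp_components.csv"))
      manifest$counts$n_erp_rows <- nrow(tabs)
      tabs
    })
  }
  if ("decoding" %in% config$stages) {
    out$decoding <- stage("decoding", {
      if (is.null(epochs_by_p)) epochs_by_p <- load_epochs()
      res <- purrr::imap_dfr(epochs_by_p, function(ep, p) {
        purrr::map_dfr(c("masked", "unmasked"), function(mk) {
          sub <- filter_epochs(ep, .data$mask == mk)
          n_per <- min(6L, floor(min(table(sub$labels$race)) / 2))
          dr <- decode_timecourse(sub, "race", n_iter = config$n_iter,
                                  n_per_class = max(3L, n_per),
                                  seed = child_seed(config$seed,
                                                    paste("dec", p, mk)))
          dplyr::mutate(tidy(dr), participant = p, mask = mk, .before = 1)
        })
      })
      readr::write_csv(res, file.path(config$out_dir, "decoding_accuracy.csv"))
      curves <- res |>
        dplyr::group_by(.data$participant, .data$mask, .data$window_ms) |>
        dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
      cl <- list()
      if (dplyr::n_distinct(curves$participant) >= 3) {
        cl <- purrr::map(c("masked", "unmasked"), function(mk) {
          cluster_permutation_test(
            dplyr::filter(curves, .data$mask == mk),
            chance = 0.5, n_perm = config$n_perm,
            seed = child_seed(config$seed, paste("perm", mk))
          )
        })
        names(cl) <- c("masked", "unmasked")
        cl_tab <- purrr::imap_dfr(cl, function(cr, mk) {
          dplyr::mutate(tidy(cr), contrast = paste0(mk, "_vs_chance"),
                        .before = 1)
        })
        readr::write_csv(cl_tab,
                         file.path(config$out_dir, "decoding_clusters.csv"))
      }
      list(accuracy = res, clusters = cl)
    })
  }
  if ("stats" %in% config$stages) {
    out$stats <- stage("stats", {
      behavior <- readr::read_csv(file.path(cohort_dir, "behavior.csv"),
                                  show_col_types = FALSE)
      beh <- summarize_behavior(behavior)
      res <- list(behavior = beh)
      if (nrow(dplyr::distinct(beh$cells, .data$participant)) >= 3) {
        res$anova_accuracy <- rm_anova_2x2(beh$cells, value = "accuracy")
        res$bias_t <- with(
          tidyr::pivot_wider(beh$bias, id_cols = "participant",
                             names_from = "mask", values_from = "bias"),
          paired_t_test(masked, unmasked)
        )
      }
      if (!is.null(out$scanpath)) {
        res$mask_effects <- compute_mask_effects(
          dplyr::select(out$scanpath$scores, "participant", "race", "mask",
                        value = "ab_scale"))
        readr::write_csv(res$mask_effects,
                         file.path(config$out_dir, "mask_effects.csv"))
      }
      readr::write_csv(beh$cells, file.path(config$out_dir, "behavior_cells.csv"))
      res
    })
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "pipeline_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
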