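#' Sample fixation sequences from a scanpath HMM
#'
#' Forward-samples the generative model: the ROI sequence follows the
#' prior/transition chain, fixation positions are drawn from the active
#' ROI's 2-D Gaussian, and durations from a lognormal with median 250 ms
#' (typical of free viewing).
#'
#' @param hmm an [eye_hmm()].
#' @param n_trials number of fixation sequences (trials) to sample.
#' @param length_range inclusive `(min, max)` fixations per trial; the
#'   length is uniform over this range.
#' @param seed integer seed; identical seeds give identical output.
#' @param dur_meanlog,dur_sdlog lognormal duration parameters (log-ms).
#' @return A tibble: `trial`, `fix_index`, `x`, `y`, `duration` (px, ms).
#' @export
simulate_fixations <- function(hmm, n_trials, length_range = c(5, 12),
                               seed = NULL, dur_meanlog = log(250),
                               dur_sdlog = 0.4) {
  stopifnot(inherits(hmm, "eye_hmm"), n_trials >= 1,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_trials,
                   replace = TRUE)
    purrr::map2_dfr(seq_len(n_trials), lens, function(tr, Tn) {
      xy <- sample_hmm_positions(hmm, Tn)
      tibble::tibble(
        trial = tr, fix_index = seq_len(Tn),
        x = xy[, 1], y = xy[, 2],
        duration = rlnorm(Tn, dur_meanlog, dur_sdlog)
      )
    })
  })
}
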