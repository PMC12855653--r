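#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the mean voltage over the pre-stimulus
#' baseline window, so the baseline mean is exactly zero afterwards.
#'
#' @param epochs an [eeg_epochs()].
#' @param baseline ms interval, default the -200-0 pre-stimulus span.
#' @return Baseline-corrected [eeg_epochs()].
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  idx <- which(epochs$times >= baseline[1] & epochs$times <= baseline[2])
  if (length(idx) == 0) abort("baseline window contains no samples")
  bl <- colMeans(aperm(epochs$data[, idx, , drop = FALSE], c(2, 1, 3)))
  epochs$data <- epochs$data -
    aperm(array(bl, dim = c(dim(bl), dim(epochs$data)[2])), c(1, 3, 2))
  epochs
}

#' Threshold artifact rejection
#'
#' Drops every trial whose absolute voltage reaches `threshold` uV on any
#' channel at any sample, mirroring automatic +/-100 uV artifact screening.
#'
#' @param epochs an [eeg_epochs()].
#' @param threshold rejection threshold in uV (> 0); a trial is kept iff
#'   `max |v| < threshold`.
#' @param participant optional id used in the all-rejected error message.
#' @return A list: `epochs` (retained trials) and `log`, a tibble of
#'   dropped trials with the peak-voltage channel.
#' @export
reject_artifacts <- function(epochs, threshold = 100, participant = NULL) {
  stopifnot(threshold > 0)
  peak <- apply(abs(epochs$data), 3, max)
  drop <- which(peak >= threshold)
  worst_channel <- vapply(drop, function(tr) {
    epochs$channels[which.max(apply(abs(epochs$data[, , tr, drop = FALSE]), 1, max))]
  }, "")
  if (length(drop) == n_trials(epochs)) {
    abort(sprintf("all %d trials rejected at %g uV%s", length(drop), threshold,
                  if (is.null(participant)) "" else
                    sprintf(" for participant %s", participant)))
  }
  keep <- setdiff(seq_len(n_trials(epochs)), drop)
  list(
    epochs = eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$times,
                        epochs$srate, epochs$channels,
                        epochs$labels[keep, , drop = FALSE]),
    log = tibble::tibble(trial = drop, channel = worst_channel,
                         peak_uv = peak[drop])
  )
}

#' Exclude participants with low epoch retention
#'
#' @param retention data frame with columns `participant` and `fraction`
#'   (retained epochs / total, in `[0, 1]`).
#' @param min_fraction retention cutoff; a participant is kept iff
#'   `fraction >= min_fraction` (default 0.5).
#' @return A tibble with columns `participant`, `fraction`, `retained`.
#' @export
exclude_low_retention <- function(retention, min_fraction = 0.5) {
  stopifnot(all(retention$fraction >= 0 & retention$fraction <= 1))
  dplyr::mutate(tibble::as_tibble(retention),
                retained = .data$fraction >= min_fraction)
}

#' Default ERP component definitions
#'
#' The three analyzed components with their measurement windows and sites:
#' P1 (80-120 ms, occipital O1/O2), N170 (120-220 ms, left and right
#' occipito-temporal sites) and P2 (150-250 ms, fronto-central sites).
#'
#' @return A tibble: `component`, `window` (list of ms pairs), `channels`
#'   (list of channel-name vectors).
#' @export
erp_components <- function() {
  tibble::tibble(
    component = c("P1", "N170_left", "N170_right", "P2"),
    window = list(c(80, 120), c(120, 220), c(120, 220), c(150, 250)),
    channels = list(
      c("O1", "O2"),
      c("T7", "TP7", "P7", "PO7"),
      c("T8", "TP8", "P8", "PO8"),
      c("F3", "F4", "Fz", "C3", "C4", "Cz")
    )
  )
}

#' Mean component amplitude per condition
#'
#' Averages voltage over the component's channels, its time window
#' (inclusive bounds) and the trials of each race x mask cell.
#'
#' @param epochs an [eeg_epochs()] (baseline-corrected).
#' @param components component table as from [erp_components()]; a subset
#'   of rows selects specific components.
#' @param by label columns defining the condition cells.
#' @return A tibble: one row per component x cell with `amplitude` (uV)
#'   and `n_trials`.
#' @export
component_amplitude <- function(epochs, components = erp_components(),
                                by = c("race", "mask")) {
  missing_by <- setdiff(by, names(epochs$labels))
  if (length(missing_by)) {
    abort(paste("label columns missing:", paste(missing_by, collapse = ", ")))
  }
  cells <- dplyr::distinct(epochs$labels[, by, drop = FALSE])
  purrr::pmap_dfr(components, function(component, window, channels, ...) {
    ch <- match(channels, epochs$channels)
    if (anyNA(ch)) {
      abort(sprintf("channels not in montage for %s: %s", component,
                    paste(channels[is.na(ch)], collapse = ", ")))
    }
    ti <- which(epochs$times >= window[1] & epochs$times <= window[2])
    purrr::pmap_dfr(cells, function(...) {
      cell <- tibble::tibble(...)
      sel <- rep(TRUE, n_trials(epochs))
      for (col in by) sel <- sel & epochs$labels[[col]] == cell[[col]]
      if (!any(sel)) {
        abort(sprintf("no trials in cell %s for %s",
                      paste(unlist(cell), collapse = "/"), component))
      }
      dplyr::bind_cols(
        tibble::tibble(component = component),
        cell,
        tibble::tibble(
          amplitude = mean(epochs$data[ch, ti, sel]),
          n_trials = sum(sel)
        )
      )
    })
  })
}
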