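#' Epoched EEG container
#'
#' A light-weight container for stimulus-locked EEG epochs: a channels x
#' time x trials voltage array (microvolts) plus sampling metadata and
#' per-trial condition labels.
#'
#' @param data numeric array, channels x time x trials (uV).
#' @param times numeric vector of sample times (ms relative to stimulus
#'   onset), length `dim(data)[2]`.
#' @param srate sampling rate in Hz.
#' @param channels character vector of unique 10-20 channel names.
#' @param labels data frame with one row per trial (columns such as
#'   `race`, `mask`, `identity`, `correct`).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, srate, channels, labels) {
  stopifnot(length(dim(data)) == 3)
  if (length(channels) != dim(data)[1]) abort("channel count mismatch")
  if (anyDuplicated(channels)) abort("channel names must be unique")
  if (length(times) != dim(data)[2]) abort("times length mismatch")
  if (nrow(labels) != dim(data)[3]) {
    abort(sprintf("label rows (%d) != trial count (%d)",
                  nrow(labels), dim(data)[3]))
  }
  structure(
    list(data = data, times = as.numeric(times), srate = srate,
         channels = channels, labels = tibble::as_tibble(labels)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d channels x %d samples x %d trials, %g Hz, [%g, %g] ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate,
              min(x$times), max(x$times)))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[3]

#' Subset epochs by trial
#'
#' @param epochs an [eeg_epochs()].
#' @param ... filter expressions evaluated on the label table (as in
#'   [dplyr::filter()]), e.g. `race == "Asian"`, `mask == "masked"`.
#' @return The filtered [eeg_epochs()].
#' @export
filter_epochs <- function(epochs, ...) {
  idx <- dplyr::filter(dplyr::mutate(epochs$labels,
                                     .row = dplyr::row_number()), ...)$.row
  eeg_epochs(epochs$data[, , idx, drop = FALSE], epochs$times, epochs$srate,
             epochs$channels, epochs$labels[idx, , drop = FALSE])
}

#' Default 61-channel extended 10-20 montage
#'
#' The scalp montage used by the synthetic generator: a 64-channel gel cap
#' layout minus EOG and the two mastoids, leaving 61 analysis channels.
#'
#' @return Character vector of 61 channel names.
#' @export
montage_61 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "O2")
}

#' Write / read an epochs container
#'
#' Serializes the voltage array with an RDS payload plus a JSON sidecar of
#' the metadata and a CSV of the trial labels, so labels stay inspectable
#' as plain text.
#'
#' @param epochs an [eeg_epochs()].
#' @param path base path (without extension).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns the [eeg_epochs()].
#' @export
write_epochs <- function(epochs, path) {
  saveRDS(epochs$data, paste0(path, ".rds"))
  readr::write_csv(epochs$labels, paste0(path, "_labels.csv"))
  jsonlite::write_json(
    list(times = epochs$times, srate = epochs$srate,
         channels = epochs$channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_epochs
#' @param path base path used by [write_epochs()].
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_epochs(readRDS(paste0(path, ".rds")), meta$times, meta$srate,
             meta$channels,
             readr::read_csv(paste0(path, "_labels.csv"),
                             show_col_types = FALSE))
}
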