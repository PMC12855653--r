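#' Specify condition effects for synthetic EEG epochs
#'
#' Describes the generative structure of a synthetic participant's epochs:
#' fixed component templates (an occipital positivity at 80-120 ms, a
#' temporo-parietal negativity at 120-220 ms and a fronto-central
#' positivity at 150-250 ms) plus additive condition effects and spatially
#' correlated 1/f-type noise. Each effect is an amplitude offset (uV)
#' applied on a set of channels inside a time window.
#'
#' @param race_effect,mask_effect,identity_effect lists with elements
#'   `amplitude` (uV), `window` (ms, length 2) and optionally `channels`
#'   (names; default posterior sites). Amplitude 0 disables the effect.
#' @param noise_sd noise standard deviation (uV), > 0.
#' @param n_channels channel count (default 61; truncates [montage_61()]).
#' @param srate sampling rate (Hz).
#' @param epoch_window epoch span in ms.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(race_effect = list(amplitude = 1, window = c(150, 350)),
                        mask_effect = list(amplitude = 1, window = c(100, 300)),
                        identity_effect = list(amplitude = 0.5, window = c(150, 500)),
                        noise_sd = 2, n_channels = 61, srate = 250,
                        epoch_window = c(-200, 1000)) {
  stopifnot(noise_sd > 0, n_channels >= 2)
  for (eff in list(race_effect, mask_effect, identity_effect)) {
    if (!is.null(eff$window) &&
        (eff$window[1] < epoch_window[1] || eff$window[2] > epoch_window[2])) {
      abort("effect window must lie within the epoch window")
    }
  }
  structure(
    list(race_effect = race_effect, mask_effect = mask_effect,
         identity_effect = identity_effect, noise_sd = noise_sd,
         n_channels = n_channels, srate = srate,
         epoch_window = epoch_window),
    class = "effect_spec"
  )
}

# smooth half-cosine bump over [w1, w2] ms, unit peak
time_bump <- function(times, window) {
  inside <- times >= window[1] & times <= window[2]
  b <- numeric(length(times))
  b[inside] <- 0.5 - 0.5 * cos(2 * pi * (times[inside] - window[1]) /
                                 (window[2] - window[1]))
  b
}

# pink (1/f) noise via FFT spectrum shaping, unit variance columns
pink_noise <- function(n_time, n_series) {
  out <- matrix(0, n_time, n_series)
  f <- c(1, seq_len(floor(n_time / 2)))
  for (j in seq_len(n_series)) {
    w <- rnorm(n_time)
    W <- fft(w)
    scale <- 1 / sqrt(c(f, rev(f[seq_len(n_time - length(f))])))
    x <- Re(fft(W * scale, inverse = TRUE)) / n_time
    out[, j] <- x / sd(x)
  }
  out
}

#' Simulate labeled EEG epochs
#'
#' Generates one participant's epochs under an [effect_spec()]: component
#' templates scaled per condition, additive race/mask/identity effects, a
#' random spatial mixing of per-channel pink noise, and exact per-channel
#' baseline-zero mean over the pre-stimulus interval.
#'
#' @param spec an [effect_spec()].
#' @param labels data frame with one row per trial and columns `race`
#'   (`"Asian"`/`"White"`), `mask` (`"masked"`/`"unmasked"`), `identity`
#'   and optionally `correct`; every race x mask cell needs >= 2 trials.
#' @param seed integer seed.
#' @return An [eeg_epochs()]; the ground-truth effect windows are attached
#'   as attribute `"ground_truth"`.
#' @export
simulate_epochs <- function(spec, labels, seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  labels <- tibble::as_tibble(labels)
  cells <- table(labels$race, labels$mask)
  if (any(cells < 2)) abort("every race x mask cell needs at least 2 trials")
  channels <- montage_61()[seq_len(spec$n_channels)]
  times <- seq(spec$epoch_window[1], spec$epoch_window[2],
               by = 1000 / spec$srate)
  nt <- length(times)
  ntr <- nrow(labels)
  post <- times >= 0
  occ <- which(channels %in% c("O1", "O2", "PO7", "PO8", "POz"))
  tp <- which(channels %in% c("T7", "TP7", "P7", "PO7", "T8", "TP8", "P8", "PO8"))
  fc <- which(channels %in% c("F3", "F4", "Fz", "C3", "C4", "Cz"))
  if (length(occ) == 0) occ <- seq_len(min(4, spec$n_channels))
  if (length(tp) == 0) tp <- seq_len(min(4, spec$n_channels))
  if (length(fc) == 0) fc <- seq_len(min(4, spec$n_channels))
  eff_channels <- function(eff, default) {
    if (is.null(eff$channels)) return(default)
    idx <- match(eff$channels, channels)
    idx[!is.na(idx)]
  }
  with_seed(seed, {
    mix <- diag(spec$n_channels) * 0.8 +
      matrix(rnorm(spec$n_channels^2, 0, sqrt(0.2 / spec$n_channels)),
             spec$n_channels)
    identities <- sort(unique(labels$identity))
    id_pattern <- lapply(identities, function(i) rnorm(spec$n_channels))
    names(id_pattern) <- as.character(identities)
    data <- array(0, dim = c(spec$n_channels, nt, ntr))
    p1 <- time_bump(times, c(80, 120))
    n170 <- time_bump(times, c(120, 220))
    p2 <- time_bump(times, c(150, 250))
    for (tr in seq_len(ntr)) {
      sig <- matrix(0, spec$n_channels, nt)
      sig[occ, ] <- sig[occ, ] + rep(4 * p1, each = length(occ))
      sig[tp, ] <- sig[tp, ] - rep(5 * n170, each = length(tp))
      sig[fc, ] <- sig[fc, ] + rep(3 * p2, each = length(fc))
      re <- spec$race_effect
      if (!is.null(re) && re$amplitude != 0 && labels$race[tr] == "Asian") {
        ch <- eff_channels(re, occ)
        sig[ch, ] <- sig[ch, ] + re$amplitude *
          rep(time_bump(times, re$window), each = length(ch))
      }
      me <- spec$mask_effect
      if (!is.null(me) && me$amplitude != 0 && labels$mask[tr] == "unmasked") {
        ch <- eff_channels(me, tp)
        sig[ch, ] <- sig[ch, ] + me$amplitude *
          rep(time_bump(times, me$window), each = length(ch))
      }
      ie <- spec$identity_effect
      if (!is.null(ie) && ie$amplitude != 0) {
        pat <- id_pattern[[as.character(labels$identity[tr])]]
        sig <- sig + ie$amplitude * pat %o% time_bump(times, ie$window)
      }
      noise <- t(mix %*% t(pink_noise(nt, spec$n_channels))) * spec$noise_sd
      data[, , tr] <- sig + t(noise)
    }
    ep <- eeg_epochs(data, times, spec$srate, channels, labels)
    ep <- baseline_correct(ep)
    attr(ep, "ground_truth") <- list(
      race_window = spec$race_effect$window,
      mask_window = spec$mask_effect$window,
      identity_window = spec$identity_effect$window,
      noise_sd = spec$noise_sd
    )
    ep
  })
}
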