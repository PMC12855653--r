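#' Plot a decoding time course
#'
#' Iteration-mean accuracy over window position with the chance level as a
#' dashed line.
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$window_ms) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     se = sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$window_ms, .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$se,
                                      ymax = .data$accuracy + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::labs(x = "window start (ms)", y = "decoding accuracy",
                  title = sprintf("%s decoding", object$scheme))
}

#' Plot scanpath model ROIs
#'
#' ROI ellipses (2 SD contours) over the stimulus frame, on eye-tracker
#' coordinates (origin top-left, y downward, hence a reversed y axis).
#'
#' @param object an `eye_hmm`.
#' @param frame screen extent (px).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eye_hmm <- function(object, frame = c(1920, 1080), ...) {
  theta <- seq(0, 2 * pi, length.out = 60)
  ell <- purrr::map_dfr(seq_len(object$K), function(k) {
    L <- chol(object$covs[, , k])
    pts <- cbind(cos(theta), sin(theta)) %*% (2 * L)
    tibble::tibble(roi = factor(k),
                   x = pts[, 1] + object$means[k, 1],
                   y = pts[, 2] + object$means[k, 2])
  })
  ggplot2::ggplot(ell, ggplot2::aes(.data$x, .data$y, group = .data$roi,
                                    colour = .data$roi)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse(limits = rev(c(0, frame[2]))) +
    ggplot2::xlim(0, frame[1]) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a cluster permutation result
#'
#' Pointwise t curve with significant clusters shaded.
#'
#' @param object a `cluster_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(window_ms = object$times, t = object$t)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$window_ms, .data$t)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (ms)", y = "t statistic")
  sig <- dplyr::filter(object$clusters, .data$significant)
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "red"
    )
  }
  p
}
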