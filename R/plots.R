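#' Plot an electrode-loss sweep
#'
#' Velocity-correlation (or another metric) against the number of dropped
#' electrodes, one line per decoder; with multiple seeds the mean and one
#' standard deviation across seeds are shown.
#'
#' @param object a `loss_sweep` tibble from [drop_sweep()] or
#'   [run_loss_experiment()].
#' @param metric column to plot (default `velocity_correlation`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot loss_sweep
#' @export
autoplot.loss_sweep <- function(object, metric = "velocity_correlation", ...) {
  df <- tibble::as_tibble(object)
  if ("seed" %in% names(df)) {
    df <- df |>
      dplyr::group_by(.data$n_dropped, .data$decoder) |>
      dplyr::summarise(mean = mean(.data[[metric]], na.rm = TRUE),
                       sd = sd(.data[[metric]], na.rm = TRUE),
                       .groups = "drop")
  } else {
    df$mean <- df[[metric]]; df$sd <- 0
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_dropped, y = .data$mean,
                                   colour = .data$decoder)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$decoder),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "electrodes dropped (most informative first)",
                  y = metric) +
    ggplot2::theme_minimal()
}

#' Eigenvalue spectrum of a dynamics matrix
#'
#' Continuous-time eigenvalues of `(M - I)/dt`: decay rate (1/s) against
#' frequency (Hz), the standard view of which rotational modes a decoder's
#' dynamics carry.
#'
#' @param x an [eigenmodes()] result, [lds_params()], or dynamics matrix.
#' @param dt bin width (used when `x` is a bare matrix).
#' @return A ggplot object.
#' @export
plot_eigenspectrum <- function(x, dt = 0.015) {
  if (!inherits(x, "eigenmode_set")) x <- eigenmodes(x, dt = dt)
  m <- tidy(x)
  df <- dplyr::bind_rows(
    m,
    m |> dplyr::filter(.data$type == "rotational") |>
      dplyr::mutate(im = -.data$im, frequency_hz = -.data$frequency_hz))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$re, y = .data$im / (2 * pi),
                                   colour = .data$type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "decay rate Re(lambda) (1/s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot per-mode contributions to the decoded output
#'
#' Regularized share of the decoded speed per eigenmode, arranged by mode
#' frequency, separating rotational from purely decaying modes.
#'
#' @param object a [mode_contributions()] report.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mode_contribution_report
#' @export
autoplot.mode_contribution_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("%.2f Hz", df$frequency_hz)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$frequency_hz),
                                   y = .data$share, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "eigenmode frequency", y = "share of decoded speed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
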