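# ggplot2 visualizations for the main result types.

#' Plot a cycle-averaged scalogram
#'
#' @param object An `mec_scalogram`.
#' @param ... Unused.
#' @return A ggplot: within-cycle time against frequency, fill = power.
#' @export
autoplot.mec_scalogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$frequency_Hz,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c(name = expression(power ~ (pA^2))) +
    ggplot2::labs(x = "time in theta cycle (ms)", y = "frequency (Hz)",
                  title = sprintf("cycle-averaged scalogram (%d cycles)",
                                  object$n_cycles_used)) +
    ggplot2::theme_minimal()
}

#' Plot an E-to-I conductance sweep
#'
#' @param object An `mec_sweep`.
#' @param what `"frequency"` or `"power"`.
#' @param ... Unused.
#' @return A ggplot with one box per swept conductance across seeds.
#' @export
autoplot.mec_sweep <- function(object, what = c("frequency", "power"),
                               ...) {
  what <- match.arg(what)
  y <- if (what == "frequency") "peak_frequency_Hz" else "peak_power"
  lab <- if (what == "frequency") "peak gamma frequency (Hz)" else
    expression(peak ~ gamma ~ power ~ (pA^2))
  df <- dplyr::filter(object, !is.na(.data[[y]]))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$g_ei), .data[[y]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = "total E→I conductance (nS)", y = lab) +
    ggplot2::theme_minimal()
}

#' Raster plot of network spiking
#'
#' @param sim An `mec_sim`.
#' @param populations Populations to show.
#' @param max_cells Optional cap on cells per population (first `n`).
#' @return A ggplot raster (time against cell, colored by population).
#' @export
plot_raster <- function(sim, populations = c("E", "I"), max_cells = NULL) {
  stopifnot(inherits(sim, "mec_sim"))
  df <- dplyr::filter(sim$spikes, .data$population %in% populations)
  if (!is.null(max_cells)) {
    keep <- df |>
      dplyr::distinct(.data$population, .data$cell) |>
      dplyr::group_by(.data$population) |>
      dplyr::slice_head(n = max_cells) |>
      dplyr::ungroup()
    df <- dplyr::semi_join(df, keep, by = c("population", "cell"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$cell,
                                   colour = .data$population)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_colour_manual(values = c(E = "#c0392b", I = "#2980b9")) +
    ggplot2::labs(x = "time (ms)", y = "cell") +
    ggplot2::theme_minimal()
}

#' Plot an impedance profile
#'
#' @param object An `mec_impedance`.
#' @param ... Unused.
#' @return A ggplot of impedance magnitude against frequency with the
#'   resonance marked.
#' @export
autoplot.mec_impedance <- function(object, ...) {
  fr <- attr(object, "resonance_frequency_Hz")
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency_Hz,
                                       .data$impedance_MOhm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = fr, linetype = 2) +
    ggplot2::labs(x = "frequency (Hz)", y = "impedance (MΩ)",
                  subtitle = sprintf("resonance at %.1f Hz", fr)) +
    ggplot2::theme_minimal()
}

#' Plot a theta-phase histogram
#'
#' @param object An `mec_phase_hist`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-cycle normalized counts.
#' @export
autoplot.mec_phase_hist <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes((.data$bin_left_rad + .data$bin_right_rad) / 2,
                               .data$per_cycle)) +
    ggplot2::geom_col(width = diff(object$bin_left_rad[1:2])) +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
      labels = c("0", expression(pi / 2), expression(pi),
                 expression(3 * pi / 2), expression(2 * pi))) +
    ggplot2::labs(x = "theta phase (rad)", y = "spikes per cycle") +
    ggplot2::theme_minimal()
}
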