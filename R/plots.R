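# ggplot2 quick-look plots for the main result types.

#' Plot a metric time series
#'
#' Thin per-chain traces with a centred running average overlaid, the way
#' per-frame channel metrics are usually presented.
#'
#' @param data Tibble with `time_ns`, `value` and optionally `chain`.
#' @param window Running-average window (frames).
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_time_series <- function(data, window = 50, ylab = "value") {
  has_chain <- "chain" %in% names(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time_ns,
                                          y = .data$value))
  if (has_chain) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$chain),
                                colour = "grey70", linewidth = 0.3)
    avg <- dplyr::summarise(dplyr::group_by(data, .data$time_ns),
                            value = mean(.data$value), .groups = "drop")
  } else {
    p <- p + ggplot2::geom_line(colour = "grey70", linewidth = 0.3)
    avg <- data
  }
  avg$value <- running_average(avg$value, window)
  p + ggplot2::geom_line(data = avg, colour = "firebrick",
                         linewidth = 0.8) +
    ggplot2::labs(x = "time (ns)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @method autoplot pore_profile
#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "pore radius (Å)") +
    ggplot2::theme_minimal()
}

#' @method autoplot fes2d
#' @export
autoplot.fes2d <- function(object, contour_level = 4, ...) {
  df <- as_tibble(unclass(object))
  df$free_energy[!is.finite(df$free_energy)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "F (kcal/mol)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot gating_charge_table
#' @export
autoplot.gating_charge_table <- function(object, ...) {
  df <- tidy(object)
  df$residue <- factor(df$residue, levels = df$residue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                   y = .data$contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$contribution - .data$error,
      ymax = .data$contribution + .data$error), width = 0.2) +
    ggplot2::labs(y = "gating-charge contribution (e)") +
    ggplot2::theme_minimal()
}

#' @method autoplot flow_profile
#' @export
autoplot.flow_profile <- function(object, highlight_threshold = 0.02, ...) {
  df <- tidy(object)
  df <- df[df$role == "interior", ]
  df$highlight <- df$flow > highlight_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$flow,
                                   fill = .data$highlight)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "purple")) +
    ggplot2::labs(y = "information flow") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a potential-grid slice
#'
#' @param grid A `potential_grid`.
#' @param point,normal Plane definition (see [probe_plane()]).
#' @param ... Passed to [probe_plane()].
#' @return A ggplot object.
#' @export
plot_potential_slice <- function(grid, point = c(0, 0, 0),
                                 normal = c(0, 1, 0), ...) {
  df <- probe_plane(grid, point, normal, ...)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "potential (mV)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
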