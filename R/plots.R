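#' Plot methods
#'
#' `autoplot()` methods for the package's result types: staircase
#' trajectories colored by protocol segment, summed reduction traces with
#' their exponential fit, semi-log Bell plots, titration curves, and
#' three-level landscape sketches.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fc-plots
NULL

#' @rdname fc-plots
#' @export
autoplot.fc_trajectory <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$time_s, .data$extension_nm, colour = .data$segment_label)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "extension (nm)", colour = "segment",
      title = sprintf(
        "%s force-clamp trajectory", attr(object, "compound_name") %||% ""
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fc-plots
#' @param rate Optional `fc_rate` whose fit curve is overlaid.
#' @export
autoplot.fc_summed <- function(object, rate = NULL, ...) {
  p <- ggplot2::ggplot(
    as_tibble(object), ggplot2::aes(.data$time_s, .data$fraction)
  ) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::labs(
      x = "time from test-pulse onset (s)", y = "reacted fraction",
      title = sprintf(
        "Summed reduction kinetics (%d traces, %g pN)",
        attr(object, "n_traces"), attr(object, "force_pN")
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(rate)) {
    t <- object$time_s
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = t, fraction = 1 - exp(-rate$rate_s * t)),
      colour = "firebrick"
    )
  }
  p
}

#' @rdname fc-plots
#' @export
autoplot.fc_bellfit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$force_pN, .data$norm_rate_M_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(
        force_pN = seq(min(d$force_pN), max(d$force_pN), length.out = 50)
      ) |>
        mutate(norm_rate_M_s = exp(
          stats::predict(object$fit, newdata = tibble(force_pN = .data$force_pN))
        )),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "force (pN)", y = expression(r / "[S-]" ~ (M^-1 ~ s^-1)),
      title = sprintf(
        "Bell/Arrhenius fit: dx = %.2f A, barrier = %.1f kT",
        object$dx_A, object$dG_barrier_kT
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fc-plots
#' @export
autoplot.fc_titration <- function(object, ...) {
  p <- ggplot2::ggplot(
    as_tibble(object), ggplot2::aes(.data$pH, .data$absorbance)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pH", y = "absorbance (240 nm)") +
    ggplot2::theme_minimal()
  if (!is.null(attr(object, "pKa_fit"))) {
    grid <- seq(min(object$pH), max(object$pH), length.out = 100)
    p <- p + ggplot2::geom_line(
      data = tibble(
        pH = grid,
        absorbance = titration_absorbance(
          grid, attr(object, "A_min"), attr(object, "A_max"),
          attr(object, "pKa_fit")
        )
      ),
      colour = "firebrick"
    ) +
      ggplot2::ggtitle(sprintf("pKa = %.2f", attr(object, "pKa_fit")))
  }
  p
}

#' @rdname fc-plots
#' @export
autoplot.fc_landscape <- function(object, ...) {
  d <- mutate(as_tibble(object), coordinate = c(0, 0.5, 1))
  ggplot2::ggplot(d, ggplot2::aes(.data$coordinate, .data$energy_kT)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), vjust = -1) +
    ggplot2::labs(
      x = "reaction coordinate", y = "free energy (kT)",
      title = sprintf(
        "%s at %g pN", attr(object, "compound_name"), attr(object, "force_pN")
      )
    ) +
    ggplot2::theme_minimal()
}
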