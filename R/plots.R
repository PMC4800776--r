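#' Group-mean trajectory plot
#'
#' Mean +/- SEM trajectories of one metric by scattering group and
#' treatment cell, the standard visual of a bleaching time course.
#'
#' @param table An observation table.
#' @param metric Metric column to plot.
#' @param profiles Optional profile table supplying `group`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(table, metric = "fvfm", profiles = NULL) {
  dat <- tibble::as_tibble(table)
  if (!"group" %in% names(dat)) {
    if (is.null(profiles)) {
      stop_schema("Supply a `group` column or a `profiles` table.")
    }
    dat <- dplyr::left_join(
      dat, tibble::as_tibble(profiles)[c("species", "group")], by = "species"
    )
  }
  dat$value <- dat[[metric]]
  summ <- dat |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$group, .data$temperature, .data$light,
                    .data$day) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(cell = paste(.data$temperature, .data$light, sep = "-"))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$day, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem, fill = .data$group),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "day relative to stress onset", y = metric,
                  colour = "scattering group", fill = "scattering group") +
    ggplot2::theme_minimal()
}

#' Delta-PE vs microscopic scattering plot
#'
#' Species-level scatter of the isolated rate difference against `mu_sm`
#' with per-conditioning OLS lines.
#'
#' @param depe A [delta_pe()] tibble.
#' @param profiles Profile table with `species` and `mu_sm`.
#' @return A ggplot object.
#' @export
plot_depe <- function(depe, profiles) {
  dat <- dplyr::inner_join(
    tibble::as_tibble(depe),
    tibble::as_tibble(profiles)[c("species", "mu_sm")], by = "species"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mu_sm, y = .data$value,
                                    colour = .data$conditioning)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = expression(mu * minute[S * ", m"] ~ (mm^-1)),
                  y = expression(Delta * PE ~ (day^-1)),
                  colour = "held fixed") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot coraloptics_powerlaw
#' @export
autoplot.coraloptics_powerlaw <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(mu = seq(min(dat$mu), max(dat$mu),
                                  length.out = 100))
  grid$y <- object$a * grid$mu^(-object$b)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mu, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(mu * minute[S * ", m"] ~ (mm^-1)),
      y = "feedback rate",
      subtitle = sprintf("y = %.3g x^-%.2f   (r2 = %.2f)",
                         object$a, object$b, object$r2)
    ) +
    ggplot2::theme_minimal()
}
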