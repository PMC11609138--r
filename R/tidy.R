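# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation trajectory
#'
#' @param x an `alignersim_trajectory`.
#' @param ... unused.
#' @return the per-step, per-iteration, per-tooth records tibble.
#' @method tidy alignersim_trajectory
#' @export
tidy.alignersim_trajectory <- function(x, ...) x$records

#' One-row summary of a trajectory
#'
#' @param x an `alignersim_trajectory`.
#' @param ... unused.
#' @return tibble with the design, step counts, space-closed step, final gap
#'   and final maximum PDL strain.
#' @method glance alignersim_trajectory
#' @export
glance.alignersim_trajectory <- function(x, ...) {
  last <- x$records[x$records$step == max(x$records$step) &
                      x$records$iteration == max(x$records$iteration), ]
  tibble::tibble(
    design = x$design,
    n_steps = max(x$records$step),
    space_closed_step = x$space_closed_step,
    final_gap = last$gap[1],
    final_max_strain_percent = max(last$max_strain_percent)
  )
}

#' Tidy a comparison report
#'
#' @param x an `alignersim_report`.
#' @param ... unused.
#' @return long displacement tibble (`design`, `quantity`, `tooth`, `value`).
#' @method tidy alignersim_report
#' @export
tidy.alignersim_report <- function(x, ...) x$displacements

#' Per-design summary of a comparison report
#'
#' @param x an `alignersim_report`.
#' @param ... unused.
#' @return metrics tibble joined with the space-closed steps.
#' @method glance alignersim_report
#' @export
glance.alignersim_report <- function(x, ...) {
  dplyr::left_join(x$metrics, x$space_closed_steps, by = "design")
}

#' Plot per-step tooth displacements of a trajectory
#'
#' Line chart of the six kinematic quantities against the staging step
#' (final remodeling iteration of each step), one line per tooth.
#'
#' @param object an `alignersim_trajectory`.
#' @param quantities which quantities to facet (default all six).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot alignersim_trajectory
#' @export
autoplot.alignersim_trajectory <- function(object,
                                           quantities = DISPLACEMENT_QUANTITIES,
                                           ...) {
  df <- object$records |>
    dplyr::group_by(.data$step, .data$tooth) |>
    dplyr::filter(.data$iteration == max(.data$iteration)) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(quantities),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value,
                                   colour = factor(.data$tooth))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$space_closed_step,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "staging step", y = "displacement [mm] / rotation [deg]",
                  colour = "tooth",
                  title = sprintf("Design %s", toupper(object$design)))
}

#' Plot a cross-design comparison report
#'
#' @param object an `alignersim_report`.
#' @param quantity quantity to plot (default mesio-distal displacement).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot alignersim_report
#' @export
autoplot.alignersim_report <- function(object, quantity = "md_displacement",
                                       ...) {
  df <- dplyr::filter(object$displacements, .data$quantity == !!quantity)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$tooth), .data$value,
                                   fill = .data$design)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tooth (FDI position)", y = quantity,
                  title = "Space-closed-step comparison")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
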