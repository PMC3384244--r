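#' Plot a simulated trajectory
#'
#' Species time courses on free y scales, with the induction event marked.
#'
#' @param object a `circuit_trajectory`.
#' @param species which state variables to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot circuit_trajectory
#' @export
autoplot.circuit_trajectory <- function(object,
                                        species = species_names(), ...) {
  long <- trajectory_long(object) |>
    dplyr::filter(.data$species %in% !!species)
  ev <- attr(object, "events")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$time),
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)",
                  title = paste("Variant",
                                attr(object, "variant")$label)) +
    ggplot2::theme_minimal()
}

#' Plot total GFP across variants
#'
#' @param trajectories named list of `circuit_trajectory` objects.
#' @param observable column to draw (`"total_gfp"`,
#'   `"fluorescence_equiv"`, `"soluble_fraction"`, ...).
#' @return A ggplot object.
#' @export
plot_variant_panel <- function(trajectories, observable = "total_gfp") {
  long <- purrr::imap_dfr(trajectories, function(traj, lab) {
    tibble::tibble(time = traj$time, value = traj[[observable]],
                   variant = lab)
  })
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$time, .data$value,
                               color = .data$variant)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = observable) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic dataset
#'
#' @param object a `timecourse_dataset`.
#' @param ... unused.
#' @return A ggplot object: fluorescence per OD by clone, faceted by
#'   variant.
#' @method autoplot timecourse_dataset
#' @export
autoplot.timecourse_dataset <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$fluorescence_per_od,
                               group = .data$clone_id,
                               color = .data$clone_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "time (h)", y = "fluorescence / OD600") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot sensitivity coefficients
#'
#' @param object a `sensitivity_report`.
#' @param top show only the `top` most influential parameters.
#' @param ... unused.
#' @return A ggplot bar chart of normalized sensitivity coefficients.
#' @method autoplot sensitivity_report
#' @export
autoplot.sensitivity_report <- function(object, top = 10, ...) {
  keep <- utils::head(sensitivity_ranking(object), top)
  tbl <- tibble::as_tibble(object) |>
    dplyr::filter(.data$parameter %in% keep) |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = rev(keep)))
  ggplot2::ggplot(tbl,
                  ggplot2::aes(.data$coefficient, .data$parameter,
                               fill = .data$output)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "normalized sensitivity", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
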