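#' Typology quadrant plot
#'
#' Scatter of TEI-G against TEI-B colored by LHS state, with the cut lines
#' (cohort medians in median-split mode).
#'
#' @param projects Project records with `tei_g`, `tei_b` and `state` columns.
#' @return A ggplot object.
#' @export
plot_typology <- function(projects) {
  ggplot2::ggplot(projects,
                  ggplot2::aes(x = .data$tei_g, y = .data$tei_b,
                               colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = stats::median(projects$tei_g),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = stats::median(projects$tei_b),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "TEI-G (gain / spillover amplification)",
                  y = "TEI-B (bottleneck balance)",
                  colour = "LHS state",
                  title = "LHS translational efficiency typology") +
    ggplot2::theme_minimal()
}

#' CTI vs ROI relationship
#'
#' @param projects Project records with `cti` and `roi` columns.
#' @return A ggplot object.
#' @export
plot_cti_roi <- function(projects) {
  ggplot2::ggplot(projects, ggplot2::aes(x = .data$cti, y = .data$roi)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Community Transmission Index",
                  y = "Global ROI (revenue / expense)",
                  title = "Community transmission and economic return") +
    ggplot2::theme_minimal()
}

#' Cycle velocities vs ROI
#'
#' @param projects Project records with `v1..v4` and `roi` columns.
#' @return A ggplot object faceted by learning cycle.
#' @export
plot_velocity_roi <- function(projects) {
  long <- projects |>
    tidyr::pivot_longer(dplyr::all_of(paste0("v", 1:4)), names_to = "cycle",
                        values_to = "velocity") |>
    dplyr::mutate(cycle = factor(.data$cycle, levels = paste0("v", 1:4),
                                 labels = lhs_cycles))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$velocity, y = .data$roi)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::facet_wrap(~cycle, scales = "free_x") +
    ggplot2::labs(x = "Cycle velocity (month^-1)", y = "Global ROI",
                  title = "ROI against translational velocities") +
    ggplot2::theme_minimal()
}

#' Plot a Monte Carlo run
#'
#' @param object An `lhs_mc` object from [run_monte_carlo()].
#' @param type One of `"typology"`, `"cti_roi"`, `"velocities"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lhs_mc <- function(object, type = c("typology", "cti_roi",
                                             "velocities"), ...) {
  type <- match.arg(type)
  switch(type,
         typology = plot_typology(object$projects),
         cti_roi = plot_cti_roi(object$projects),
         velocities = plot_velocity_roi(object$projects))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
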