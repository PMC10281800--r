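# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Timing variation per milestone
#'
#' Box plot of milestone dates (cycle days) per milestone kind, mirroring
#' the variance-by-milestone view of the annual cycle.
#'
#' @param milestones Milestone tibble with `kind` and `cycle_day`.
#' @return A ggplot.
#' @export
plot_milestone_variation <- function(milestones) {
  milestones |>
    dplyr::mutate(kind = factor(.data$kind, MILESTONE_KINDS)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$kind, y = .data$cycle_day)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "days since 1 June") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.vc_fit <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$R)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(
      xintercept = object$summary$median[object$summary$parameter == "R"],
      linetype = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "repeatability R", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.path_fit <- function(object, min_p = 0.8, ...) {
  ed <- object$edges |>
    dplyr::filter(.data$p_nonzero >= min_p) |>
    dplyr::mutate(label = paste(.data$from, "→", .data$to))
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$median,
                                   y = stats::reorder(.data$label, .data$median))) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper,
                                          colour = .data$tier)) +
    ggplot2::labs(x = "standardized path coefficient", y = NULL,
                  colour = "support") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mortality_fit <- function(object, ...) {
  cf <- dplyr::filter(object$coefficients, .data$term != "intercept")
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$median, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "log-odds coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
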