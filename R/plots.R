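#' Plot the purchasing trajectories of a scenario run
#'
#' Draws mean weekly UPF purchasing over the reporting window for the
#' population and, optionally, the income or education strata, with the
#' policy activation week marked.
#'
#' @param object An `upf_run`.
#' @param strata `"population"`, `"income"` or `"education"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot upf_run
#' @export
autoplot.upf_run <- function(object, strata = c("population", "income",
                                                "education"), ...) {
  strata <- match.arg(strata)
  keep <- switch(strata,
                 population = "population",
                 income = c("income_low", "income_high"),
                 education = c("edu_low", "edu_high"))
  d <- dplyr::filter(tidy(object), .data$stratum %in% keep)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$mean_kcal,
                                  colour = .data$stratum)) +
    ggplot2::geom_vline(xintercept = object$config$policy$activation_step,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Week", y = "Mean UPF purchasing (kcal/week)",
                  colour = NULL, title = object$scenario) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare percent purchasing changes across a scenario grid
#'
#' @param grid A tibble from [scenario_grid()].
#' @return A ggplot bar chart of the percent change from the pre-policy to
#'   the final week per scenario.
#' @export
plot_grid_effects <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = stats::reorder(.data$scenario,
                                                  .data$pct_change),
                               y = -.data$pct_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Change in mean UPF purchasing (%)") +
    ggplot2::theme_minimal()
}
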