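#' Plot a trajectory
#'
#' Compartment time courses as line plots, faceted or overlaid.
#'
#' @param object A `siirr_trajectory`.
#' @param compartments Which columns to draw (default the two infected
#'   classes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.siirr_trajectory <- function(object,
                                      compartments = c("I1", "I2"), ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t", compartments)],
    -"t", names_to = "compartment", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$count,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (model units)", y = "individuals",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Peak height and peak time of each strain against the swept value.
#'
#' @param object A `siirr_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.siirr_sweep <- function(object, ...) {
  parameter <- attr(object, "parameter")
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("value", "peak_I1", "peak_I2",
                          "t_peak_I1", "t_peak_I2")],
    -"value", names_to = c("metric", "compartment"),
    names_pattern = "(.*)_(I[12])", values_to = "y"
  )
  long$metric <- ifelse(long$metric == "peak", "peak height", "peak time")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$y,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = parameter, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
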