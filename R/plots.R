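#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Ignored.
#' @return A ggplot step plot of survival over time.
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot per-sample mixture weights of a fitted deconvolution model
#'
#' Samples ordered by increasing up-signature weight — the "impregnation"
#' waterfall.
#'
#' @param object A `wisp_model` from [fit_wisp()].
#' @param ... Ignored.
#' @return A ggplot bar chart.
#' @export
autoplot.wisp_model <- function(object, ...) {
  w <- object$weights
  w <- w[order(w$w_up), ]
  w$rank <- seq_len(nrow(w))
  long <- tidyr::pivot_longer(w, c("w_down", "w_up"),
                              names_to = "program", values_to = "weight")
  long$program <- ifelse(long$program == "w_up", .CLASS_UP, .CLASS_DOWN)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$weight,
                                     fill = .data$program)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "Samples (ordered by up-signature weight)",
                  y = "Mixture weight", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves per group
#'
#' Convenience plot for class- or quartile-stratified survival.
#'
#' @param data Tibble with `time`, `event`, `group`.
#' @return A ggplot of one step curve per group.
#' @export
plot_km_groups <- function(data) {
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  curves <- dplyr::bind_rows(lapply(split(data, data$group), function(d) {
    cv <- km_estimate(d$time, d$event)
    tibble(time = cv$time, survival = cv$survival, group = d$group[1])
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
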