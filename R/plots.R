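# ggplot2 views of the result tables.

#' Plot a modularity-vs-threshold curve
#'
#' @param object A `modularity_curve` from [modularity_vs_threshold()].
#' @param ... Unused.
#' @return A ggplot: Q against the threshold in minutes; unreliable
#'   points (fewer than two surviving communities) hollow.
#' @exportS3Method ggplot2::autoplot
autoplot.modularity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold_minutes, y = .data$q)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$reliable), na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(
      x = "contact-duration threshold (min)", y = "modularity Q",
      shape = "reliable",
      title = sprintf("Modularity vs threshold (%s partition)",
                      attr(object, "level") %||% "external")
    )
}

#' Plot an overlap-vs-weight curve
#'
#' @param object An `overlap_curve` from [overlap_vs_weight_curve()].
#' @param ... Unused.
#' @return A ggplot of mean edge overlap per contact-duration bin.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_curve <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, .data$n_edges > 0),
    ggplot2::aes(x = .data$bin_mid, y = .data$mean_overlap)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "contact duration (min)", y = "mean overlap ratio")
}

#' Plot a degree histogram
#'
#' @param object A `degree_histogram` from [degree_distribution_table()].
#' @param ... Unused.
#' @return A ggplot of N_k against k.
#' @exportS3Method ggplot2::autoplot
autoplot.degree_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$n_k)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "degree k", y = expression(N[k]))
}

#' Plot the time-binned average degree
#'
#' @param object A `degree_timecourse` from [time_binned_degree()].
#' @param ... Unused.
#' @return A ggplot of mean per-student degree over the day.
#' @exportS3Method ggplot2::autoplot
autoplot.degree_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start_s / 3600, y = .data$mean_degree)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time of day (h)", y = "mean degree per bin")
}

#' Plot a power-law fit against the empirical tail
#'
#' @param object A `power_law_fit`.
#' @param values The sample the fit came from.
#' @param ... Unused.
#' @return A log-log ggplot of the empirical survival function with the
#'   fitted tail overlaid above `x_min`.
#' @exportS3Method ggplot2::autoplot
autoplot.power_law_fit <- function(object, values, ...) {
  values <- sort(values[values > 0])
  sf <- 1 - (seq_along(values) - 1) / length(values)
  df <- tibble(x = values, sf = sf)
  p_tail <- mean(values >= object$xmin)
  fit_df <- tibble(x = seq(object$xmin, max(values), length.out = 100)) %>%
    mutate(sf = p_tail * (.data$x / object$xmin)^(object$beta + 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$sf)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = fit_df, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "duration", y = "P(X >= x)",
                  title = sprintf("Power-law fit: beta = %.2f, x_min = %g",
                                  object$beta, object$xmin))
}

#' Heat map of a contact matrix
#'
#' @param M Matrix from [contact_matrix()].
#' @return A ggplot tile map of per-pair contact rates between groups.
#' @export
plot_contact_matrix <- function(M) {
  df <- as_tibble(M, rownames = "group_a") %>%
    tidyr::pivot_longer(-"group_a", names_to = "group_b", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_a, y = .data$group_b,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "edges per pair")
}
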