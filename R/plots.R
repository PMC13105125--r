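# ggplot2 helpers for the main result types.

#' Plot a binned series
#'
#' Step/line plot of a binned count or distance series against time in
#' experiment hours; masked bins are drawn in grey.
#'
#' @param object An [binned_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hc_binned <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$hours <- (df$bin_start - df$bin_start[1]) / 3600
  ggplot2::ggplot(df, ggplot2::aes(x = hours, y = value, colour = masked)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey70"),
                                 guide = "none") +
    ggplot2::labs(x = "time (h from series start)", y = "value") +
    ggplot2::theme_minimal()
}

#' Polar plot of an hourly circadian profile
#'
#' Draws the 24-hour profile on a polar (clock-face) axis with ZT0 at the
#' top, optionally overlaying the mean resultant vector as an arrow whose
#' length is the resultant magnitude times the profile maximum.
#'
#' @param profile Tibble with columns `zt_h` (0--23) and `value`.
#' @param vector Optional `circadian_vector` to overlay.
#' @return A ggplot.
#' @export
plot_circadian_profile <- function(profile, vector = NULL) {
  stopifnot(all(c("zt_h", "value") %in% names(profile)))
  df <- profile
  df$value[is.na(df$value)] <- 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = zt_h, y = value)) +
    ggplot2::geom_col(width = 1, fill = "steelblue", alpha = 0.7) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = seq(0, 21, 3),
                                labels = paste0("ZT", seq(0, 21, 3))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(vector) && !is.na(vector$direction_zt)) {
    arrow_df <- tibble::tibble(x = vector$direction_zt,
                               yend = vector$magnitude * max(df$value))
    p <- p + ggplot2::geom_segment(
      data = arrow_df,
      ggplot2::aes(x = x, xend = x, y = 0, yend = yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      colour = "black", linewidth = 0.8)
  }
  p
}

#' Stacked daily time-budget bars
#'
#' One stacked bar per day showing the percentage of the day spent in each
#' behavior group.
#'
#' @param budgets Tibble with columns `day`, `group_label`, `pct_of_day`
#'   (as produced by the pipeline's ethogram stage).
#' @return A ggplot.
#' @export
plot_time_budget <- function(budgets) {
  stopifnot(all(c("day", "group_label", "pct_of_day") %in% names(budgets)))
  ggplot2::ggplot(budgets,
                  ggplot2::aes(x = factor(day), y = pct_of_day,
                               fill = group_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "experiment day", y = "% of day", fill = "behavior") +
    ggplot2::theme_minimal()
}

#' Daily preference differences by swap state
#'
#' Points per day, panelled by medium and coloured by which position held
#' the treat (sucrose water / fatty food), with a zero reference line. The
#' sign pattern across the two colours separates content from place
#' preference.
#'
#' @param differences Output of [group_by_swap_state()] (or the pipeline's
#'   `preference_differences` table) with a single difference column.
#' @param value Name of the difference column.
#' @return A ggplot.
#' @export
plot_preference <- function(differences,
                            value = intersect(c("difference",
                                                "diff_pos2_minus_pos1",
                                                "diff_treat_minus_regular"),
                                              names(differences))[1]) {
  stopifnot(!is.na(value),
            all(c("day", "medium", "treat_position") %in% names(differences)))
  ggplot2::ggplot(differences,
                  ggplot2::aes(x = day, y = .data[[value]],
                               colour = treat_position)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~medium, scales = "free_y") +
    ggplot2::labs(x = "experiment day", y = "daily difference (beambreaks)") +
    ggplot2::theme_minimal()
}
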