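#' Survival, risk-set and hazard figures
#'
#' Standard graphics for a post-RTP analysis: the Kaplan-Meier survivor
#' step function with its confidence ribbon and (when reached) the median
#' survival time; the daily risk-set and observed-event bars; and the
#' continuous hazard curves, coloured by stratum. Negative raw hazards are
#' clamped to zero at this plotting layer only — the underlying
#' `hazard_curve` keeps them (flagged) for diagnostics.
#'
#' @param curve A `survival_curve` ([km_fit()]) or, for [plot_hazard()],
#'   a `hazard_curve`.
#' @param max_day Last day shown (default: last observed day).
#' @param show_median Draw the median survival reference lines.
#' @return A ggplot object.
#' @export
plot_survival <- function(curve, max_day = NULL, show_median = TRUE) {
  grid <- curve_daily_grid(curve, max_day = max_day)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$day, y = .data$surv)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_step(colour = "steelblue4") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since return-to-play",
                  y = "Survival (no subsequent non-contact injury)") +
    ggplot2::theme_minimal()
  med <- median_survival(curve)
  if (show_median && !is.na(med)) {
    p <- p +
      ggplot2::geom_vline(xintercept = med, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                          colour = "grey60")
  }
  p
}

#' @rdname plot_survival
#' @export
plot_risk_set <- function(curve, max_day = NULL) {
  grid <- curve_daily_grid(curve, max_day = max_day)
  long <- tidyr::pivot_longer(
    grid[, c("day", "n_risk", "n_event")],
    cols = c("n_risk", "n_event"),
    names_to = "what", values_to = "count"
  )
  long$what <- factor(long$what, levels = c("n_risk", "n_event"),
                      labels = c("still at risk", "observed events"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$count,
                                     fill = .data$what)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c("seagreen", "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "Days since return-to-play", y = "Count") +
    ggplot2::theme_minimal()
}

#' @rdname plot_survival
#' @param clamp_negative Clamp negative fitted hazards to zero for display
#'   (default `TRUE`).
#' @export
plot_hazard <- function(curve, clamp_negative = TRUE) {
  dat <- tibble::as_tibble(curve)
  if (clamp_negative) dat$hazard <- pmax(dat$hazard, 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$hazard,
                                    colour = .data$stratum)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Days since return-to-play",
                  y = "Hazard (per-day probability of non-contact injury)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
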