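#' Polynomial regression of the cumulative hazard on time
#'
#' Least-squares polynomial (tenth degree by default) with the cumulative
#' hazard as response and days since return-to-play as explanatory
#' variable, restricted to the first `window` days. Time is internally
#' rescaled to \eqn{[0, 1]} and an orthogonal polynomial basis is used for
#' numerical conditioning; predictions are returned on the original day
#' grid, which leaves the fitted values mathematically unchanged.
#'
#' By default the response has one row per integer day `0..window`
#' carrying the right-continuous step value of \eqn{\hat H} (equal per-day
#' weighting); `grid = "event"` instead fits at day 0 plus the days where
#' \eqn{\hat H} increases (event days only).
#'
#' @param cumhaz A `cumhaz_curve` from [cumulative_hazard()], or a
#'   `survival_curve` (converted internally).
#' @param degree Polynomial degree (default 10).
#' @param window Fit window in days after RTP (default 100).
#' @param grid `"daily"` (default) or `"event"`; see Details.
#'
#' @return An object of class `cumhaz_poly`: list with `degree`, `window`,
#'   `grid`, `days` (0..window), `pred` (predicted cumulative hazard per
#'   day), the underlying `model` and the `support` points used.
#' @export
fit_cumhaz_poly <- function(cumhaz, degree = 10, window = 100,
                            grid = c("daily", "event")) {
  grid <- match.arg(grid)
  if (inherits(cumhaz, "survival_curve")) {
    cumhaz <- suppressWarnings(cumulative_hazard(cumhaz))
  }
  if (!inherits(cumhaz, "cumhaz_curve")) {
    stop("`cumhaz` must be a cumhaz_curve or survival_curve.")
  }
  stopifnot(degree >= 1, window >= 1)
  keep <- cumhaz$time <= window & is.finite(cumhaz$cumhaz)
  times <- cumhaz$time[keep]
  h <- cumhaz$cumhaz[keep]
  if (grid == "daily") {
    days <- 0:window
    y <- approx(x = c(0, times), y = c(0, h), xout = days,
                method = "constant", f = 0, rule = 2)$y
  } else {
    rises <- c(TRUE, diff(h) > 0)
    days <- c(0, times[rises])
    y <- c(0, h[rises])
  }
  if (length(unique(days)) < degree + 1) {
    stop(sprintf(
      paste0("only %d distinct support day(s) in the first %d days; ",
             "need degree + 1 = %d. Lower `degree` or widen `window`."),
      length(unique(days)), window, degree + 1
    ))
  }
  x <- days / window
  fit <- lm(y ~ poly(x, degree))
  pred_days <- 0:window
  pred <- as.numeric(predict(fit, newdata = data.frame(x = pred_days / window)))
  structure(
    list(degree = degree, window = window, grid = grid,
         days = pred_days, pred = pred, model = fit,
         support = tibble::tibble(day = days, cumhaz = y)),
    class = "cumhaz_poly"
  )
}

#' @export
print.cumhaz_poly <- function(x, ...) {
  cat(sprintf(
    "<cumhaz_poly: degree %d on days 0..%d (%s grid), %d support points>\n",
    x$degree, x$window, x$grid, nrow(x$support)
  ))
  invisible(x)
}

#' Continuous hazard curve from a fitted cumulative-hazard polynomial
#'
#' The per-day hazard is the rate of change of the predicted cumulative
#' hazard on the unit-day grid:
#' \eqn{h(d) = \hat H_{pred}(d) - \hat H_{pred}(d - 1)} for
#' `d = 1..window`. Raw values are preserved; negative values (possible for
#' a polynomial fit) are flagged, not clamped.
#'
#' @param model A `cumhaz_poly` from [fit_cumhaz_poly()].
#' @param stratum Label attached to the curve (default `"overall"`).
#' @return A tibble of class `hazard_curve`: `stratum`, `day` (1..window),
#'   `hazard`, `negative_flag`.
#' @export
hazard_curve <- function(model, stratum = "overall") {
  stopifnot(inherits(model, "cumhaz_poly"))
  h <- diff(model$pred)
  out <- tibble::tibble(
    stratum = stratum, day = model$days[-1], hazard = h,
    negative_flag = h < 0
  )
  class(out) <- c("hazard_curve", class(out))
  out
}

#' Run the full hazard-retrieval pipeline on an episode table
#'
#' Convenience wrapper chaining [km_fit()], [cumulative_hazard()],
#' [fit_cumhaz_poly()] and [hazard_curve()].
#'
#' @param episodes Episode tibble.
#' @param degree,window,grid Passed to [fit_cumhaz_poly()].
#' @param level Confidence level for the survival bands.
#' @param stratum Label for the resulting hazard curve.
#' @return List with `km` (survival_curve), `cumhaz`, `model` and `hazard`.
#' @export
hazard_pipeline <- function(episodes, degree = 10, window = 100,
                            grid = "daily", level = 0.95,
                            stratum = "overall") {
  km <- km_fit(episodes, level = level)
  ch <- suppressWarnings(cumulative_hazard(km))
  model <- fit_cumhaz_poly(ch, degree = degree, window = window, grid = grid)
  list(km = km, cumhaz = ch, model = model,
       hazard = hazard_curve(model, stratum = stratum))
}

#' Stratified continuous hazard curves
#'
#' Applies the full Kaplan-Meier, cumulative-hazard, polynomial and
#' first-difference pipeline independently within each stratum of index
#' severity or playing position. Strata with fewer than `degree + 1`
#' distinct event days inside the window are skipped with a warning.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param by `"severity"` or `"position"`.
#' @param degree,window,grid Passed to [fit_cumhaz_poly()].
#' @return A `hazard_curve` tibble with one block of rows per fitted
#'   stratum; the per-stratum `cumhaz_poly` models are attached as the
#'   `models` attribute.
#' @export
stratified_curves <- function(episodes, by = c("severity", "position"),
                              degree = 10, window = 100, grid = "daily") {
  by <- match.arg(by)
  col <- switch(by, severity = "index_severity", position = "position")
  if (!col %in% names(episodes)) {
    stop("episodes lack the `", col, "` column required for by = '", by, "'.")
  }
  vals <- episodes[[col]]
  levs <- if (is.factor(vals)) levels(vals) else sort(unique(as.character(vals)))
  curves <- list()
  models <- list()
  for (lev in levs) {
    sub <- episodes[as.character(vals) == lev, , drop = FALSE]
    ev_days <- unique(sub$time_days[sub$event & sub$time_days <= window])
    if (length(ev_days) < degree + 1) {
      warning(sprintf(
        "stratum '%s' skipped: %d distinct event day(s) within %d days (< %d).",
        lev, length(ev_days), window, degree + 1
      ))
      next
    }
    run <- hazard_pipeline(sub, degree = degree, window = window,
                           grid = grid, stratum = lev)
    curves[[lev]] <- run$hazard
    models[[lev]] <- run$model
  }
  if (!length(curves)) stop("no stratum had enough event days to fit.")
  out <- dplyr::bind_rows(curves)
  class(out) <- c("hazard_curve", class(tibble::tibble()))
  attr(out, "models") <- models
  out
}

#' Half-time of the post-RTP excess hazard
#'
#' Quantifies how quickly the excess over the late plateau decays: the
#' plateau is the mean hazard over `plateau_window` (days 60-100 by
#' default), the peak is the maximum over the days before the plateau
#' window, and the half-time is the first day at or after the peak where
#' the hazard has dropped to within half of the peak-over-plateau excess.
#' Returns `NA` when there is no meaningful excess — the peak does not
#' exceed the plateau by at least `min_excess` (a relative margin that
#' keeps sampling noise on a flat curve from being read as an excess).
#'
#' @param curve A single-stratum `hazard_curve`.
#' @param plateau_window Day interval `c(lo, hi)` treated as the baseline
#'   plateau (default `c(60, 100)`).
#' @param min_excess Minimum relative excess of the peak over the plateau
#'   for a half-time to be declared (default 0.25).
#' @return Half-time in days, or `NA_real_`.
#' @export
excess_half_time <- function(curve, plateau_window = c(60, 100),
                             min_excess = 0.25) {
  stopifnot(is.data.frame(curve), all(c("day", "hazard") %in% names(curve)))
  if ("stratum" %in% names(curve) && length(unique(curve$stratum)) > 1) {
    stop("`curve` holds several strata; pass one stratum at a time.")
  }
  lo <- plateau_window[1]
  hi <- plateau_window[2]
  if (max(curve$day) < hi) {
    stop("curve does not cover the plateau window (needs days up to ", hi, ").")
  }
  plateau <- mean(curve$hazard[curve$day >= lo & curve$day <= hi])
  pre <- curve[curve$day >= 1 & curve$day <= lo, , drop = FALSE]
  peak <- max(pre$hazard)
  if (peak <= plateau + min_excess * abs(plateau)) return(NA_real_)
  peak_day <- pre$day[which.max(pre$hazard)]
  half_level <- plateau + (peak - plateau) / 2
  after <- curve[curve$day >= peak_day, , drop = FALSE]
  hit <- which(after$hazard <= half_level)
  if (!length(hit)) return(NA_real_)
  as.numeric(after$day[hit[1]])
}

#' Summary statistics of one or more hazard curves
#'
#' Per stratum: the hazard on day 1, the peak and its day (searched before
#' the plateau window), the plateau level, the day-1-to-plateau ratio and
#' the excess half-time of [excess_half_time()].
#'
#' @param curve A `hazard_curve` (possibly several strata).
#' @param plateau_window,min_excess As in [excess_half_time()].
#' @return A tibble with one row per stratum.
#' @export
hazard_summary <- function(curve, plateau_window = c(60, 100),
                           min_excess = 0.25) {
  stopifnot(is.data.frame(curve))
  strata <- unique(curve$stratum)
  purrr::map_dfr(strata, function(s) {
    cv <- curve[curve$stratum == s, , drop = FALSE]
    lo <- plateau_window[1]
    plateau <- mean(cv$hazard[cv$day >= lo & cv$day <= plateau_window[2]])
    pre <- cv[cv$day >= 1 & cv$day <= lo, , drop = FALSE]
    tibble::tibble(
      stratum = s,
      h_day1 = cv$hazard[cv$day == 1],
      peak = max(pre$hazard),
      peak_day = pre$day[which.max(pre$hazard)],
      plateau = plateau,
      ratio_day1 = h_day1 / plateau,
      half_time = excess_half_time(cv, plateau_window, min_excess)
    )
  })
}

#' Write hazard curves as CSV
#'
#' Columns: `stratum, day, hazard, negative_flag (0/1)`.
#'
#' @param curve A `hazard_curve`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hazard_csv <- function(curve, path) {
  out <- tibble::as_tibble(curve)
  out$negative_flag <- as.integer(out$negative_flag)
  readr::write_csv(out, path)
  invisible(path)
}
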