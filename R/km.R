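#' Kaplan-Meier product-limit fit on the daily time grid
#'
#' From-scratch product-limit estimator
#' \eqn{\hat S(t_j) = \prod_{t_i \le t_j} (1 - d_i / n_i)} over the distinct
#' episode days, with events processed before censorings at tied days (both
#' count into the risk set at their day; both leave it afterwards).
#' Greenwood variances and complementary log-log confidence bands are
#' attached via [greenwood_band()].
#'
#' @param episodes Episode tibble with at least `time_days` (positive
#'   integers) and `event` (logical) columns, e.g. from [build_episodes()].
#' @param level Coverage probability of the confidence band (default 0.95).
#'
#' @return An object of class `survival_curve`: a list with `data` (tibble
#'   with one row per distinct day: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err`, `lower`, `upper` and the cumulative Greenwood sum
#'   `gw`), the initial risk-set size `n`, the band `level`, and an
#'   `all_censored` flag.
#' @export
#' @examples
#' ep <- tibble::tibble(time_days = c(1, 2, 3, 10),
#'                      event = c(TRUE, FALSE, TRUE, FALSE))
#' km_fit(ep)
km_fit <- function(episodes, level = 0.95) {
  if (!is.data.frame(episodes) ||
      !all(c("time_days", "event") %in% names(episodes))) {
    stop("`episodes` needs columns `time_days` and `event`.")
  }
  if (nrow(episodes) == 0) stop("cannot fit a survival curve to 0 episodes.")
  t <- as.numeric(episodes$time_days)
  ev <- as.logical(episodes$event)
  if (any(is.na(t)) || any(t < 1) || any(t != floor(t))) {
    stop("`time_days` must be positive integer days.")
  }
  n0 <- length(t)
  tt <- sort(unique(t))
  d <- tabulate(match(t[ev], tt), nbins = length(tt))
  cns <- tabulate(match(t[!ev], tt), nbins = length(tt))
  n_risk <- n0 - c(0, cumsum(d + cns))[seq_along(tt)]
  surv <- cumprod(1 - d / n_risk)
  gw <- cumsum(ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0))
  std_err <- ifelse(surv > 0, surv * sqrt(gw), 0)

  all_censored <- sum(d) == 0L
  if (all_censored) {
    warning("all episodes are censored; survival is identically 1.")
  }
  curve <- structure(
    list(
      data = tibble::tibble(
        time = tt, n_risk = as.integer(n_risk), n_event = as.integer(d),
        n_censor = as.integer(cns), surv = surv, std_err = std_err, gw = gw,
        lower = NA_real_, upper = NA_real_
      ),
      n = n0, level = level, all_censored = all_censored
    ),
    class = "survival_curve"
  )
  greenwood_band(curve, level)
}

#' Greenwood confidence bands on the complementary log-log scale
#'
#' Pointwise bands from the Greenwood variance
#' \eqn{\widehat{Var}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t}
#' d_i / (n_i (n_i - d_i))}, transformed through
#' \eqn{\log(-\log \hat S)} so the band respects \eqn{[0, 1]}:
#' the limits are \eqn{\hat S^{\exp(\pm z \, se)}} with
#' \eqn{se = \sqrt{\sum d_i/(n_i(n_i-d_i))} / |\log \hat S|}. Where
#' \eqn{\hat S \in \{0, 1\}} the band collapses to the point estimate.
#'
#' @param curve A `survival_curve` from [km_fit()].
#' @param level Coverage probability in (0, 1).
#' @return The curve with `lower` / `upper` columns (and `level`) updated.
#' @export
greenwood_band <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1.")
  }
  dat <- curve$data
  z <- qnorm(1 - (1 - level) / 2)
  s <- dat$surv
  interior <- s > 0 & s < 1
  lower <- s
  upper <- s
  se_cll <- sqrt(dat$gw[interior]) / abs(log(s[interior]))
  lower[interior] <- s[interior]^exp(z * se_cll)
  upper[interior] <- s[interior]^exp(-z * se_cll)
  dat$lower <- pmax(pmin(lower, 1), 0)
  dat$upper <- pmax(pmin(upper, 1), 0)
  curve$data <- dat
  curve$level <- level
  curve
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve: %d episodes, %d events, %d censored, %g%% band>\n",
    x$n, sum(x$data$n_event), sum(x$data$n_censor), 100 * x$level
  ))
  med <- median_survival(x)
  cat(sprintf("  median survival: %s\n",
              if (is.na(med)) "not reached" else sprintf("%.2f days", med)))
  print(x$data[setdiff(names(x$data), "gw")], ...)
  invisible(x)
}

#' Cumulative hazard from a survival curve
#'
#' \eqn{\hat H(t_j) = -\ln \hat S_{KM}(t_j)}, elementwise at the distinct
#' episode days. Points where the survival estimate has reached 0 (infinite
#' cumulative hazard) are dropped with a warning.
#'
#' @param curve A `survival_curve` from [km_fit()].
#' @return An object of class `cumhaz_curve`: a tibble `time`, `cumhaz`,
#'   carrying `n` (initial risk set) and `max_time` as attributes.
#' @export
cumulative_hazard <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  dat <- curve$data
  zero <- dat$surv <= 0
  if (any(zero)) {
    warning(sprintf(
      "%d day(s) with S = 0 dropped from the cumulative hazard.", sum(zero)
    ))
  }
  out <- tibble::tibble(time = dat$time[!zero],
                        cumhaz = -log(dat$surv[!zero]))
  structure(out, n = curve$n, max_time = max(dat$time),
            class = c("cumhaz_curve", class(out)))
}

#' Daily grid view of a survival curve
#'
#' Expands the step function onto every integer day `0..max_day`,
#' carrying values rightwards (right-continuous), so downstream fitting has
#' one row per day. `n_risk` at day `d` is the number of episodes with
#' `time_days >= d`; `n_event` / `n_censor` are the counts at exactly day
#' `d`; `cumhaz` is `-log(surv)` (`Inf` where survival has reached 0).
#'
#' @param curve A `survival_curve`.
#' @param max_day Last day of the grid (default: last observed day).
#' @return A tibble `day`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `lower`, `upper`, `cumhaz`.
#' @export
curve_daily_grid <- function(curve, max_day = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  dat <- curve$data
  if (is.null(max_day)) max_day <- max(dat$time)
  days <- 0:max_day
  step <- function(y, y0) {
    approx(x = c(0, dat$time), y = c(y0, y), xout = days,
           method = "constant", f = 0, rule = 2)$y
  }
  removed <- cumsum(dat$n_event + dat$n_censor)
  # removals at day d happen during day d: still at risk at its start
  n_risk <- c(curve$n, (curve$n - step(removed, 0))[-length(days)])
  ev <- integer(length(days))
  cn <- integer(length(days))
  inside <- dat$time <= max_day
  ev[dat$time[inside] + 1L] <- dat$n_event[inside]
  cn[dat$time[inside] + 1L] <- dat$n_censor[inside]
  surv <- step(dat$surv, 1)
  tibble::tibble(
    day = days, n_risk = as.integer(n_risk), n_event = ev, n_censor = cn,
    surv = surv, lower = step(dat$lower, 1), upper = step(dat$upper, 1),
    cumhaz = ifelse(surv > 0, -log(surv), Inf)
  )
}

#' Median survival time by linear interpolation
#'
#' On the daily grid, with `m` the last day at which the survival estimate
#' is still above 0.5, the median is interpolated linearly across the unit
#' day in which the curve crosses one half:
#' \eqn{T = m + (\hat S(t_m) - 0.5) / (\hat S(t_m) - \hat S(t_{m+1}))}.
#' Returns `NA` when the curve never reaches 0.5 within the observed range.
#'
#' @param curve A `survival_curve`.
#' @return Median survival in days (possibly fractional), or `NA_real_`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  grid <- curve_daily_grid(curve)
  below <- which(grid$surv <= 0.5)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  m <- grid$day[j - 1]
  s_m <- grid$surv[j - 1]
  s_m1 <- grid$surv[j]
  m + (s_m - 0.5) / (s_m - s_m1)
}

#' Write the per-day survival curve as CSV
#'
#' Columns: `day, n_at_risk, n_events, n_censored, S, ci_lower, ci_upper, H`.
#'
#' @param curve A `survival_curve`.
#' @param path File path.
#' @param max_day Last day of the grid (default: last observed day).
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, max_day = NULL) {
  grid <- curve_daily_grid(curve, max_day = max_day)
  out <- tibble::tibble(
    day = grid$day, n_at_risk = grid$n_risk, n_events = grid$n_event,
    n_censored = grid$n_censor, S = grid$surv, ci_lower = grid$lower,
    ci_upper = grid$upper, H = grid$cumhaz
  )
  readr::write_csv(out, path)
  invisible(path)
}
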