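test_that("product-limit estimate matches hand computation on small tables", {
  # single episode, event at day 5
  km1 <- km_fit(make_episodes(5, TRUE))
  expect_equal(km1$data$surv, 0)
  expect_equal(km1$data$time, 5)
  # event d1, censor d2, event d3, censor d10
  km2 <- km_fit(make_episodes(c(1, 2, 3, 10), c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(km2$data$surv, c(3 / 4, 3 / 4, 0.375, 0.375))
  expect_equal(km2$data$n_risk, c(4L, 3L, 2L, 1L))
  # with no censoring the KM curve is 1 - ECDF of the event times
  t <- c(2, 2, 5, 7, 7, 7, 9)
  km3 <- km_fit(make_episodes(t, rep(TRUE, length(t))))
  ecdf_t <- stats::ecdf(t)
  expect_equal(km3$data$surv, 1 - ecdf_t(km3$data$time))
})

test_that("product-limit matches brute force and the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(20240901)
  for (i in 1:200) {
    ep <- random_episode_table()
    km <- suppressWarnings(km_fit(ep))
    expect_equal(km$data$surv,
                 brute_km(ep$time_days, ep$event, km$data$time),
                 tolerance = 1e-12)
    fit <- survival::survfit(
      survival::Surv(ep$time_days, ep$event) ~ 1, conf.type = "none"
    )
    sf <- summary(fit, times = km$data$time)
    expect_equal(km$data$surv, sf$surv, tolerance = 1e-12)
    expect_equal(km$data$n_risk, sf$n.risk, tolerance = 1e-12)
    expect_equal(km$data$n_event, sf$n.event, tolerance = 1e-12)
  }
})

test_that("survival curves are monotone with a consistent risk-set recursion", {
  set.seed(4711)
  for (i in 1:40) {
    ep <- random_episode_table()
    km <- suppressWarnings(km_fit(ep))
    d <- km$data
    expect_true(all(diff(d$surv) <= 1e-15))
    expect_true(all(d$surv >= 0 & d$surv <= 1))
    if (nrow(d) > 1) {
      expect_equal(d$n_risk[-1],
                   (d$n_risk - d$n_event - d$n_censor)[-nrow(d)])
    }
    expect_true(all(d$lower <= d$surv + 1e-12 & d$surv <= d$upper + 1e-12))
    h <- suppressWarnings(cumulative_hazard(km))
    expect_true(all(diff(h$cumhaz) >= -1e-15))
  }
})

test_that("Greenwood variance and bands follow the closed form", {
  # n = 2, one event at day 1: S = 0.5, Var = 0.25 * 1/(2*1) = 0.125
  km <- km_fit(make_episodes(c(1, 2), c(TRUE, FALSE)))
  expect_equal(km$data$std_err[1]^2, 0.125)
  skip_if_not_installed("survival")
  ep <- ref_decay_cohort()$episodes
  km2 <- km_fit(ep)
  fit <- survival::survfit(survival::Surv(ep$time_days, ep$event) ~ 1)
  sf <- summary(fit, times = km2$data$time)
  # summary.survfit's std.err is the Greenwood se of S itself
  keep <- km2$data$surv > 0
  expect_equal(km2$data$std_err[keep], sf$std.err[keep], tolerance = 1e-10)
})

test_that("confidence bands respect [0,1], collapse without events, and shrink with level", {
  no_event <- suppressWarnings(km_fit(make_episodes(c(3, 6), c(FALSE, FALSE))))
  expect_true(no_event$all_censored)
  expect_true(all(no_event$data$lower == 1 & no_event$data$upper == 1))

  ep <- make_episodes(c(1, 2, 4, 4, 9, 12), c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  km <- km_fit(ep, level = 0.95)
  narrow <- greenwood_band(km, level = 1e-9)
  expect_equal(narrow$data$lower, km$data$surv, tolerance = 1e-6)
  expect_equal(narrow$data$upper, km$data$surv, tolerance = 1e-6)
  wide <- greenwood_band(km, level = 0.999)
  interior <- km$data$surv > 0 & km$data$surv < 1
  expect_true(all(wide$data$lower[interior] < km$data$lower[interior]))
  expect_error(greenwood_band(km, level = 1.2), "level")
})

test_that("cumulative hazard is the exact negative log of survival", {
  km <- km_fit(make_episodes(c(1, 2, 3, 10), c(TRUE, FALSE, TRUE, FALSE)))
  h <- cumulative_hazard(km)
  expect_equal(h$cumhaz, -log(c(3 / 4, 3 / 4, 0.375, 0.375)))
  expect_equal(exp(-h$cumhaz), km$data$surv, tolerance = 1e-12)
  # S = 1 -> H = 0; S = 0.5 -> H = ln 2; S = 0.375 -> H ~ 0.9808
  expect_equal(-log(0.5), 0.6931472, tolerance = 1e-7)
  expect_equal(h$cumhaz[3], 0.9808293, tolerance = 1e-7)
  # points at S = 0 are dropped with a warning
  km0 <- km_fit(make_episodes(c(2, 5), c(TRUE, TRUE)))
  expect_warning(h0 <- cumulative_hazard(km0), "S = 0")
  expect_equal(h0$time, 2)
})

test_that("the daily grid carries step values rightwards", {
  km <- km_fit(make_episodes(c(2, 5, 9), c(TRUE, FALSE, TRUE)))
  g <- curve_daily_grid(km, max_day = 12)
  expect_equal(g$day, 0:12)
  expect_equal(g$surv[g$day < 2], c(1, 1))
  expect_equal(g$surv[g$day %in% 2:4], rep(2 / 3, 3))
  expect_equal(g$n_risk[g$day %in% 0:2], c(3L, 3L, 3L))
  expect_equal(g$n_risk[g$day == 3], 2L)
  expect_equal(g$n_event[g$day == 9], 1L)
  expect_equal(g$n_risk[g$day == 12], 0L)
})

test_that("median survival interpolates linearly across the half-survival day", {
  km <- km_fit(median_toy_episodes())
  g <- curve_daily_grid(km)
  expect_equal(g$surv[g$day == 10], 0.6)
  expect_equal(g$surv[g$day == 11], 0.4)
  expect_equal(median_survival(km), 10.5)
  # full drop within one day lands halfway
  km2 <- km_fit(make_episodes(c(7, 7), c(TRUE, TRUE)))
  expect_equal(median_survival(km2), 6.5)
  # all censored: never crosses 0.5
  km3 <- suppressWarnings(km_fit(make_episodes(c(5, 8), c(FALSE, FALSE))))
  expect_true(is.na(median_survival(km3)))
})

test_that("with no censoring the median lies between the middle order statistics", {
  set.seed(99)
  for (i in 1:25) {
    t <- sample.int(40, 12, replace = TRUE)
    km <- km_fit(make_episodes(t, rep(TRUE, 12)))
    med <- median_survival(km)
    o <- sort(t)
    expect_gte(med, o[6] - 1)   # crossing interpolates inside the day before
    expect_lte(med, o[7])
  }
})

test_that("per-day curve CSV exports the documented schema", {
  km <- km_fit(make_episodes(c(1, 2, 3, 10), c(TRUE, FALSE, TRUE, FALSE)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(km, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(out, c("day", "n_at_risk", "n_events", "n_censored",
                      "S", "ci_lower", "ci_upper", "H"))
  expect_identical(nrow(out), 11L)
  expect_equal(out$S[out$day == 3], 0.375)
  expect_equal(out$H[out$day == 10], -log(0.375))
})
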