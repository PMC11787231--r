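as_cumhaz <- function(time, cumhaz) {
  out <- tibble::tibble(time = time, cumhaz = cumhaz)
  structure(out, n = length(time), max_time = max(time),
            class = c("cumhaz_curve", class(out)))
}

test_that("polynomial fit reproduces polynomial cumulative hazards exactly", {
  # linear H: any degree interpolates it
  lin <- as_cumhaz(1:100, 0.01 * (1:100))
  m <- fit_cumhaz_poly(lin, degree = 10, window = 100)
  expect_equal(m$pred, 0.01 * (0:100), tolerance = 1e-9)
  hz <- hazard_curve(m)
  expect_equal(hz$hazard, rep(0.01, 100), tolerance = 1e-9)
  expect_false(any(hz$negative_flag))
  # quadratic H: per-day hazard equals the exact first difference,
  # i.e. the analytic derivative at the midpoint of each day
  quad <- as_cumhaz(1:100, 1e-4 * (1:100)^2)
  mq <- fit_cumhaz_poly(quad, degree = 10, window = 100)
  hq <- hazard_curve(mq)
  d <- hq$day
  expect_equal(hq$hazard, 1e-4 * (d^2 - (d - 1)^2), tolerance = 1e-9)
  expect_equal(hq$hazard, 2e-4 * (d - 0.5), tolerance = 1e-9)
  # two support points, degree 1: the exact line through both
  two <- as_cumhaz(10, 0.3)
  m2 <- fit_cumhaz_poly(two, degree = 1, window = 10, grid = "event")
  expect_equal(m2$pred, 0.03 * (0:10), tolerance = 1e-12)
})

test_that("underdetermined fits are rejected with guidance", {
  few <- as_cumhaz(c(3, 8), c(0.1, 0.2))
  expect_error(fit_cumhaz_poly(few, degree = 10, window = 100, grid = "event"),
               "Lower `degree`")
})

test_that("the telescoping identity holds for every fitted model", {
  models <- list(
    fit_cumhaz_poly(as_cumhaz(1:100, 0.01 * sqrt(1:100)), degree = 10),
    fit_cumhaz_poly(suppressWarnings(cumulative_hazard(const_cohort()$run$km)),
                    degree = 10),
    ref_decay_cohort()$run$model
  )
  for (m in models) {
    hz <- hazard_curve(m)
    expect_equal(sum(hz$hazard), m$pred[length(m$pred)] - m$pred[1],
                 tolerance = 1e-12)
  }
})

test_that("a constant-hazard cohort is recovered flat at the generative rate", {
  cc <- const_cohort()
  m <- cc$run$model
  mean_h <- (m$pred[96] - m$pred[5]) / 91          # mean over days 5..95
  exposure <- sum(pmin(pmax(0, cc$episodes$time_days - 4), 91))
  se <- sqrt(0.01 / exposure)                      # Poisson MC error
  expect_lt(abs(mean_h - 0.01), 3 * se)
  expect_true(is.na(excess_half_time(cc$run$hazard)))
})

test_that("the exponential-decay excess is recovered from a simulated cohort", {
  run <- ref_decay_cohort()$run
  hs <- hazard_summary(run$hazard)
  expect_gt(hs$ratio_day1, 1.3)
  expect_lt(hs$ratio_day1, 2.6)
  expect_false(is.na(hs$half_time))
})

test_that("halving the polynomial degree leaves the recovered half-time stable", {
  ep <- big_decay_episodes(1)
  h10 <- excess_half_time(hazard_pipeline(ep, degree = 10)$hazard)
  h6 <- excess_half_time(hazard_pipeline(ep, degree = 6)$hazard)
  expect_lt(abs(h10 - h6) / h10, 0.2)
})

test_that("excess half-time matches the closed form and detects flat curves", {
  # h(t) = 0.005 (1 + 2^(-t/25)): the defined plateau (mean over days
  # 60-100) retains residual excess, so the half-crossing lands on day 22
  grid <- tibble::tibble(stratum = "truth", day = 1:100,
                         hazard = 0.005 * (1 + 2^(-(1:100) / 25)),
                         negative_flag = FALSE)
  expect_equal(excess_half_time(grid), 22)
  # constant and monotonically increasing curves have no excess to halve
  flat <- tibble::tibble(stratum = "flat", day = 1:100, hazard = 0.004)
  expect_true(is.na(excess_half_time(flat)))
  rising <- tibble::tibble(stratum = "up", day = 1:100,
                           hazard = 0.004 + 1e-5 * (1:100))
  expect_true(is.na(excess_half_time(rising)))
  short <- grid[grid$day <= 80, ]
  expect_error(excess_half_time(short), "plateau window")
})

test_that("stratified curves discriminate a delayed severe peak", {
  dp <- delayed_peak_cohort()
  sc <- stratified_curves(dp$episodes, by = "severity")
  hs <- hazard_summary(sc)
  expect_setequal(hs$stratum, c("minimal", "mild", "moderate", "severe"))
  expect_gt(hs$peak_day[hs$stratum == "severe"],
            hs$peak_day[hs$stratum == "minimal"])
  # a single stratum reproduces the unstratified pipeline
  sub <- dp$episodes[dp$episodes$index_severity == "severe", ]
  solo <- hazard_pipeline(sub, stratum = "severe")$hazard
  expect_equal(sc$hazard[sc$stratum == "severe"], solo$hazard)
})

test_that("strata without enough event days are skipped with a warning", {
  ep <- ref_decay_cohort()$episodes
  rich <- ep[ep$index_severity == "severe", ]
  poor <- ep[ep$index_severity == "minimal", ][1:5, ]
  both <- rbind(rich, poor)
  suppressWarnings(
    expect_warning(sc <- stratified_curves(both, by = "severity"), "skipped")
  )
  expect_identical(unique(sc$stratum), "severe")
  # nothing fittable at all -> error
  suppressWarnings(
    expect_error(stratified_curves(poor, by = "severity"), "no stratum")
  )
  expect_error(stratified_curves(ep, by = "diagnosis"), "arg")
})

test_that("hazard CSV exports flag negative fitted values instead of clamping", {
  hz <- tibble::tibble(stratum = "overall", day = 1:3,
                       hazard = c(0.01, -0.002, 0.005),
                       negative_flag = c(FALSE, TRUE, FALSE))
  class(hz) <- c("hazard_curve", class(tibble::tibble()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hazard_csv(hz, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(out$hazard[2], -0.002)
  expect_equal(out$negative_flag, c(0L, 1L, 0L))
})
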