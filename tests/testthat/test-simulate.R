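test_that("simulation is deterministic and honours basic contracts", {
  cfg <- sim_config(rng_seed = 42, n_players = 120)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_gt(nrow(a), 0)

  empty <- simulate_cohort(sim_config(rng_seed = 1, n_players = 0))
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("player_id", "position", "season", "injury_date",
                        "rtp_date", "contact", "time_loss_days"))
})

test_that("generated records satisfy the injury-record invariants", {
  cfg <- sim_config(rng_seed = 9, n_players = 300)
  rec <- simulate_cohort(cfg)
  expect_true(all(rec$rtp_date > rec$injury_date))
  expect_identical(rec$time_loss_days,
                   as.integer(rec$rtp_date - rec$injury_date))
  # every injury falls inside a configured season interval
  cal <- cfg$season_calendar
  in_season <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(cal))) {
    in_season <- in_season |
      (rec$injury_date >= cal$start[i] & rec$injury_date <= cal$last_match[i])
  }
  expect_true(all(in_season))
  expect_true(all(rec$season %in% cal$season))
  # time losses respect the configured per-category day ranges
  sev <- categorize_severity(rec$time_loss_days)
  for (lev in levels(sev)) {
    r <- cfg$severity_duration_ranges[[lev]]
    tl <- rec$time_loss_days[sev == lev]
    expect_true(all(tl >= r[1] & tl <= r[2]))
  }
})

test_that("position mix follows the configured weights within binomial error", {
  cfg <- sim_config(rng_seed = 5, n_players = 3000)
  rec <- simulate_cohort(cfg)
  players <- dplyr::distinct(rec, player_id, position)
  n <- nrow(players)
  for (pos in names(cfg$position_weights)) {
    p <- cfg$position_weights[[pos]]
    share <- mean(players$position == pos)
    expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("constant-hazard cohort reproduces the exponential waiting-time law", {
  cc <- const_cohort()
  ep <- cc$episodes
  # pooled per-day event rate across all post-RTP exposure ~ lambda0
  lam0 <- 0.01
  rate <- sum(ep$event) / sum(ep$time_days)
  se <- sqrt(lam0 / sum(ep$time_days))
  expect_lt(abs(rate - lam0), 3 * se)
  # among episodes with >= 69 days of possible follow-up, the fraction
  # re-injured within 69 days is 1 - 0.99^69 ~ 0.5
  cal <- long_season_calendar()
  open <- ep[as.numeric(cal$last_match - ep$rtp_date) >= 69, , drop = FALSE]
  expect_gt(nrow(open), 2000)
  frac <- mean(open$event & open$time_days <= 69)
  p_true <- 1 - 0.99^69
  expect_lt(abs(frac - p_true),
            3 * sqrt(p_true * (1 - p_true) / nrow(open)))
})

test_that("gamma frailty produces overdispersed injury counts", {
  cfg <- sim_config(rng_seed = 77, n_players = 800, frailty_shape = 2)
  rec <- simulate_cohort(cfg)
  counts <- as.numeric(table(factor(rec$player_id,
                                    levels = sprintf("P%05d", 1:800))))
  expect_gt(stats::var(counts), mean(counts))
})

test_that("injury-record CSV round-trips losslessly", {
  rec <- simulate_cohort(sim_config(rng_seed = 3, n_players = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_injury_csv(rec, path)
  back <- read_injury_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(), "rng_seed")
  expect_error(sim_config(rng_seed = 1, baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(rng_seed = 1, severity_probs = c(minimal = 0.5, mild = 0.5,
                                                           moderate = 0.2, severe = 0.2)),
               "severity_probs")
  expect_error(sim_config(rng_seed = 1, contact_prob = 1.5), "contact_prob")
  bad_cal <- tibble::tibble(season = c("a", "b"),
                            start = as.Date(c("2015-08-01", "2015-01-01")),
                            last_match = as.Date(c("2016-05-01", "2015-06-01")))
  expect_error(sim_config(rng_seed = 1, season_calendar = bad_cal))
})

test_that("YAML config round-trips, and a missing seed is diagnosed", {
  cfg <- sim_config(rng_seed = 11, n_players = 40, contact_prob = 0.2,
                    excess_params = list(
                      minimal = exp_decay(0.5, 20), mild = exp_decay(),
                      moderate = delayed_peak(1, 25, 5),
                      severe = delayed_peak(1.5, 30, 12)
                    ))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$rng_seed, cfg$rng_seed)
  expect_equal(back$contact_prob, cfg$contact_prob)
  expect_equal(back$excess_params, cfg$excess_params)
  expect_equal(back$season_calendar, cfg$season_calendar)
  expect_identical(simulate_cohort(back), simulate_cohort(cfg))

  noseed <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_players: 10", noseed)
  expect_error(read_sim_config(noseed), "rng_seed")
})
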