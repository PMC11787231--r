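# Shared fixtures. Heavy simulations are built once per test run and cached,
# so several test files can reuse the same cohorts.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# episode table shorthand for survival-core tests
make_episodes <- function(time, event) {
  tibble::tibble(time_days = as.integer(time), event = as.logical(event))
}

# brute-force product-limit recomputation (independent of km_fit internals):
# S(t) = prod over distinct event times u <= t of (1 - d(u)/n(u)),
# n(u) = #episodes with time >= u
brute_km <- function(time, event, at) {
  vapply(at, function(u) {
    evs <- sort(unique(time[event & time <= u]))
    prod(vapply(evs, function(v) {
      1 - sum(time == v & event) / sum(time >= v)
    }, numeric(1)))
  }, numeric(1))
}

flat_excess <- function(amplitude = 0) {
  lapply(
    stats::setNames(nm = c("minimal", "mild", "moderate", "severe")),
    function(x) exp_decay(amplitude = amplitude, half_time = 25)
  )
}

decay_excess <- function() flat_excess(amplitude = 1)

long_season_calendar <- function() {
  tibble::tibble(season = "long",
                 start = as.Date("2014-08-01"),
                 last_match = as.Date("2017-07-31"))
}

# constant-hazard cohort: amplitude 0 (hazard identically lambda0 = 0.01/day),
# one long season, no contact injuries, homogeneous players
const_cohort <- function() {
  fixture("const_cohort", function() {
    cal <- long_season_calendar()
    cfg <- sim_config(
      rng_seed = 101, n_players = 1500, season_calendar = cal,
      frailty_shape = Inf, baseline_hazard = 0.01, contact_prob = 0,
      excess_params = flat_excess(0)
    )
    records <- simulate_cohort(cfg)
    episodes <- suppressWarnings(build_episodes(records, cal))
    list(config = cfg, records = records, episodes = episodes,
         run = hazard_pipeline(episodes))
  })
}

# reference exponential-decay cohort at study scale (single seed), used by
# module-level tests; the multi-seed recovery study re-simulates per seed
ref_decay_cohort <- function() {
  fixture("ref_decay_cohort", function() {
    cfg <- sim_config(
      rng_seed = 1, n_players = 2000, frailty_shape = Inf,
      baseline_hazard = 0.005, excess_params = decay_excess()
    )
    records <- simulate_cohort(cfg)
    episodes <- suppressWarnings(build_episodes(records))
    list(config = cfg, records = records, episodes = episodes,
         run = hazard_pipeline(episodes))
  })
}

# large exponential-decay cohort: Monte-Carlo error small enough that the
# fitted day-1 ratio and half-time reflect the method, not sampling noise
big_decay_episodes <- function(seed) {
  fixture(sprintf("big_decay_%d", seed), function() {
    cfg <- sim_config(
      rng_seed = seed, n_players = 20000, frailty_shape = Inf,
      baseline_hazard = 0.005, excess_params = decay_excess()
    )
    suppressWarnings(build_episodes(simulate_cohort(cfg)))
  })
}

# cohort whose severe stratum has a delayed excess peak (d = 10) while the
# minimal stratum decays from day one (package defaults)
delayed_peak_cohort <- function() {
  fixture("delayed_peak_cohort", function() {
    cfg <- sim_config(rng_seed = 202, n_players = 4000, frailty_shape = Inf,
                      baseline_hazard = 0.005)
    episodes <- suppressWarnings(build_episodes(simulate_cohort(cfg)))
    list(config = cfg, episodes = episodes)
  })
}

# six-record toy covering the censoring scenarios: chained non-contact
# injuries (observed events), a contact subsequent injury (censoring), and
# trailing injuries censored at the season's last match. Hand enumeration:
#   P1: ep1 event t=30; ep2 contact-censored t=20; ep3 season-end t=196
#   P2: ep4 contact-censored t=30; ep5 event t=30; ep6 season-end t=170
toy_records <- function() {
  tibble::tibble(
    player_id = c("P1", "P1", "P1", "P2", "P2", "P2"),
    position = c("defender", "defender", "defender",
                 "forward", "forward", "forward"),
    season = c("2014/15", "2014/15", "2014/15",
               "2015/16", "2015/16", "2015/16"),
    injury_date = as.Date(c("2014-09-01", "2014-10-06", "2014-11-05",
                            "2015-09-10", "2015-10-17", "2015-11-20")),
    rtp_date = as.Date(c("2014-09-06", "2014-10-16", "2014-11-08",
                         "2015-09-17", "2015-10-21", "2015-11-26")),
    contact = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    time_loss_days = c(5L, 10L, 3L, 7L, 4L, 6L)
  )
}

# episodes whose daily KM curve passes S(10) = 0.6, S(11) = 0.4:
# 10 at risk, 4 events at day 5, 2 events at day 11, 4 censored at day 20
median_toy_episodes <- function() {
  make_episodes(
    time = c(rep(5, 4), rep(11, 2), rep(20, 4)),
    event = c(rep(TRUE, 6), rep(FALSE, 4))
  )
}

random_episode_table <- function(n_max = 25) {
  n <- sample.int(n_max, 1)
  make_episodes(
    time = sample.int(30, n, replace = TRUE),
    event = as.logical(stats::rbinom(n, 1, 0.6))
  )
}
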