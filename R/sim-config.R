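#' Default four-season Bundesliga-style calendar
#'
#' Seasons 2014/15 through 2017/18 with 1 August starts and the last official
#' match dates 23 May 2015, 14 May 2016, 20 May 2017 and 12 May 2018. The
#' interval between a season's last match and the next season's start is the
#' summer break: no exposure and no injury onset is simulated there, and
#' episodes are censored at the last-match date.
#'
#' @return A tibble with columns `season`, `start`, `last_match`.
#' @export
default_season_calendar <- function() {
  tibble::tibble(
    season = c("2014/15", "2015/16", "2016/17", "2017/18"),
    start = as.Date(c("2014-08-01", "2015-08-01", "2016-08-01", "2017-08-01")),
    last_match = as.Date(c("2015-05-23", "2016-05-14", "2017-05-20", "2018-05-12"))
  )
}

validate_season_calendar <- function(calendar) {
  if (!is.data.frame(calendar) ||
      !all(c("season", "start", "last_match") %in% names(calendar))) {
    stop("`season_calendar` needs columns season, start, last_match.")
  }
  calendar$start <- as.Date(calendar$start)
  calendar$last_match <- as.Date(calendar$last_match)
  if (any(is.na(calendar$start)) || any(is.na(calendar$last_match))) {
    stop("season_calendar: unparseable dates.")
  }
  if (any(calendar$last_match <= calendar$start)) {
    stop("season_calendar: each last_match must be after its season start.")
  }
  if (nrow(calendar) > 1) {
    if (is.unsorted(calendar$start, strictly = TRUE)) {
      stop("season_calendar: seasons must be in chronological order.")
    }
    overlap <- calendar$start[-1] <= calendar$last_match[-nrow(calendar)]
    if (any(overlap)) stop("season_calendar: season intervals overlap.")
  }
  calendar
}

#' Configuration of the synthetic injury cohort
#'
#' Bundles every generative parameter of [simulate_cohort()]. The defaults
#' emulate the study population the package is designed for: four seasons of
#' a professional league with ~800 players, position mix proportional to the
#' observed counts (41 goalkeepers, 236 defenders, 272 midfielders,
#' 141 forwards per 690 multiply-injured players), gamma player frailty
#' (shape 2, mean 1) producing over-representation of injury-prone players,
#' a baseline non-contact hazard of 0.004/day, 35% contact injuries, the
#' time-loss severity mix of observed subsequent injuries, and a post-RTP
#' excess hazard that starts around two-fold baseline and decays with a
#' 25-day half-time — with a delayed excess peak (5 d / 10 d) after moderate
#' and severe index injuries.
#'
#' @param rng_seed Integer seed; mandatory so every cohort is reproducible.
#' @param n_players Number of players simulated.
#' @param season_calendar Tibble `season`, `start`, `last_match`
#'   (see [default_season_calendar()]).
#' @param position_weights Named probabilities over playing positions;
#'   must sum to 1.
#' @param frailty_shape Shape of the mean-1 gamma frailty multiplying each
#'   player's hazard; `Inf` switches frailty off (homogeneous cohort).
#' @param baseline_hazard Baseline per-day injury probability
#'   \eqn{\lambda_0 > 0}.
#' @param excess_params Named list (one `excess_params` per severity
#'   category) giving the post-RTP excess shape following an index injury of
#'   that severity.
#' @param contact_prob Probability that a generated injury is
#'   contact-related.
#' @param severity_probs Named probabilities over the four time-loss severity
#'   categories; must sum to 1.
#' @param severity_duration_ranges Named list of inclusive day ranges
#'   `c(lo, hi)` from which the time loss of each severity category is drawn
#'   uniformly. Severe injuries default to 29-180 days.
#'
#' @return A validated object of class `sim_config`.
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @export
sim_config <- function(rng_seed,
                       n_players = 800,
                       season_calendar = default_season_calendar(),
                       position_weights = c(goalkeeper = 41, defender = 236,
                                            midfielder = 272, forward = 141) / 690,
                       frailty_shape = 2,
                       baseline_hazard = 0.004,
                       excess_params = list(
                         minimal = exp_decay(amplitude = 1, half_time = 25),
                         mild = exp_decay(amplitude = 1, half_time = 25),
                         moderate = delayed_peak(amplitude = 1, half_time = 25,
                                                 peak_delay = 5),
                         severe = delayed_peak(amplitude = 1, half_time = 25,
                                               peak_delay = 10)
                       ),
                       contact_prob = 0.35,
                       severity_probs = c(minimal = 0.39, mild = 0.20,
                                          moderate = 0.245, severe = 0.165),
                       severity_duration_ranges = list(
                         minimal = c(1, 3), mild = c(4, 7),
                         moderate = c(8, 28), severe = c(29, 180)
                       )) {
  if (missing(rng_seed)) stop("`rng_seed` is required in a sim_config.")
  cfg <- structure(
    list(
      rng_seed = rng_seed, n_players = n_players,
      season_calendar = season_calendar,
      position_weights = position_weights, frailty_shape = frailty_shape,
      baseline_hazard = baseline_hazard, excess_params = excess_params,
      contact_prob = contact_prob, severity_probs = severity_probs,
      severity_duration_ranges = severity_duration_ranges
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' Validate a `sim_config`
#'
#' Checks every structural invariant (probability vectors summing to 1,
#' positive rates, ordered non-overlapping seasons, day ranges of at least
#' one day) and returns the normalised config, stopping with an informative
#' message naming the offending field otherwise.
#'
#' @param config A `sim_config` (or compatible list).
#' @return The validated `sim_config`.
#' @export
validate_sim_config <- function(config) {
  if (!is.list(config)) stop("config must be a list / sim_config.")
  req <- c("rng_seed", "n_players", "season_calendar", "position_weights",
           "frailty_shape", "baseline_hazard", "excess_params",
           "contact_prob", "severity_probs", "severity_duration_ranges")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f)) {
    stop("sim_config is missing field(s): ", paste(missing_f, collapse = ", "))
  }
  seed <- config$rng_seed
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != as.integer(seed)) {
    stop("`rng_seed` must be a single integer.")
  }
  config$rng_seed <- as.integer(seed)
  if (!is.numeric(config$n_players) || length(config$n_players) != 1 ||
      config$n_players < 0) {
    stop("`n_players` must be a single non-negative count.")
  }
  config$n_players <- as.integer(config$n_players)
  config$season_calendar <-
    validate_season_calendar(tibble::as_tibble(config$season_calendar))

  pw <- config$position_weights
  if (is.null(names(pw)) || any(pw < 0) || abs(sum(pw) - 1) > 1e-9) {
    stop("`position_weights` must be named, non-negative and sum to 1.")
  }
  if (!is.numeric(config$frailty_shape) || length(config$frailty_shape) != 1 ||
      is.na(config$frailty_shape) || config$frailty_shape <= 0) {
    stop("`frailty_shape` must be positive (Inf disables frailty).")
  }
  if (!is.numeric(config$baseline_hazard) ||
      length(config$baseline_hazard) != 1 ||
      config$baseline_hazard <= 0 || config$baseline_hazard > 1) {
    stop("`baseline_hazard` must be a per-day rate in (0, 1].")
  }
  sp <- config$severity_probs
  if (!identical(sort(names(sp)), sort(severity_levels)) ||
      any(sp < 0) || abs(sum(sp) - 1) > 1e-9) {
    stop("`severity_probs` must be named over ",
         paste(severity_levels, collapse = "/"), " and sum to 1.")
  }
  config$severity_probs <- sp[severity_levels]
  ep <- config$excess_params
  if (!all(severity_levels %in% names(ep))) {
    stop("`excess_params` must name one shape per severity category.")
  }
  ok <- vapply(ep[severity_levels], inherits, logical(1), "excess_params")
  if (!all(ok)) {
    stop("`excess_params` entries must be excess_params objects ",
         "(see exp_decay()).")
  }
  config$excess_params <- ep[severity_levels]
  if (!is.numeric(config$contact_prob) || config$contact_prob < 0 ||
      config$contact_prob > 1) {
    stop("`contact_prob` must lie in [0, 1].")
  }
  dr <- config$severity_duration_ranges
  if (!all(severity_levels %in% names(dr))) {
    stop("`severity_duration_ranges` must name one range per severity.")
  }
  dr <- dr[severity_levels]
  for (lev in severity_levels) {
    r <- dr[[lev]]
    if (length(r) != 2 || any(r < 1) || r[1] > r[2] || any(r != floor(r))) {
      stop("`severity_duration_ranges$", lev,
           "` must be an integer day range c(lo, hi) with 1 <= lo <= hi.")
    }
  }
  config$severity_duration_ranges <- dr
  structure(config, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  players: %d over %d season(s), seed %d\n",
              x$n_players, nrow(x$season_calendar), x$rng_seed))
  cat(sprintf("  baseline hazard: %g/day; frailty shape: %g; contact prob: %g\n",
              x$baseline_hazard, x$frailty_shape, x$contact_prob))
  for (lev in severity_levels) {
    p <- x$excess_params[[lev]]
    cat(sprintf("  excess after %-8s %s (e=%g, tau=%g%s)\n", lev, p$family,
                p$amplitude, p$half_time,
                if (p$family == "delayed_peak") sprintf(", d=%g", p$peak_delay) else ""))
  }
  invisible(x)
}

#' Read / write a simulation config as YAML
#'
#' Every `sim_config` field is addressable in the YAML file; `rng_seed` is
#' mandatory. Excess shapes are nested maps with a `family` key, e.g.
#' `excess_params: {severe: {family: delayed_peak, amplitude: 1,
#' half_time: 25, peak_delay: 10}}`. Fields left out fall back to the
#' package defaults.
#'
#' @param path Path of the YAML file.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$rng_seed)) {
    stop("config file `", path, "` is missing the mandatory key `rng_seed`.")
  }
  args <- list(rng_seed = raw$rng_seed)
  if (!is.null(raw$n_players)) args$n_players <- raw$n_players
  if (!is.null(raw$season_calendar)) {
    cal <- raw$season_calendar
    args$season_calendar <- tibble::tibble(
      season = vapply(cal, `[[`, character(1), "season"),
      start = as.Date(vapply(cal, `[[`, character(1), "start")),
      last_match = as.Date(vapply(cal, `[[`, character(1), "last_match"))
    )
  }
  if (!is.null(raw$position_weights)) {
    args$position_weights <- unlist(raw$position_weights)
  }
  for (f in c("frailty_shape", "baseline_hazard", "contact_prob")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$severity_probs)) {
    args$severity_probs <- unlist(raw$severity_probs)
  }
  if (!is.null(raw$severity_duration_ranges)) {
    args$severity_duration_ranges <-
      lapply(raw$severity_duration_ranges, as.numeric)
  }
  if (!is.null(raw$excess_params)) {
    args$excess_params <- lapply(raw$excess_params, function(p) {
      fam <- p$family %||% "exp_decay"
      if (fam == "exp_decay") {
        exp_decay(amplitude = p$amplitude %||% 1, half_time = p$half_time %||% 25)
      } else if (fam == "delayed_peak") {
        delayed_peak(amplitude = p$amplitude %||% 1,
                     half_time = p$half_time %||% 25,
                     peak_delay = p$peak_delay %||% 10)
      } else {
        stop("config file `", path, "`: unknown excess family `", fam,
             "` under key `excess_params`.")
      }
    })
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param config A validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  config <- validate_sim_config(config)
  cal <- config$season_calendar
  out <- list(
    rng_seed = config$rng_seed,
    n_players = config$n_players,
    season_calendar = lapply(seq_len(nrow(cal)), function(i) {
      list(season = cal$season[i], start = as.character(cal$start[i]),
           last_match = as.character(cal$last_match[i]))
    }),
    position_weights = as.list(config$position_weights),
    frailty_shape = config$frailty_shape,
    baseline_hazard = config$baseline_hazard,
    excess_params = lapply(config$excess_params, unclass),
    contact_prob = config$contact_prob,
    severity_probs = as.list(config$severity_probs),
    severity_duration_ranges = lapply(config$severity_duration_ranges, as.numeric)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
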