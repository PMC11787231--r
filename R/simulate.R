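#' Simulate a multi-season injury cohort with known ground-truth hazard
#'
#' Day-by-day simulation on the in-season calendar. Each player draws a
#' position and a mean-1 gamma frailty; before the first injury, injuries
#' arrive as per-day Bernoulli events with probability
#' `frailty * baseline_hazard`, and after each return-to-play (RTP) with
#' probability `frailty * excess_hazard(t since RTP)` where the excess shape
#' is the one configured for the severity of the index injury. Each injury
#' gets a contact flag, a severity category and a time loss drawn uniformly
#' from the category's day range; the RTP date is `injury_date + time_loss`.
#' No injuries occur during the summer break, but the post-RTP clock runs on
#' calendar days, so a rehabilitation crossing the break resumes at the
#' actual RTP date in the following season. Identical configs (including the
#' seed) produce identical cohorts.
#'
#' @param config A [sim_config()].
#'
#' @return A tibble of injury records, one row per injury, sorted by player
#'   and injury date: `player_id`, `position`, `season`, `injury_date`,
#'   `rtp_date`, `contact`, `time_loss_days`.
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 1, n_players = 20)
#' simulate_cohort(cfg)
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$rng_seed)

  cal <- config$season_calendar
  day_dates <- as.Date(
    unlist(Map(function(s, e) as.numeric(seq(s, e, by = "day")),
               cal$start, cal$last_match)),
    origin = "1970-01-01"
  )
  day_season <- rep(cal$season, as.integer(cal$last_match - cal$start) + 1L)
  day_num <- as.numeric(day_dates)
  n_days <- length(day_num)

  empty <- tibble::tibble(
    player_id = character(), position = character(), season = character(),
    injury_date = as.Date(character()), rtp_date = as.Date(character()),
    contact = logical(), time_loss_days = integer()
  )
  n <- config$n_players
  if (n == 0L) return(empty)

  pos <- sample(names(config$position_weights), n, replace = TRUE,
                prob = config$position_weights)
  frailty <- if (is.finite(config$frailty_shape)) {
    rgamma(n, shape = config$frailty_shape, rate = config$frailty_shape)
  } else {
    rep(1, n)
  }
  lam0 <- config$baseline_hazard
  sev_probs <- config$severity_probs
  dur <- config$severity_duration_ranges
  exc <- config$excess_params

  cap <- max(64L, n * 8L)
  k <- 0L
  r_player <- integer(cap); r_inj <- numeric(cap); r_rtp <- numeric(cap)
  r_sev <- integer(cap); r_contact <- logical(cap); r_season <- character(cap)

  for (p in seq_len(n)) {
    cur <- 1L
    last_rtp <- NA_real_
    last_sev <- NA_integer_
    while (cur <= n_days) {
      idx <- cur:n_days
      h <- if (is.na(last_rtp)) {
        rep.int(lam0, length(idx))
      } else {
        excess_hazard(day_num[idx] - last_rtp, exc[[last_sev]], lam0)
      }
      hit <- which(runif(length(idx)) < pmin(frailty[p] * h, 1))
      if (!length(hit)) break
      j <- idx[hit[1L]]
      sev <- sample.int(4L, 1L, prob = sev_probs)
      rng <- dur[[sev]]
      tl <- if (rng[1] == rng[2]) rng[1] else sample(seq.int(rng[1], rng[2]), 1L)
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(r_player) <- cap; length(r_inj) <- cap; length(r_rtp) <- cap
        length(r_sev) <- cap; length(r_contact) <- cap; length(r_season) <- cap
      }
      r_player[k] <- p
      r_inj[k] <- day_num[j]
      r_rtp[k] <- day_num[j] + tl
      r_sev[k] <- sev
      r_contact[k] <- runif(1L) < config$contact_prob
      r_season[k] <- day_season[j]
      last_rtp <- r_rtp[k]
      last_sev <- sev
      # exposure resumes the day after RTP (the first whole day back on the
      # daily metric): first in-season day strictly after the RTP date
      cur <- findInterval(last_rtp + 0.5, day_num) + 1L
    }
  }
  if (k == 0L) return(empty)
  keep <- seq_len(k)
  out <- tibble::tibble(
    player_id = sprintf("P%05d", r_player[keep]),
    position = pos[r_player[keep]],
    season = r_season[keep],
    injury_date = as.Date(r_inj[keep], origin = "1970-01-01"),
    rtp_date = as.Date(r_rtp[keep], origin = "1970-01-01"),
    contact = r_contact[keep],
    time_loss_days = as.integer(r_rtp[keep] - r_inj[keep])
  )
  dplyr::arrange(out, .data$player_id, .data$injury_date)
}

#' Read / write injury-record CSV files
#'
#' The on-disk schema is `player_id, position, season, injury_date,
#' rtp_date, contact, time_loss_days` with ISO-8601 dates, `contact` coded
#' 0/1 and a mandatory header row.
#'
#' @param records Injury-record tibble as produced by [simulate_cohort()].
#' @param path File path.
#' @return `read_injury_csv()` returns the validated record tibble;
#'   `write_injury_csv()` returns `path` invisibly.
#' @export
write_injury_csv <- function(records, path) {
  out <- records
  out$contact <- as.integer(out$contact)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_injury_csv
#' @export
read_injury_csv <- function(path) {
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      player_id = readr::col_character(),
      position = readr::col_character(),
      season = readr::col_character(),
      injury_date = readr::col_date(),
      rtp_date = readr::col_date(),
      contact = readr::col_integer(),
      time_loss_days = readr::col_integer()
    )
  )
  rec$contact <- rec$contact > 0L
  validate_injury_records(rec)
}

#' Validate a table of injury records
#'
#' Asserts the record invariants: RTP strictly after the injury date and
#' `time_loss_days` equal to the date difference.
#'
#' @param records Injury-record tibble.
#' @return The records, invisibly validated (stops on violation).
#' @export
validate_injury_records <- function(records) {
  req <- c("player_id", "position", "season", "injury_date", "rtp_date",
           "contact", "time_loss_days")
  missing_c <- setdiff(req, names(records))
  if (length(missing_c)) {
    stop("injury records are missing column(s): ",
         paste(missing_c, collapse = ", "))
  }
  if (nrow(records) == 0) return(records)
  if (any(records$rtp_date <= records$injury_date)) {
    stop("injury records: rtp_date must be strictly after injury_date.")
  }
  dd <- as.integer(records$rtp_date - records$injury_date)
  if (any(dd != records$time_loss_days)) {
    stop("injury records: time_loss_days must equal rtp_date - injury_date.")
  }
  records
}
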