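#' Time-loss severity category of an injury
#'
#' Categorises time-loss durations into the standard consensus classes:
#' minimal (1-3 days), mild (4-7 days), moderate (8-28 days) and severe
#' (more than 28 days). The classes partition the positive integers.
#'
#' @param time_loss_days Positive integer day counts (vectorised).
#' @return An ordered factor with levels minimal < mild < moderate < severe.
#' @export
#' @examples
#' categorize_severity(c(1, 3, 4, 7, 8, 28, 29, 180))
categorize_severity <- function(time_loss_days) {
  if (!is.numeric(time_loss_days) || any(is.na(time_loss_days)) ||
      any(time_loss_days < 1) || any(time_loss_days != floor(time_loss_days))) {
    stop("`time_loss_days` must be positive integers (>= 1 day).")
  }
  cut(time_loss_days, breaks = c(0, 3, 7, 28, Inf),
      labels = severity_levels, ordered_result = TRUE)
}

season_index_at <- function(dates, calendar) {
  # first season whose last-match date is on/after `dates`; a date inside a
  # summer break therefore maps to the *following* season (exposure resumes
  # there); NA_integer_ when beyond the final last match
  lm_num <- as.numeric(calendar$last_match)
  idx <- findInterval(as.numeric(dates), lm_num + 0.5) + 1L
  idx[idx > nrow(calendar)] <- NA_integer_
  idx
}

#' Build censored return-to-play episodes from injury records
#'
#' Chains each player's injuries in date order: every injury is the index
#' injury of one episode starting at its RTP date. The outcome is the
#' player's next injury when that injury is non-contact and occurs in the
#' same season as the RTP (an observed event); otherwise the episode is
#' censored at the next contact injury, or at the last-match date of the
#' RTP's season when the next injury falls in a later season or there is no
#' next injury. Both contact and non-contact injuries are eligible as index
#' injuries. A subsequent injury on the RTP day itself is coded as
#' `time_days = 1` (the daily metric cannot represent sub-day intervals).
#' Episodes whose RTP falls after the final season's last match, or that
#' would have zero days of exposure, are dropped with a warning.
#'
#' @param records Injury-record tibble (see [simulate_cohort()] /
#'   [read_injury_csv()]).
#' @param calendar Season calendar (see [default_season_calendar()]).
#'
#' @return A tibble of episodes: `player_id`, `season`, `rtp_date`,
#'   `time_days`, `event` (logical), `censor_reason`
#'   (none / season_end / contact_injury), `index_severity`, `position`.
#' @export
build_episodes <- function(records, calendar = default_season_calendar()) {
  calendar <- validate_season_calendar(tibble::as_tibble(calendar))
  records <- validate_injury_records(tibble::as_tibble(records))
  empty <- tibble::tibble(
    player_id = character(), season = character(),
    rtp_date = as.Date(character()), time_days = integer(),
    event = logical(),
    censor_reason = factor(character(), levels = censor_levels),
    index_severity = categorize_severity(integer(0)),
    position = character()
  )
  if (nrow(records) == 0) return(empty)

  rec <- dplyr::arrange(records, .data$player_id, .data$injury_date)
  rec <- rec |>
    dplyr::group_by(.data$player_id) |>
    dplyr::mutate(
      .next_date = dplyr::lead(.data$injury_date),
      .next_contact = dplyr::lead(.data$contact),
      .next_pos = dplyr::lead(.data$position)
    ) |>
    dplyr::ungroup()

  rtp_num <- as.numeric(rec$rtp_date)
  s_idx <- season_index_at(rec$rtp_date, calendar)
  ns_idx <- season_index_at(rec$.next_date, calendar)
  lm_num <- as.numeric(calendar$last_match)

  no_exposure <- is.na(s_idx)
  s_safe <- ifelse(no_exposure, 1L, s_idx)
  same_season <- !no_exposure & !is.na(ns_idx) & ns_idx == s_idx

  event <- same_season & !rec$.next_contact
  contact_censor <- same_season & rec$.next_contact
  time_days <- ifelse(same_season,
                      as.numeric(rec$.next_date) - rtp_num,
                      lm_num[s_safe] - rtp_num)
  # same-day subsequent injury -> 1 day on the daily metric
  time_days[same_season & time_days == 0] <- 1

  drop <- no_exposure | time_days < 1
  n_drop <- sum(drop)
  if (n_drop > 0) {
    warning(sprintf(
      "%d episode(s) dropped: no in-season exposure after RTP.", n_drop
    ))
  }

  out <- tibble::tibble(
    player_id = rec$player_id,
    season = calendar$season[s_safe],
    rtp_date = rec$rtp_date,
    time_days = as.integer(time_days),
    event = event,
    censor_reason = factor(
      ifelse(event, "none",
             ifelse(contact_censor, "contact_injury", "season_end")),
      levels = censor_levels
    ),
    index_severity = categorize_severity(rec$time_loss_days),
    position = ifelse(same_season, rec$.next_pos, rec$position)
  )
  out <- out[!drop, , drop = FALSE]
  dplyr::arrange(out, .data$player_id, .data$rtp_date)
}

#' Summarise an episode table
#'
#' Accounting of observed vs censored episodes, censor-reason breakdown and
#' the cross-tabulation of index severity by playing position — the per-run
#' counts a study report states.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @return A list with `total`, `observed`, `censored`, `by_censor_reason`,
#'   `by_severity`, `by_position` and `severity_by_position` (a tibble in
#'   long form with counts of observed events).
#' @export
episode_summary <- function(episodes) {
  if (nrow(episodes) == 0) {
    return(list(
      total = 0L, observed = 0L, censored = 0L,
      by_censor_reason = tibble::tibble(censor_reason = character(), n = integer()),
      by_severity = tibble::tibble(index_severity = character(), n = integer()),
      by_position = tibble::tibble(position = character(), n = integer()),
      severity_by_position = tibble::tibble(position = character(),
                                            index_severity = character(),
                                            n = integer())
    ))
  }
  censored <- episodes[!episodes$event, , drop = FALSE]
  list(
    total = nrow(episodes),
    observed = sum(episodes$event),
    censored = sum(!episodes$event),
    by_censor_reason = dplyr::count(censored, .data$censor_reason,
                                    .drop = FALSE),
    by_severity = dplyr::count(episodes, .data$index_severity, .drop = FALSE),
    by_position = dplyr::count(episodes, .data$position),
    severity_by_position = dplyr::count(
      episodes[episodes$event, , drop = FALSE],
      .data$position, .data$index_severity, .drop = FALSE
    )
  )
}

#' Read / write episode CSV files
#'
#' Schema: `player_id, season, rtp_date, time_days, event (0/1),
#' censor_reason, index_severity, position`, ISO-8601 dates, header row.
#'
#' @param episodes Episode tibble.
#' @param path File path.
#' @return `read_episode_csv()` returns the episode tibble;
#'   `write_episode_csv()` returns `path` invisibly.
#' @export
write_episode_csv <- function(episodes, path) {
  out <- episodes
  out$event <- as.integer(out$event)
  out$censor_reason <- as.character(out$censor_reason)
  out$index_severity <- as.character(out$index_severity)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_episode_csv
#' @export
read_episode_csv <- function(path) {
  ep <- readr::read_csv(
    path,
    col_types = readr::cols(
      player_id = readr::col_character(),
      season = readr::col_character(),
      rtp_date = readr::col_date(),
      time_days = readr::col_integer(),
      event = readr::col_integer(),
      censor_reason = readr::col_character(),
      index_severity = readr::col_character(),
      position = readr::col_character()
    )
  )
  ep$event <- ep$event > 0L
  ep$censor_reason <- factor(ep$censor_reason, levels = censor_levels)
  ep$index_severity <- factor(ep$index_severity, levels = severity_levels,
                              ordered = TRUE)
  ep
}
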