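#' Baseline comparator episodes outside the post-RTP window
#'
#' Re-clocks the episode table to the time period after the first `offset`
#' days (default 100) following return-to-play: episodes surviving past the
#' offset are retained with `time_days` reduced by the offset and their
#' event / censor status unchanged, episodes ending at or before the offset
#' are excluded. Running the hazard pipeline on the result yields the
#' injury hazard of players *not* returning from a recent injury — a
#' baseline against which the post-RTP excess can be judged. Censoring
#' reasons are kept: the original censoring date already encodes season
#' membership, so re-clocking does not re-evaluate it.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param offset Days to cut away from the front of each episode
#'   (default 100).
#' @return The re-clocked episode tibble.
#' @export
baseline_comparator_episodes <- function(episodes, offset = 100) {
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0) {
    stop("`offset` must be a single non-negative day count.")
  }
  out <- episodes[episodes$time_days > offset, , drop = FALSE]
  out$time_days <- as.integer(out$time_days - offset)
  out
}

#' Down-sample to the first RTP per player and season
#'
#' Keeps, for every (player, season) pair, only the episode with the
#' earliest RTP date — removing the over-representation of frequently
#' injured players at the cost of discarding data.
#'
#' @param episodes Episode tibble.
#' @return Episode tibble with at most one row per (player, season).
#' @export
downsample_first_rtp <- function(episodes) {
  episodes |>
    dplyr::group_by(.data$player_id, .data$season) |>
    dplyr::slice_min(.data$rtp_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Up-sample every player to the season maximum of RTP episodes
#'
#' Within each season, every player's episodes are brought up to
#' \eqn{M_s}, the maximum number of RTP episodes any player has in that
#' season: all original episodes are retained and the shortfall is filled
#' by resampling the player's own episodes with replacement. Deterministic
#' given `seed`.
#'
#' @param episodes Episode tibble.
#' @param seed Integer seed for the resampling.
#' @return Episode tibble in which every player active in a season
#'   contributes exactly \eqn{M_s} episodes to it.
#' @export
upsample_to_max <- function(episodes, seed) {
  if (missing(seed)) stop("`seed` is required for reproducible up-sampling.")
  set.seed(seed)
  seasons <- sort(unique(episodes$season))
  out <- lapply(seasons, function(s) {
    df <- episodes[episodes$season == s, , drop = FALSE]
    df <- dplyr::arrange(df, .data$player_id, .data$rtp_date)
    counts <- table(df$player_id)
    m_s <- max(counts)
    extra <- lapply(sort(unique(df$player_id)), function(pid) {
      rows <- df[df$player_id == pid, , drop = FALSE]
      need <- m_s - nrow(rows)
      if (need > 0) {
        rows[sample.int(nrow(rows), need, replace = TRUE), , drop = FALSE]
      } else {
        rows[0, , drop = FALSE]
      }
    })
    dplyr::bind_rows(df, dplyr::bind_rows(extra))
  })
  dplyr::bind_rows(out)
}

#' Leave-one-quarter-out round-robin split with refitted hazard curves
#'
#' Players are split into `k` folds (default 4) at the player level,
#' stratified by playing position: within each position players are sorted
#' by id, shuffled with the given seed and dealt cyclically, so per-position
#' fold sizes differ by at most one. For each fold the full hazard pipeline
#' is refitted on the complementary `(k-1)/k` of players; comparing the `k`
#' resulting curves with the main analysis probes overfitting by the
#' high-degree polynomial.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param k Number of folds (default 4).
#' @param seed Integer seed for the within-position shuffles.
#' @param degree,window,grid Passed to [fit_cumhaz_poly()].
#' @return A list of class `round_robin`: `assignment` (tibble `player_id`,
#'   `position`, `fold`) and `curves` (a `hazard_curve` tibble with strata
#'   `fold_1` .. `fold_k`, fitted models in its `models` attribute).
#' @export
round_robin_split <- function(episodes, k = 4, seed, degree = 10,
                              window = 100, grid = "daily") {
  if (missing(seed)) stop("`seed` is required for a reproducible split.")
  stopifnot(k >= 2)
  players <- episodes |>
    dplyr::count(.data$player_id, .data$position) |>
    dplyr::group_by(.data$player_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("player_id", "position") |>
    dplyr::arrange(.data$player_id)
  short <- players |>
    dplyr::count(.data$position) |>
    dplyr::filter(.data$n < k)
  if (nrow(short) > 0) {
    stop("position(s) with fewer players than folds: ",
         paste(short$position, collapse = ", "))
  }
  set.seed(seed)
  assignment <- players |>
    dplyr::group_by(.data$position) |>
    dplyr::group_modify(function(df, key) {
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      df$fold <- rep_len(seq_len(k), nrow(df))
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("player_id", "position", "fold") |>
    dplyr::arrange(.data$player_id)

  curves <- list()
  models <- list()
  for (i in seq_len(k)) {
    keep_ids <- assignment$player_id[assignment$fold != i]
    sub <- episodes[episodes$player_id %in% keep_ids, , drop = FALSE]
    run <- hazard_pipeline(sub, degree = degree, window = window,
                           grid = grid, stratum = sprintf("fold_%d", i))
    curves[[i]] <- run$hazard
    models[[i]] <- run$model
  }
  out_curves <- dplyr::bind_rows(curves)
  class(out_curves) <- c("hazard_curve", class(tibble::tibble()))
  attr(out_curves, "models") <- models
  structure(list(assignment = assignment, curves = out_curves),
            class = "round_robin")
}

#' Write a fold assignment as CSV
#'
#' Columns: `player_id, position, fold`.
#'
#' @param split A `round_robin` object (or its `assignment` tibble).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fold_csv <- function(split, path) {
  assignment <- if (inherits(split, "round_robin")) split$assignment else split
  readr::write_csv(assignment, path)
  invisible(path)
}
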