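# Published reference tables from the 32-game professional ASF video
# analysis (2009-2015 regular seasons): per-position frequency counts,
# career context, exemplar reconstruction counts, and per-game impact
# frequencies by magnitude level.  These are inputs to the reporting
# arithmetic and the synthetic generator defaults, not computed values.

#' Reference per-position frequency counts (32 tracked games)
#'
#' Documented head-impact counts for the eight field positions over 32
#' regular-season professional games: confirmed and suspected totals,
#' pile-up (multiple) counts, the average career length in seasons for
#' each position, and the greatest number of games played on record.
#'
#' @return Tibble with one row per position: `position`,
#'   `total_confirmed`, `n_suspected`, `n_pileup`, `avg_career_years`,
#'   `record_games`, and `n_games` (32 for all).
#' @export
reference_position_counts <- function() {
  tibble::tibble(
    position = c("QB", "RB", "WR", "TE", "OL", "DL", "LB", "DB"),
    total_confirmed = c(73, 468, 106, 459, 637, 706, 377, 115),
    n_suspected = c(23, 186, 33, 34, 31, 71, 82, 38),
    n_pileup = c(7, 106, 7, 10, 15, 15, 22, 10),
    avg_career_years = c(3.08, 2.42, 2.21, 2.67, 3.67, 3, 3, 3.17),
    record_games = c(302, 226, 303, 270, 296, 282, 278, 295),
    n_games = 32L
  )
}

#' Reference exemplar reconstruction counts
#'
#' Number of exemplar impact conditions (event type x velocity level x
#' head location) physically reconstructed per position and primary
#' event type. Each exemplar was reconstructed in three impact trials.
#'
#' @return Tibble with `position`, `helmet`, `shoulder`, `hip_thigh`,
#'   `ground`.
#' @export
reference_exemplar_counts <- function() {
  tibble::tibble(
    position = c("QB", "RB", "WR", "TE", "OL", "DL", "LB", "DB"),
    helmet = c(5, 14, 9, 11, 7, 11, 10, 5),
    shoulder = c(1, 13, 2, 11, 8, 9, 9, 9),
    hip_thigh = c(0, 6, 3, 3, 3, 3, 3, 4),
    ground = c(10, 16, 14, 12, 5, 8, 10, 15)
  )
}

#' Reference per-game impact frequencies by magnitude level
#'
#' Mean confirmed primary-event impacts per game, distributed over the
#' five MPS magnitude levels, for each position. Row sums reproduce the
#' magnitude-collapsed per-game frequencies to within print rounding.
#' Used (normalized) as the default magnitude mixes of the synthetic
#' generator.
#'
#' @return Tibble with `position` and one column per magnitude level.
#' @export
reference_magnitude_frequencies <- function() {
  tibble::tibble(
    position = c("QB", "RB", "WR", "TE", "OL", "DL", "LB", "DB"),
    very_low = c(0.03, 1.34, 0.38, 0.22, 0.22, 0.50, 0.47, 0.25),
    low = c(0.13, 4.06, 0.81, 10.41, 17.53, 19.81, 5.47, 1.03),
    moderate = c(0.69, 4.13, 0.66, 2.00, 0.97, 0.47, 2.34, 0.88),
    high = c(0.63, 0.59, 0.06, 0.72, 0.13, 0.41, 0.53, 0.25),
    very_high = c(0.28, 0.47, 0.69, 0.31, 0, 0, 0.09, 0.34)
  )
}

#' Reproduce the published frequency-table arithmetic
#'
#' From per-position confirmed totals over `n_games` tracked games,
#' recomputes the presentation columns of the published frequency table:
#' per-game mean (1 decimal), per-season estimate (unrounded per-game
#' mean x `games_per_season`), and both career projections via
#' [career_projection()].
#'
#' @param counts Tibble like [reference_position_counts()].
#' @param games_per_season Games per regular season (default 16).
#' @return `counts` with columns `per_game_mean`, `per_season`,
#'   `career_avg_est`, `career_record_est` appended.
#' @export
#' @examples
#' project_frequencies(reference_position_counts())
project_frequencies <- function(counts, games_per_season = 16) {
  per_game_raw <- counts$total_confirmed / counts$n_games
  per_season <- per_game_raw * games_per_season
  per_game_mean <- round_half_up(per_game_raw, 1)
  proj <- career_projection(per_game_mean, per_season,
                            counts$avg_career_years, counts$record_games)
  dplyr::bind_cols(
    counts,
    tibble::tibble(per_game_mean = per_game_mean, per_season = per_season),
    proj
  )
}
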