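# Conversion of countdown game-clock stamps to real inter-impact time
# intervals: stop-time multiplication plus fixed real-time paddings at
# quarter breaks, halftime, and the regulation/overtime boundary.

#' Game timeline parameters
#'
#' Quarter lengths and the fixed real-time paddings inserted between
#' playing periods: 2 min at the Q1/Q2 and Q3/Q4 breaks, 12 min at
#' halftime, 5 min between the end of regulation and overtime.
#'
#' @param quarter_length_min Regulation quarter length (minutes).
#' @param ot_length_min Overtime period length (minutes).
#' @param quarter_break_min Padding at the Q1/Q2 and Q3/Q4 breaks.
#' @param halftime_min Padding at halftime.
#' @param ot_break_min Padding before overtime.
#' @return A list of class `game_timeline`.
#' @export
game_timeline <- function(quarter_length_min = 15, ot_length_min = 15,
                          quarter_break_min = 2, halftime_min = 12,
                          ot_break_min = 5) {
  structure(list(quarter_length_min = quarter_length_min,
                 ot_length_min = ot_length_min,
                 quarter_break_min = quarter_break_min,
                 halftime_min = halftime_min,
                 ot_break_min = ot_break_min),
            class = "game_timeline")
}

quarter_length <- function(quarter, timeline) {
  ifelse(quarter == 5L, timeline$ot_length_min, timeline$quarter_length_min)
}

#' Stop-time factor of a game
#'
#' Real minutes elapsed per game-clock minute: total broadcast duration
#' divided by total game-clock playing time. Always >= 1 for a valid
#' game (play stops while the real clock runs on).
#'
#' @param meta A [game_meta()] row.
#' @return The multiplicative stop-time factor.
#' @export
#' @examples
#' stop_factor(game_meta("g1", broadcast_duration_min = 186)) # 3.1
stop_factor <- function(meta) {
  if (is.null(meta)) stop("game metadata is required", call. = FALSE)
  if (meta$clock_duration_min <= 0) {
    stop("clock duration must be positive", call. = FALSE)
  }
  meta$broadcast_duration_min / meta$clock_duration_min
}

#' Game-clock time elapsed between two stamps
#'
#' Countdown-clock arithmetic: within a quarter the elapsed clock time
#' is the difference in time remaining; across quarters it is the time
#' remaining at the first stamp, plus full intervening quarters, plus
#' the time already played in the later quarter.
#'
#' @param quarter_a,remaining_a Quarter (1-4, 5 = OT) and minutes
#'   remaining of the earlier stamp.
#' @param quarter_b,remaining_b The later stamp.
#' @param timeline A [game_timeline()].
#' @return Elapsed game-clock minutes (vectorized).
#' @export
#' @examples
#' clock_elapsed(1, 0.5, 2, 14.5) # 1.0
clock_elapsed <- function(quarter_a, remaining_a, quarter_b, remaining_b,
                          timeline = game_timeline()) {
  n <- max(length(quarter_a), length(quarter_b))
  quarter_a <- rep_len(quarter_a, n); remaining_a <- rep_len(remaining_a, n)
  quarter_b <- rep_len(quarter_b, n); remaining_b <- rep_len(remaining_b, n)
  earlier <- quarter_b < quarter_a |
    (quarter_b == quarter_a & remaining_b > remaining_a)
  if (any(earlier)) {
    stop("ordering error: second stamp precedes the first", call. = FALSE)
  }
  out <- numeric(n)
  same <- quarter_a == quarter_b
  out[same] <- remaining_a[same] - remaining_b[same]
  if (any(!same)) {
    full <- vapply(which(!same), function(i) {
      qs <- seq_len(quarter_b[i] - quarter_a[i] - 1) + quarter_a[i]
      if (length(qs)) sum(quarter_length(qs, timeline)) else 0
    }, 1.0)
    out[!same] <- remaining_a[!same] + full +
      (quarter_length(quarter_b[!same], timeline) - remaining_b[!same])
  }
  out
}

# real-time padding for every period boundary crossed between two stamps
boundary_padding <- function(quarter_a, quarter_b, timeline) {
  pads <- c(timeline$quarter_break_min, timeline$halftime_min,
            timeline$quarter_break_min, timeline$ot_break_min)
  vapply(seq_along(quarter_a), function(i) {
    if (quarter_b[i] <= quarter_a[i]) return(0)
    sum(pads[seq(quarter_a[i], quarter_b[i] - 1)])
  }, 1.0)
}

#' Real time intervals between consecutive impacts
#'
#' Converts the game-clock gaps between consecutive impacts of a
#' chronologically sorted analysis set into real minutes: clock gap
#' times the game's stop-time factor, plus the fixed real-time paddings
#' for every period boundary the pair straddles (the paddings are
#' wall-clock quantities, so they are added after the stop-factor
#' multiplication). The first impact's interval is measured from
#' kickoff (Q1, full clock) under the same rules, or set `NA` with
#' `first_impact = "exclude"`.
#'
#' @param impacts Sorted analysis-set impacts (tibble), or a `game_log`
#'   (its analysis set is used).
#' @param meta [game_meta()] for the game; taken from the log if absent.
#' @param timeline A [game_timeline()].
#' @param first_impact `"from_start"` (default) or `"exclude"`.
#' @return Numeric vector of real interval minutes, one per impact.
#' @export
real_intervals <- function(impacts, meta = NULL, timeline = game_timeline(),
                           first_impact = c("from_start", "exclude")) {
  first_impact <- match.arg(first_impact)
  if (inherits(impacts, "game_log")) {
    if (is.null(meta)) meta <- impacts$meta
    impacts <- select_analysis_set(impacts)
  }
  n <- nrow(impacts)
  if (n == 0) return(numeric(0))
  f <- stop_factor(meta)
  q <- impacts$quarter; rem <- impacts$clock_remaining
  unsorted <- diff(q) < 0 | (diff(q) == 0 & diff(rem) > 1e-9)
  if (any(unsorted)) {
    stop("ordering error: impacts are not chronologically sorted", call. = FALSE)
  }
  prev_q <- c(1L, q[-n])
  prev_rem <- c(quarter_length(1L, timeline), rem[-n])
  out <- clock_elapsed(prev_q, prev_rem, q, rem, timeline) * f +
    boundary_padding(prev_q, q, timeline)
  if (first_impact == "exclude") out[1] <- NA_real_
  out
}

#' Mean interval between same-magnitude impacts in a game
#'
#' For each MPS magnitude category, the mean real time between
#' consecutive impacts of that category within the game. Reported only
#' when the game holds more than two impacts of the category; otherwise
#' the category is marked not computable.
#'
#' @param magnitude Ordered factor of magnitude levels, one per impact
#'   (chronological order).
#' @param interval_min Real interval minutes per impact (from
#'   [real_intervals()]); absolute impact times are their cumulative sum.
#' @param min_impacts Minimum impacts of a category required (default 3,
#'   i.e. "more than two").
#' @return Tibble with `level`, `n`, `mean_interval_min` (`NA` when not
#'   computable) and `computable`.
#' @export
per_magnitude_intervals <- function(magnitude, interval_min, min_impacts = 3) {
  lv <- magnitude_categories()$level
  times <- cumsum(ifelse(is.na(interval_min), 0, interval_min))
  rows <- lapply(as.character(lv), function(l) {
    idx <- which(as.character(magnitude) == l)
    n <- length(idx)
    ok <- n >= min_impacts
    tibble::tibble(
      level = factor(l, levels = levels(lv), ordered = TRUE),
      n = n,
      mean_interval_min = if (ok) mean(diff(times[idx])) else NA_real_,
      computable = ok
    )
  })
  dplyr::bind_rows(rows)
}

#' Export per-impact intervals for audit
#'
#' @param log A `game_log`.
#' @param path CSV output path.
#' @param ... Passed to [real_intervals()].
#' @return The audit tibble, invisibly.
#' @export
write_interval_audit <- function(log, path, ...) {
  impacts <- select_analysis_set(log)
  iv <- real_intervals(impacts, meta = log$meta, ...)
  out <- tibble::tibble(
    game_id = impacts$game_id,
    impact_index = seq_len(nrow(impacts)),
    interval_min = iv,
    interval_cat = as.character(categorize_interval(iv))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}
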