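# Data model, IO, validation and frequency reporting for annotated
# head-impact logs.  One row per documented impact; games keyed by game_id.

#' Controlled vocabularies for impact logs
#'
#' @return Character vectors of the allowed codes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
position_codes <- function() c("QB", "RB", "WR", "TE", "OL", "DL", "LB", "DB")

#' @rdname vocabularies
#' @export
event_types <- function() c("helmet", "shoulder", "hip_thigh", "ground", "other")

#' @rdname vocabularies
#' @export
primary_event_types <- function() c("helmet", "shoulder", "hip_thigh", "ground")

#' @rdname vocabularies
#' @export
head_location_codes <- function() {
  c("front", "front_boss", "side", "rear_boss", "rear", "crown")
}

#' @rdname vocabularies
#' @export
impact_statuses <- function() c("confirmed", "suspected", "multiple")

#' Parse a countdown game-clock stamp
#'
#' Converts `"MM:SS"` strings (time remaining in the quarter) to decimal
#' minutes. Whole-number strings are read as minutes.
#'
#' @param x Character vector of clock stamps.
#' @return Numeric minutes remaining.
#' @export
#' @examples
#' parse_clock("14:30") # 14.5
parse_clock <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  has_colon <- grepl(":", x, fixed = TRUE)
  if (any(has_colon)) {
    parts <- strsplit(x[has_colon], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    mins <- suppressWarnings(vapply(parts, function(p) {
      as.numeric(p[1]) + as.numeric(p[2]) / 60
    }, 1.0))
    mins[bad] <- NA_real_
    out[has_colon] <- mins
  }
  plain <- !has_colon & !is.na(x) & x != ""
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("unparseable clock stamp at row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Format decimal minutes as an MM:SS clock stamp
#'
#' @param minutes Numeric minutes remaining.
#' @return Character `"MM:SS"`.
#' @export
format_clock <- function(minutes) {
  total_s <- round(minutes * 60)
  sprintf("%02d:%02d", total_s %/% 60, total_s %% 60)
}

#' Game metadata
#'
#' Timing metadata for one game, needed for stop-time correction:
#' the real (broadcast) duration and the game-clock playing time.
#'
#' @param game_id Identifier.
#' @param broadcast_duration_min Total real game time in minutes.
#' @param clock_duration_min Total game-clock time in minutes (60 for a
#'   regulation professional game).
#' @param has_overtime Logical; whether the game went to overtime.
#' @return A one-row tibble of class `game_meta`.
#' @export
game_meta <- function(game_id, broadcast_duration_min, clock_duration_min = 60,
                      has_overtime = FALSE) {
  if (clock_duration_min <= 0) {
    stop("`clock_duration_min` must be positive", call. = FALSE)
  }
  if (broadcast_duration_min < clock_duration_min) {
    stop("`broadcast_duration_min` must be >= `clock_duration_min`",
         call. = FALSE)
  }
  out <- tibble::tibble(
    game_id = as.character(game_id),
    broadcast_duration_min = as.numeric(broadcast_duration_min),
    clock_duration_min = as.numeric(clock_duration_min),
    has_overtime = as.logical(has_overtime)
  )
  class(out) <- c("game_meta", class(out))
  out
}

impact_columns <- function() {
  c("game_id", "position", "player", "event_type", "event_sublabel",
    "head_location", "elevation_level", "status", "quarter",
    "clock_remaining", "velocity_mps", "pile_count")
}

mandatory_columns <- function() {
  c("game_id", "position", "event_type", "status", "quarter", "clock_remaining")
}

#' Construct a validated game log
#'
#' Bundles the impacts tracked during one game with its timing metadata.
#' Impacts are validated against the documented schema and sorted
#' chronologically (by quarter, then descending clock time remaining);
#' the sort is stable, so simultaneous stamps keep their input order.
#'
#' @param impacts Tibble/data frame, one row per impact. Mandatory
#'   columns: `game_id`, `position`, `event_type`, `status`, `quarter`,
#'   `clock_remaining` (decimal minutes remaining). Optional: `player`,
#'   `event_sublabel`, `head_location`, `elevation_level`,
#'   `velocity_mps`, `pile_count`, `mps_percent`. Unknown columns are
#'   preserved as annotations.
#' @param meta A [game_meta()] row, or `NULL`.
#' @param ot_length_min Overtime quarter length used for clock validation.
#' @return An object of class `game_log`: a list with elements `impacts`
#'   (sorted tibble) and `meta`.
#' @export
game_log <- function(impacts, meta = NULL, ot_length_min = 15) {
  impacts <- tibble::as_tibble(impacts)
  missing_cols <- setdiff(mandatory_columns(), names(impacts))
  if (length(missing_cols)) {
    stop("impact log schema error: missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(impact_columns(), names(impacts))) {
    impacts[[col]] <- if (col %in% c("elevation_level", "pile_count")) {
      NA_integer_
    } else if (col %in% c("velocity_mps")) NA_real_ else NA_character_
  }
  impacts$game_id <- as.character(impacts$game_id)
  impacts$quarter <- parse_quarter(impacts$quarter)
  impacts$clock_remaining <- as.numeric(impacts$clock_remaining)
  impacts$elevation_level <- as.integer(impacts$elevation_level)
  impacts$pile_count <- as.integer(impacts$pile_count)
  impacts$pile_count[impacts$status == "multiple" & is.na(impacts$pile_count)] <- 1L
  validate_impacts(impacts, ot_length_min = ot_length_min)
  ord <- order(impacts$quarter, -impacts$clock_remaining)
  impacts <- impacts[ord, , drop = FALSE]
  structure(list(impacts = impacts, meta = meta), class = "game_log")
}

parse_quarter <- function(q) {
  q_chr <- toupper(trimws(as.character(q)))
  q_chr[q_chr == "OT"] <- "5"
  out <- suppressWarnings(as.integer(q_chr))
  if (any(is.na(out) & !is.na(q))) {
    stop("unparseable quarter value(s): ",
         paste(unique(q[is.na(out) & !is.na(q)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

validate_impacts <- function(impacts, ot_length_min = 15) {
  fail <- function(rows, what) {
    stop("impact log validation error (row ", paste(rows, collapse = ", "),
         "): ", what, call. = FALSE)
  }
  chk_enum <- function(col, allowed, required = TRUE) {
    v <- impacts[[col]]
    bad <- if (required) is.na(v) | !(v %in% allowed) else !is.na(v) & !(v %in% allowed)
    if (any(bad)) fail(which(bad), paste0("invalid ", col))
  }
  chk_enum("position", position_codes())
  chk_enum("status", impact_statuses())
  chk_enum("event_type", event_types(), required = FALSE)
  chk_enum("head_location", head_location_codes(), required = FALSE)

  conf <- !is.na(impacts$status) & impacts$status == "confirmed"
  bad <- conf & (is.na(impacts$event_type) | is.na(impacts$head_location))
  if (any(bad)) {
    fail(which(bad), "confirmed impacts require event_type and head_location")
  }
  # other_label present iff event kind is 'other'
  is_other <- !is.na(impacts$event_type) & impacts$event_type == "other"
  bad <- is_other & (is.na(impacts$event_sublabel) | impacts$event_sublabel == "")
  if (any(bad)) fail(which(bad), "event_type 'other' requires event_sublabel")
  bad <- !is_other & !is.na(impacts$event_sublabel) & impacts$event_sublabel != ""
  if (any(bad)) fail(which(bad), "event_sublabel only allowed for event_type 'other'")

  bad <- is.na(impacts$quarter) | impacts$quarter < 1L | impacts$quarter > 5L
  if (any(bad)) fail(which(bad), "quarter must be 1-4 or OT")
  qlen <- ifelse(impacts$quarter == 5L, ot_length_min, 15)
  bad <- is.na(impacts$clock_remaining) | impacts$clock_remaining < 0 |
    impacts$clock_remaining > qlen
  if (any(bad)) fail(which(bad), "clock_remaining outside [0, quarter length]")

  bad <- !is.na(impacts$elevation_level) &
    (impacts$elevation_level < 1L | impacts$elevation_level > 5L)
  if (any(bad)) fail(which(bad), "elevation_level must be 1-5")
  bad <- !is.na(impacts$velocity_mps) & impacts$velocity_mps < 0
  if (any(bad)) fail(which(bad), "velocity_mps must be non-negative")
  mult <- !is.na(impacts$status) & impacts$status == "multiple"
  bad <- mult & (is.na(impacts$pile_count) | impacts$pile_count < 1L)
  if (any(bad)) fail(which(bad), "pile-up rows require pile_count >= 1")
  if ("mps_percent" %in% names(impacts)) {
    bad <- !is.na(impacts$mps_percent) &
      (impacts$mps_percent < 0 | impacts$mps_percent > 100)
    if (any(bad)) fail(which(bad), "mps_percent outside [0, 100]")
  }
  invisible(impacts)
}

#' @export
print.game_log <- function(x, ...) {
  n <- nrow(x$impacts)
  id <- if (n) x$impacts$game_id[1] else x$meta$game_id %||% "?"
  cat("<game_log> game ", id, ": ", n, " documented impact(s)\n", sep = "")
  if (n) {
    tab <- table(x$impacts$status)
    cat("  status: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$meta)) {
    cat("  broadcast ", x$meta$broadcast_duration_min, " min / clock ",
        x$meta$clock_duration_min, " min\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a game log from CSV or JSON
#'
#' The documented schema is column-name keyed: `game_id`, `position`,
#' `player`, `event_type`, `event_sublabel`, `head_location`,
#' `elevation_level`, `status`, `quarter` (1-4 or `"OT"`),
#' `clock_remaining` (`"MM:SS"` counting down), `velocity_mps` and
#' `pile_count` (both optional). Unknown columns are preserved.
#'
#' @param path File path (`.csv` or `.json`).
#' @param meta Optional [game_meta()] row (or tibble of rows keyed by
#'   `game_id`; the matching row is attached).
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return A [game_log()] (or a list of them if the file holds several
#'   `game_id`s).
#' @export
read_game_log <- function(path, meta = NULL, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  missing_cols <- setdiff(mandatory_columns(), names(raw))
  if (length(missing_cols)) {
    stop("impact log schema error: missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    raw$clock_remaining <- numeric(0)
    return(game_log(raw, meta = meta))
  }
  raw$clock_remaining <- parse_clock(raw$clock_remaining)
  for (col in c("elevation_level", "pile_count")) {
    if (col %in% names(raw)) raw[[col]] <- as.integer(raw[[col]])
  }
  for (col in c("velocity_mps", "mps_percent")) {
    if (col %in% names(raw)) raw[[col]] <- as.numeric(raw[[col]])
  }
  ids <- unique(raw$game_id)
  pick_meta <- function(id) {
    if (is.null(meta)) return(NULL)
    m <- meta[meta$game_id == id, , drop = FALSE]
    if (nrow(m)) m else NULL
  }
  logs <- lapply(ids, function(id) {
    game_log(raw[raw$game_id == id, , drop = FALSE], meta = pick_meta(id))
  })
  if (length(logs) == 1L) logs[[1]] else stats::setNames(logs, ids)
}

#' Write a game log to CSV or JSON
#'
#' Inverse of [read_game_log()]: `clock_remaining` is rendered as
#' `"MM:SS"` and quarter 5 as `"OT"`, so a written file reads back to an
#' identical log.
#'
#' @param log A `game_log` (or list of them).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_game_log <- function(log, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  logs <- if (inherits(log, "game_log")) list(log) else log
  out <- dplyr::bind_rows(lapply(logs, function(l) l$impacts))
  out$clock_remaining <- format_clock(out$clock_remaining)
  out$quarter <- ifelse(out$quarter == 5L, "OT", as.character(out$quarter))
  if (format == "json") {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null", digits = NA)
  } else {
    readr::write_csv(out, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Read game metadata from CSV or JSON
#'
#' @param path File with columns `game_id`, `broadcast_duration_min`,
#'   `clock_duration_min`, `has_overtime`.
#' @return A tibble of `game_meta` rows.
#' @export
read_game_meta <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("game_id", "broadcast_duration_min", "clock_duration_min")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("game meta schema error: missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  if (!"has_overtime" %in% names(raw)) raw$has_overtime <- FALSE
  dplyr::bind_rows(lapply(seq_len(nrow(raw)), function(i) {
    game_meta(raw$game_id[i], raw$broadcast_duration_min[i],
              raw$clock_duration_min[i], isTRUE(as.logical(raw$has_overtime[i])))
  }))
}

#' Select the analysis set of a game log
#'
#' Frequencies, magnitudes and intervals are scored only for confirmed
#' impacts from the four primary event types (helmet, shoulder,
#' hip/thigh, ground). Suspected and pile-up rows, and confirmed 'other'
#' events, are excluded. Order is preserved.
#'
#' @param log A `game_log` or an impacts tibble.
#' @param position Optional position code to additionally filter on.
#' @return The retained impact rows (tibble).
#' @export
select_analysis_set <- function(log, position = NULL) {
  impacts <- if (inherits(log, "game_log")) log$impacts else tibble::as_tibble(log)
  keep <- !is.na(impacts$status) & impacts$status == "confirmed" &
    !is.na(impacts$event_type) & impacts$event_type %in% primary_event_types()
  if (!is.null(position)) keep <- keep & impacts$position %in% position
  impacts[keep, , drop = FALSE]
}

#' Per-position head-impact frequency summary
#'
#' Summarizes confirmed, suspected and pile-up counts across a
#' collection of game logs in the layout of the published frequency
#' table: per position, the total confirmed count, per-game mean and SD
#' (every log counts as one tracked game for every reported position,
#' contributing zeros where no impact was documented), the per-season
#' estimate (unrounded per-game mean times `games_per_season`), and
#' suspected / pile-up counts.
#'
#' @param logs A `game_log` or list of game logs.
#' @param games_per_season Games in a regular season (default 16).
#' @param positions Positions to report; defaults to those observed. A
#'   requested position with zero observed games is omitted with a warning.
#' @return Tibble with one row per position: `position`, `n_games`,
#'   `total_confirmed`, `per_game_mean`, `per_game_sd`, `per_season`,
#'   `n_suspected`, `n_pileup`.
#' @export
frequency_summary <- function(logs, games_per_season = 16, positions = NULL) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  n_games <- length(logs)
  if (!n_games) stop("at least one game log is required", call. = FALSE)
  all_imp <- dplyr::bind_rows(lapply(logs, function(l) l$impacts))
  observed <- unique(all_imp$position)
  if (is.null(positions)) {
    positions <- intersect(position_codes(), observed)
  } else {
    absent <- setdiff(positions, observed)
    if (length(absent)) {
      warning("position(s) with zero games omitted: ",
              paste(absent, collapse = ", "), call. = FALSE)
      positions <- setdiff(positions, absent)
    }
  }
  per_game <- function(pos) {
    vapply(logs, function(l) {
      imp <- l$impacts
      sum(imp$position == pos & imp$status == "confirmed", na.rm = TRUE)
    }, 1.0)
  }
  rows <- lapply(positions, function(pos) {
    counts <- per_game(pos)
    tibble::tibble(
      position = pos,
      n_games = n_games,
      total_confirmed = sum(counts),
      per_game_mean = mean(counts),
      per_game_sd = if (n_games > 1) stats::sd(counts) else 0,
      per_season = mean(counts) * games_per_season,
      n_suspected = sum(all_imp$position == pos & all_imp$status == "suspected",
                        na.rm = TRUE),
      n_pileup = sum(all_imp$position == pos & all_imp$status == "multiple",
                     na.rm = TRUE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Career head-impact projections
#'
#' Extrapolates per-game and per-season frequencies to an average
#' professional career and to the longest documented career. Following
#' the published presentation, the average-career estimate is rounded to
#' the nearest integer and the record-games estimate to one decimal.
#'
#' @param per_game_mean Confirmed impacts per game.
#' @param per_season Confirmed impacts per season.
#' @param avg_years Average career length in seasons.
#' @param record_games Greatest number of games played on record.
#' @return Tibble with `career_avg_est` and `career_record_est`.
#' @export
#' @examples
#' career_projection(2.3, 36.5, 3.08, 302) # 112 and 694.6
career_projection <- function(per_game_mean, per_season, avg_years, record_games) {
  args <- cbind(per_game_mean, per_season, avg_years, record_games)
  if (any(args < 0)) stop("all inputs must be non-negative", call. = FALSE)
  tibble::tibble(
    career_avg_est = round_half_up(per_season * avg_years, 0),
    career_record_est = round_half_up(per_game_mean * record_games, 1)
  )
}
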