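# The BSE/T cumulative exposure index and its aggregation across games,
# seasons and position profiles.

#' Compute the BSE/T exposure index
#'
#' BSE/T (brain strain exposure per time) combines, for one
#' position-game, the frequency of impacts in each MPS magnitude
#' category, the category severity weights (very_low = 1 ... very_high
#' = 5), and inter-impact interval weights (very_low = 4 ... high = 1),
#' normalized by the total impact frequency.
#'
#' Two weightings are exposed. In the default `"per_impact"` mode every
#' impact contributes its severity weight times the weight of its own
#' interval category; contributions are summed and divided by the total
#' frequency. The `"category_mean"` mode follows the five-term literal
#' reading: per magnitude category, frequency x severity x the interval
#' weight of the category of the *mean* interval of that category's
#' impacts; the five terms are summed and divided by total frequency.
#' The modes agree whenever all impacts of a magnitude category share
#' one interval category. The index is bounded in `[1, 20]` for any
#' non-empty input.
#'
#' @param magnitude Ordered factor (or character) of magnitude levels,
#'   one per impact.
#' @param interval_min Real interval minutes per impact; required for
#'   `"category_mean"` and used to derive interval categories when
#'   `interval_cat` is missing.
#' @param interval_cat Interval categories per impact (optional if
#'   `interval_min` given).
#' @param mode `"per_impact"` or `"category_mean"`.
#' @return The index value (numeric scalar) with attribute `mode`.
#' @export
#' @examples
#' compute_bset(c("moderate", "moderate"), interval_min = c(5, 10)) # 12
compute_bset <- function(magnitude, interval_min = NULL, interval_cat = NULL,
                         mode = c("per_impact", "category_mean")) {
  mode <- match.arg(mode)
  n <- length(magnitude)
  if (n == 0) {
    stop("BSE/T is undefined for an empty impact set", call. = FALSE)
  }
  if (is.null(interval_cat)) {
    if (is.null(interval_min)) {
      stop("provide `interval_min` or `interval_cat`", call. = FALSE)
    }
    interval_cat <- categorize_interval(interval_min)
  }
  sev <- severity_weight(magnitude)
  if (anyNA(sev)) stop("invalid magnitude level(s)", call. = FALSE)
  value <- if (mode == "per_impact") {
    iw <- interval_weight(interval_cat)
    if (anyNA(iw)) stop("invalid interval category(s)", call. = FALSE)
    sum(sev * iw) / n
  } else {
    if (is.null(interval_min)) {
      stop("`category_mean` mode requires `interval_min`", call. = FALSE)
    }
    terms <- vapply(split(seq_len(n), as.character(magnitude)), function(idx) {
      cat_of_mean <- categorize_interval(mean(interval_min[idx]))
      length(idx) * sev[idx[1]] * interval_weight(cat_of_mean)
    }, 1.0)
    sum(terms) / n
  }
  structure(value, mode = mode)
}

#' Score one position-game
#'
#' Runs the full per-game pipeline for one position: analysis-set
#' selection, exemplar MPS assignment (skipped for impacts that already
#' carry `mps_percent`, e.g. synthetic logs), magnitude and interval
#' categorization, and the BSE/T index.
#'
#' @param log A `game_log`.
#' @param position Position code to score.
#' @param table [exemplar_table()] for MPS assignment.
#' @param mode BSE/T weighting mode, see [compute_bset()].
#' @param timeline A [game_timeline()].
#' @param first_impact First-impact interval rule, see [real_intervals()].
#' @return One-row tibble (an exposure record): `game_id`, `position`,
#'   `n_impacts`, per-magnitude counts `n_very_low` ... `n_very_high`,
#'   `mean_interval_min`, `bset` (`NA` when no impacts), `bset_mode`,
#'   and conservative-bound annotations `n_suspected`, `n_pileup`.
#' @export
game_exposure <- function(log, position, table = bundled_exemplar_table(),
                          mode = c("per_impact", "category_mean"),
                          timeline = game_timeline(),
                          first_impact = c("from_start", "exclude")) {
  mode <- match.arg(mode)
  first_impact <- match.arg(first_impact)
  stopifnot(inherits(log, "game_log"))
  all_imp <- log$impacts
  aset <- select_analysis_set(log, position = position)
  game_id <- if (nrow(all_imp)) all_imp$game_id[1] else log$meta$game_id
  n_susp <- sum(all_imp$position == position & all_imp$status == "suspected",
                na.rm = TRUE)
  n_pile <- sum(all_imp$position == position & all_imp$status == "multiple",
                na.rm = TRUE)
  lv <- as.character(magnitude_categories()$level)
  if (nrow(aset) == 0) {
    counts <- stats::setNames(rep(0L, 5), paste0("n_", lv))
    return(tibble::tibble(
      game_id = game_id, position = position, n_impacts = 0L,
      !!!counts, mean_interval_min = NA_real_, bset = NA_real_,
      bset_mode = mode, n_suspected = n_susp, n_pileup = n_pile
    ))
  }
  has_mps <- "mps_percent" %in% names(aset) && !anyNA(aset$mps_percent)
  if (!has_mps) aset <- assign_mps(aset, table)
  magnitude <- categorize_mps(aset$mps_percent)
  iv <- real_intervals(aset, meta = log$meta, timeline = timeline,
                       first_impact = first_impact)
  usable <- !is.na(iv)
  bset <- if (any(usable)) {
    as.numeric(compute_bset(magnitude[usable], interval_min = iv[usable],
                            mode = mode))
  } else NA_real_
  counts <- stats::setNames(
    as.integer(base::table(factor(as.character(magnitude), levels = lv))),
    paste0("n_", lv)
  )
  tibble::tibble(
    game_id = game_id, position = position, n_impacts = nrow(aset),
    !!!counts, mean_interval_min = mean(iv, na.rm = TRUE),
    bset = bset, bset_mode = mode,
    n_suspected = n_susp, n_pileup = n_pile
  )
}

#' Aggregate exposure records to a per-position season summary
#'
#' Per position: per-game mean and SD of confirmed-primary frequency and
#' of BSE/T, the per-season frequency estimate (per-game mean times
#' `games_per_season`), per-game means of the magnitude-category counts,
#' and the mean interval. The grand mean of the per-position per-season
#' estimates is attached as attribute `grand_mean_per_season`.
#'
#' @param records Exposure records from [game_exposure()] (row-bound).
#' @param games_per_season Games per regular season (default 16).
#' @return Per-position tibble with attribute `grand_mean_per_season`.
#' @export
season_aggregate <- function(records, games_per_season = 16) {
  records <- tibble::as_tibble(records)
  lv <- paste0("n_", as.character(magnitude_categories()$level))
  out <- records |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n_games = dplyr::n(),
      total_impacts = sum(.data$n_impacts),
      per_game_mean = mean(.data$n_impacts),
      per_game_sd = if (dplyr::n() > 1) stats::sd(.data$n_impacts) else 0,
      per_season = mean(.data$n_impacts) * games_per_season,
      dplyr::across(dplyr::all_of(lv), mean, .names = "per_game_{.col}"),
      bset_mean = mean(.data$bset, na.rm = TRUE),
      bset_sd = if (sum(!is.na(.data$bset)) > 1) {
        stats::sd(.data$bset, na.rm = TRUE)
      } else 0,
      mean_interval_min = mean(.data$mean_interval_min, na.rm = TRUE),
      .groups = "drop"
    )
  attr(out, "grand_mean_per_season") <- mean(out$per_season)
  out
}

#' Default BSE/T profile membership
#'
#' The three observed cumulative exposure profiles: profile 1 (QB, WR,
#' DB) — few impacts, typically high magnitude, long intervals; profile
#' 2 (LB, RB) — all magnitude levels at mid-range frequency and
#' intervals; profile 3 (OL, DL) — highest frequency, predominantly low
#' magnitude, shortest intervals. TE overlaps profiles 2 and 3.
#'
#' @return Named list of character vectors (`TE` appears in both
#'   profile_2 and profile_3).
#' @export
default_profile_membership <- function() {
  list(
    profile_1 = c("QB", "WR", "DB"),
    profile_2 = c("LB", "RB", "TE"),
    profile_3 = c("OL", "DL", "TE")
  )
}

#' Descriptive profile report
#'
#' Groups per-position season summaries by profile membership (no
#' clustering is performed; membership is configuration) and emits
#' descriptive contrasts: mean per-game frequency, magnitude mix, mean
#' interval, and mean BSE/T. Positions appearing in more than one
#' profile are flagged as overlapping.
#'
#' @param summary A [season_aggregate()] tibble.
#' @param membership Named list of position vectors; defaults to
#'   [default_profile_membership()].
#' @return Tibble with one row per profile plus `overlapping` members.
#' @export
profile_report <- function(summary, membership = default_profile_membership()) {
  if (nrow(summary) < 2) {
    stop("profile report needs summaries for >= 2 positions", call. = FALSE)
  }
  assigned <- unique(unlist(membership))
  missing_pos <- setdiff(summary$position, assigned)
  if (length(missing_pos)) {
    stop("configuration error: position(s) absent from membership map: ",
         paste(missing_pos, collapse = ", "), call. = FALSE)
  }
  counts <- table(unlist(membership))
  overlapping <- names(counts)[counts > 1]
  lv <- paste0("per_game_n_", as.character(magnitude_categories()$level))
  rows <- lapply(names(membership), function(p) {
    members <- intersect(membership[[p]], summary$position)
    s <- summary[summary$position %in% members, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    mix <- colSums(s[, lv, drop = FALSE])
    mix <- if (sum(mix) > 0) mix / sum(mix) else mix
    tibble::tibble(
      profile = p,
      positions = paste(members, collapse = ","),
      mean_per_game_impacts = mean(s$per_game_mean),
      mean_interval_min = mean(s$mean_interval_min, na.rm = TRUE),
      mean_bset = mean(s$bset_mean, na.rm = TRUE),
      !!!stats::setNames(as.list(mix), sub("per_game_n_", "mix_", lv)),
      overlapping = paste(intersect(members, overlapping), collapse = ",")
    )
  })
  dplyr::bind_rows(rows)
}
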