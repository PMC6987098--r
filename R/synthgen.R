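# Seeded synthetic game-log generator.  Emulates the statistical
# structure of the documented positional exposure profiles (per-game
# confirmed counts, magnitude mixes, event-type mixes, clock-time
# arrival) so the whole pipeline is testable without game footage.

#' Position exposure profile for the generator
#'
#' @param position Position code.
#' @param per_game_mean,per_game_sd Mean and SD of confirmed impacts per
#'   game. Counts are drawn negative-binomial with this mean/SD
#'   (Poisson when `sd^2 <= mean`).
#' @param magnitude_mix Probabilities over the five MPS magnitude
#'   categories (normalized if needed).
#' @param event_mix Named probabilities over event kinds
#'   (helmet/shoulder/hip_thigh/ground/other).
#' @param suspected_rate Expected suspected impacts per confirmed impact.
#' @param pileup_rate Expected pile-up (multiple) rows per game.
#' @return A list of class `position_profile`.
#' @export
position_profile <- function(position, per_game_mean, per_game_sd,
                             magnitude_mix, event_mix = default_event_mix(),
                             suspected_rate = 0.17, pileup_rate = 0.6) {
  if (per_game_mean < 0 || per_game_sd < 0) {
    stop("mean and sd must be non-negative", call. = FALSE)
  }
  if (length(magnitude_mix) != 5 || any(magnitude_mix < 0) ||
        sum(magnitude_mix) <= 0) {
    stop("`magnitude_mix` must be 5 non-negative weights", call. = FALSE)
  }
  if (!setequal(names(event_mix), event_types()) || any(event_mix < 0)) {
    stop("`event_mix` must be named probabilities over the five event kinds",
         call. = FALSE)
  }
  structure(list(
    position = position,
    per_game_mean = per_game_mean,
    per_game_sd = per_game_sd,
    magnitude_mix = magnitude_mix / sum(magnitude_mix),
    event_mix = event_mix / sum(event_mix),
    suspected_rate = suspected_rate,
    pileup_rate = pileup_rate
  ), class = "position_profile")
}

#' Default event-kind mix
#'
#' Approximate shares of documented impacts by striking surface with
#' position collapsed: helmet 49%, shoulder 23%, ground 13%, hip/thigh
#' 2%, other 13%.
#'
#' @return Named numeric probabilities.
#' @export
default_event_mix <- function() {
  c(helmet = 0.49, shoulder = 0.23, hip_thigh = 0.02, ground = 0.13,
    other = 0.13)
}

#' Default position profiles
#'
#' Eight profiles parameterized from the published 32-game summaries:
#' per-game confirmed means and SDs from the frequency table, magnitude
#' mixes normalized from the published per-game frequencies by magnitude
#' level (approximations of the true mixes; see
#' [reference_magnitude_frequencies()]), suspected rates from the
#' per-position suspected/confirmed ratios, and pile-up rates from the
#' per-position pile-up counts per game.
#'
#' @return Named list of [position_profile()]s.
#' @export
#' @examples
#' default_profiles()$DL$per_game_mean # 22.1
default_profiles <- function() {
  freq <- tibble::tibble(
    position = c("QB", "RB", "WR", "TE", "OL", "DL", "LB", "DB"),
    per_game_mean = c(2.3, 14.6, 3.3, 14.3, 19.9, 22.1, 11.8, 3.6),
    per_game_sd = c(2.0, 5.4, 2.9, 6.1, 8.3, 8.5, 4.6, 2.5)
  )
  mags <- reference_magnitude_frequencies()
  ref <- reference_position_counts()
  profiles <- lapply(seq_len(nrow(freq)), function(i) {
    pos <- freq$position[i]
    m <- as.numeric(mags[mags$position == pos,
                         as.character(magnitude_categories()$level)])
    r <- ref[ref$position == pos, ]
    position_profile(
      position = pos,
      per_game_mean = freq$per_game_mean[i],
      per_game_sd = freq$per_game_sd[i],
      magnitude_mix = m,
      suspected_rate = r$n_suspected / r$total_confirmed,
      pileup_rate = r$n_pileup / r$n_games
    )
  })
  stats::setNames(profiles, freq$position)
}

draw_count <- function(n, mean, sd) {
  if (mean == 0) return(rep(0L, n))
  v <- sd^2
  if (v <= mean) {
    rpois(n, mean)
  } else {
    size <- mean^2 / (v - mean)
    if (!is.finite(size) || size <= 0) {
      stop("invalid overdispersion parameterization (mean ", mean, ", sd ",
           sd, ")", call. = FALSE)
    }
    rnbinom(n, mu = mean, size = size)
  }
}

# observed exemplar MPS range: magnitude draws are uniform within the
# assigned category's bounds, floored/capped at the documented 4.6-50.6%
draw_mps <- function(n, magnitude_mix) {
  lv <- magnitude_categories()
  cat_idx <- sample.int(5, n, replace = TRUE, prob = magnitude_mix)
  lo <- pmax(lv$lower_pct[cat_idx], 4.6)
  hi <- pmin(lv$upper_pct[cat_idx], 50.6)
  runif(n, lo, hi)
}

other_sublabels <- function() {
  c("back", "chest", "stomach", "arm", "hand", "leg", "knee")
}

location_mix <- function() {
  c(front = 0.40, front_boss = 0.15, side = 0.20, rear_boss = 0.10,
    rear = 0.10, crown = 0.05)
}

#' Generate one synthetic game log
#'
#' Draws, for each supplied profile, a confirmed impact count
#' (negative-binomial with the profile's mean/SD, Poisson if
#' underdispersed), uniform clock stamps over the four quarters, event
#' kinds from the event mix, head locations from a front-dominated mix,
#' and MPS values from the magnitude mix (uniform within the assigned
#' category band). Suspected and pile-up rows are added at the
#' profile's rates. The result always passes impact-log validation.
#'
#' In `"reconstruction"` mode, instead of drawing MPS directly, impacts
#' draw a velocity level and are routed through the exemplar table
#' (full-fidelity pipeline exercise).
#'
#' @param profiles A [position_profile()] or list of them.
#' @param meta A [game_meta()] row; a default (186 broadcast / 60 clock
#'   minutes) is synthesized when omitted.
#' @param seed Integer seed; generation is deterministic given it.
#' @param game_id Identifier for the game.
#' @param mode `"direct"` (default) or `"reconstruction"`.
#' @param table Exemplar table for `"reconstruction"` mode.
#' @return A [game_log()].
#' @export
generate_game <- function(profiles, meta = NULL, seed,
                          game_id = "synthetic_game",
                          mode = c("direct", "reconstruction"),
                          table = bundled_exemplar_table()) {
  mode <- match.arg(mode)
  if (inherits(profiles, "position_profile")) profiles <- list(profiles)
  if (missing(seed)) stop("`seed` is mandatory for reproducibility",
                          call. = FALSE)
  set.seed(seed)
  if (is.null(meta)) {
    meta <- game_meta(game_id, broadcast_duration_min = 186,
                      clock_duration_min = 60)
  }
  rows <- lapply(profiles, function(p) synth_position_rows(p, meta, mode, table))
  impacts <- dplyr::bind_rows(rows)
  if (nrow(impacts) == 0) {
    impacts <- tibble::tibble(
      game_id = character(0), position = character(0),
      event_type = character(0), status = character(0),
      quarter = integer(0), clock_remaining = numeric(0)
    )
  }
  impacts$game_id <- rep(meta$game_id, nrow(impacts))
  game_log(impacts, meta = meta)
}

synth_position_rows <- function(p, meta, mode, table) {
  n_conf <- draw_count(1, p$per_game_mean, p$per_game_sd)
  n_susp <- rpois(1, p$suspected_rate * p$per_game_mean)
  n_pile <- rpois(1, p$pileup_rate)
  n <- n_conf + n_susp + n_pile
  if (n == 0) return(NULL)
  na_c <- NA_character_; na_i <- NA_integer_; na_r <- NA_real_
  ev <- loc <- sub <- rep(na_c, n)
  elev <- rep(na_i, n)
  mps <- velocity <- rep(na_r, n)
  pile <- rep(na_i, n)
  status <- rep(c("confirmed", "suspected", "multiple"),
                c(n_conf, n_susp, n_pile))
  if (n_conf > 0) {
    ci <- seq_len(n_conf)
    ev[ci] <- sample(names(p$event_mix), n_conf, replace = TRUE,
                     prob = p$event_mix)
    loc[ci] <- sample(names(location_mix()), n_conf, replace = TRUE,
                      prob = location_mix())
    elev[ci] <- ifelse(loc[ci] == "crown", na_i,
                       sample(1:5, n_conf, replace = TRUE))
    is_other <- ev[ci] == "other"
    sub[ci][is_other] <- sample(other_sublabels(), sum(is_other),
                                replace = TRUE)
    primary <- which(ev[ci] %in% primary_event_types())
    if (mode == "direct") {
      mps[primary] <- draw_mps(length(primary), p$magnitude_mix)
    } else if (length(primary)) {
      kind <- ifelse(ev[primary] == "ground", "fall", "collision")
      vlevel <- sample(five_levels, length(primary), replace = TRUE,
                       prob = c(0.1, 0.4, 0.3, 0.15, 0.05))
      velocity[primary] <- vapply(seq_along(vlevel), function(i) {
        lv <- velocity_levels(kind[i])
        r <- lv[as.character(lv$level) == vlevel[i], ]
        runif(1, r$lower_mps, min(r$upper_mps, r$lower_mps + 3))
      }, 1.0)
      scored <- assign_mps(
        tibble::tibble(position = p$position, event_type = ev[primary],
                       velocity_level = vlevel, head_location = loc[primary]),
        table
      )
      mps[primary] <- scored$mps_percent
    }
  }
  if (n_pile > 0) {
    pile[status == "multiple"] <- 1L + rpois(n_pile, 1)
  }
  data.frame(
    position = rep(p$position, n), player = rep(paste0(p$position, "_1"), n),
    event_type = ev, event_sublabel = sub, head_location = loc,
    elevation_level = elev, status = status, velocity_mps = velocity,
    pile_count = pile, mps_percent = mps,
    quarter = sample(1:4, n, replace = TRUE),
    clock_remaining = runif(n, 0, 15),
    stringsAsFactors = FALSE
  )
}

#' Season specification for the generator
#'
#' @param n_games Number of games (>= 1).
#' @param seed Master seed (mandatory); per-game child seeds are drawn
#'   deterministically from it.
#' @param positions Position codes to include (default all eight).
#' @param profiles Profiles to use; defaults to [default_profiles()].
#' @param stop_factor_mean,stop_factor_sd Normal distribution of the
#'   per-game stop-time factor (truncated at 1); broadcast duration is
#'   the factor times the 60-minute game clock.
#' @return A list of class `season_spec`.
#' @export
season_spec <- function(n_games, seed, positions = position_codes(),
                        profiles = default_profiles(),
                        stop_factor_mean = 3.1, stop_factor_sd = 0.15) {
  if (n_games < 1) stop("`n_games` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory for reproducibility",
                          call. = FALSE)
  structure(list(n_games = n_games, seed = as.integer(seed),
                 positions = positions,
                 profiles = profiles[positions],
                 stop_factor_mean = stop_factor_mean,
                 stop_factor_sd = stop_factor_sd),
            class = "season_spec")
}

#' Generate a synthetic season of game logs
#'
#' Generates `n_games` logs, each carrying impacts for every position in
#' the spec. Child seeds for each game are drawn deterministically from
#' the master seed, so the season is byte-reproducible.
#'
#' @param spec A [season_spec()].
#' @return Named list of [game_log()]s (`game_0001`, ...).
#' @export
generate_season <- function(spec) {
  stopifnot(inherits(spec, "season_spec"))
  set.seed(spec$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_games)
  factors <- pmax(1, rnorm(spec$n_games, spec$stop_factor_mean,
                           spec$stop_factor_sd))
  ids <- sprintf("game_%04d", seq_len(spec$n_games))
  logs <- lapply(seq_len(spec$n_games), function(i) {
    meta <- game_meta(ids[i], broadcast_duration_min = factors[i] * 60,
                      clock_duration_min = 60)
    generate_game(spec$profiles, meta = meta, seed = child_seeds[i],
                  game_id = ids[i])
  })
  stats::setNames(logs, ids)
}
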