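# In-code fixtures: small hand-built logs used across the suite.

impact_row <- function(position = "OL", event_type = "helmet",
                       head_location = "front", status = "confirmed",
                       quarter = 1L, clock_remaining = 10,
                       event_sublabel = NA_character_,
                       elevation_level = 3L, velocity_mps = NA_real_,
                       pile_count = NA_integer_, game_id = "g1", ...) {
  tibble::tibble(
    game_id = game_id, position = position, player = paste0(position, "_1"),
    event_type = event_type, event_sublabel = event_sublabel,
    head_location = head_location, elevation_level = elevation_level,
    status = status, quarter = quarter, clock_remaining = clock_remaining,
    velocity_mps = velocity_mps, pile_count = pile_count, ...
  )
}

make_log <- function(..., broadcast = 186, clock = 60, game_id = "g1") {
  impacts <- dplyr::bind_rows(...)
  impacts$game_id <- game_id
  game_log(impacts, meta = game_meta(game_id, broadcast, clock))
}

impact_columns_for_test <- function() {
  c("game_id", "position", "player", "event_type", "event_sublabel",
    "head_location", "elevation_level", "status", "quarter",
    "clock_remaining", "velocity_mps", "pile_count")
}

# the three-impact OL fixture whose exposure record is hand-traced in
# test-exposure.R
ol_fixture <- function(broadcast = 186) {
  make_log(
    impact_row(event_type = "helmet", head_location = "front",
               quarter = 1L, clock_remaining = 12.5),
    impact_row(event_type = "ground", head_location = "side",
               quarter = 2L, clock_remaining = 8.25, elevation_level = 2L),
    impact_row(event_type = "shoulder", head_location = "front_boss",
               quarter = 4L, clock_remaining = 10),
    broadcast = broadcast
  )
}
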