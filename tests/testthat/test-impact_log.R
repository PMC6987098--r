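test_that("clock stamps parse and format round-trip", {
  expect_equal(parse_clock(c("14:30", "00:45", "15:00")), c(14.5, 0.75, 15))
  expect_equal(format_clock(c(14.5, 0.75)), c("14:30", "00:45"))
  expect_error(parse_clock(c("10:00", "oops")), "row\\(s\\) 2")
})

test_that("reading the bundled fixture yields a sorted three-impact log", {
  meta <- read_game_meta(system.file("extdata", "example_game_meta.csv",
                                     package = "bsetr"))
  log <- read_game_log(system.file("extdata", "example_game_log.csv",
                                   package = "bsetr"), meta = meta)
  expect_s3_class(log, "game_log")
  expect_equal(nrow(log$impacts), 3)
  # chronological: quarter ascending, clock remaining descending within
  expect_equal(log$impacts$quarter, c(1L, 2L, 4L))
  expect_equal(log$impacts$clock_remaining, c(12.5, 8.25, 10))
  expect_equal(stop_factor(log$meta), 3.1)
})

test_that("empty input gives an empty log; schema errors name the column", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("game_id,position,event_type,status,quarter,clock_remaining", tmp)
  log <- read_game_log(tmp)
  expect_equal(nrow(log$impacts), 0)

  writeLines(c("game_id,position,status", "g1,QB,confirmed"), tmp)
  expect_error(read_game_log(tmp), "'event_type'")
})

test_that("confirmed impacts require event type and head location", {
  expect_error(
    make_log(impact_row(head_location = NA_character_)),
    "event_type and head_location"
  )
  expect_error(
    make_log(impact_row(event_type = NA_character_)),
    "event_type and head_location"
  )
  # suspected impacts may lack both
  log <- make_log(impact_row(status = "suspected", event_type = NA_character_,
                             head_location = NA_character_,
                             elevation_level = NA_integer_))
  expect_equal(nrow(log$impacts), 1)
})

test_that("other_label is present iff event kind is other", {
  expect_error(make_log(impact_row(event_type = "other")), "event_sublabel")
  expect_error(make_log(impact_row(event_sublabel = "back")), "event_sublabel")
  log <- make_log(impact_row(event_type = "other", event_sublabel = "back"))
  expect_equal(log$impacts$event_sublabel, "back")
})

test_that("pile-up rows need a count and default to 1", {
  log <- make_log(impact_row(status = "multiple", event_type = NA_character_,
                             head_location = NA_character_,
                             elevation_level = NA_integer_))
  expect_equal(log$impacts$pile_count, 1L)
  expect_error(
    make_log(impact_row(status = "multiple", event_type = NA_character_,
                        head_location = NA_character_,
                        elevation_level = NA_integer_, pile_count = 0L)),
    "pile_count"
  )
})

test_that("chronological sort is stable for simultaneous stamps", {
  log <- make_log(
    impact_row(quarter = 2L, clock_remaining = 5, velocity_mps = 1),
    impact_row(quarter = 1L, clock_remaining = 5, velocity_mps = 2),
    impact_row(quarter = 1L, clock_remaining = 5, velocity_mps = 3)
  )
  expect_equal(log$impacts$velocity_mps, c(2, 3, 1))
})

test_that("write/read round-trips every documented field", {
  log <- make_log(
    impact_row(event_type = "other", event_sublabel = "back",
               quarter = 5L, clock_remaining = 7.25, velocity_mps = 4.2),
    impact_row(status = "suspected", event_type = NA_character_,
               head_location = NA_character_, elevation_level = NA_integer_,
               quarter = 2L, clock_remaining = 0.5),
    impact_row(status = "multiple", event_type = NA_character_,
               head_location = NA_character_, elevation_level = NA_integer_,
               pile_count = 3L, quarter = 3L, clock_remaining = 14)
  )
  for (ext in c(".csv", ".json")) {
    tmp <- withr::local_tempfile(fileext = ext)
    write_game_log(log, tmp)
    back <- read_game_log(tmp)
    expect_equal(back$impacts[impact_columns_for_test()],
                 log$impacts[impact_columns_for_test()])
  }
})

test_that("analysis set keeps only confirmed primary impacts", {
  log <- make_log(
    impact_row(event_type = "helmet"),
    impact_row(event_type = "helmet", status = "suspected",
               head_location = NA_character_),
    impact_row(event_type = "other", event_sublabel = "back")
  )
  sel <- select_analysis_set(log)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$event_type, "helmet")

  # identity on an all-confirmed, all-primary log
  log2 <- make_log(
    impact_row(event_type = "helmet", clock_remaining = 10),
    impact_row(event_type = "ground", clock_remaining = 9),
    impact_row(event_type = "hip_thigh", clock_remaining = 8)
  )
  expect_equal(nrow(select_analysis_set(log2)), 3)
  # empty in, empty out
  expect_equal(nrow(select_analysis_set(log2$impacts[0, ])), 0)
})

test_that("frequency summary reproduces hand counts and conserves totals", {
  g1 <- make_log(
    impact_row(position = "QB", event_type = "ground", head_location = "rear"),
    impact_row(position = "QB", event_type = "helmet", clock_remaining = 5),
    impact_row(position = "DL", event_type = "helmet"),
    game_id = "g1"
  )
  g2 <- make_log(
    impact_row(position = "QB", event_type = "helmet"),
    impact_row(position = "DL", status = "suspected",
               event_type = NA_character_, head_location = NA_character_,
               elevation_level = NA_integer_),
    game_id = "g2"
  )
  fs <- frequency_summary(list(g1, g2))
  qb <- fs[fs$position == "QB", ]
  dl <- fs[fs$position == "DL", ]
  expect_equal(qb$total_confirmed, 3)
  expect_equal(qb$per_game_mean, 1.5)
  expect_equal(qb$per_season, 1.5 * 16)
  expect_equal(dl$total_confirmed, 1)
  expect_equal(dl$n_suspected, 1)
  # conservation: totals equal the sum of per-game counts
  expect_equal(sum(fs$total_confirmed), 4)
  # per-season is exactly per-game mean x 16
  expect_equal(fs$per_season, fs$per_game_mean * 16)
  expect_warning(frequency_summary(list(g1, g2), positions = c("QB", "WR")),
                 "WR")
})

test_that("single empty game gives zero mean and SD", {
  g <- make_log(impact_row(position = "DL"))
  fs <- frequency_summary(list(g), positions = "DL")
  expect_equal(fs$per_game_sd, 0)
  fs_qb <- suppressWarnings(frequency_summary(list(g)))
  expect_false("QB" %in% fs_qb$position)
})

test_that("career projections follow the published rounding", {
  qb <- career_projection(2.3, 36.5, 3.08, 302)
  expect_equal(qb$career_avg_est, 112)
  expect_equal(qb$career_record_est, 694.6)
  dl <- career_projection(22.1, 353, 3, 282)
  expect_equal(dl$career_avg_est, 1059)
  expect_equal(dl$career_record_est, 6232.2)
  zero <- career_projection(2.3, 36.5, 0, 0)
  expect_equal(zero$career_avg_est, 0)
  expect_equal(zero$career_record_est, 0)
  expect_error(career_projection(-1, 1, 1, 1), "non-negative")
})
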