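test_that("BSE/T worked examples: floor, mid, ceiling", {
  # two moderate impacts at very-low intervals: (2 * 3 * 4) / 2 = 12
  expect_equal(as.numeric(compute_bset(c("moderate", "moderate"),
                                       interval_min = c(5, 10))), 12)
  expect_equal(as.numeric(compute_bset(c("moderate", "moderate"),
                                       interval_min = c(5, 10),
                                       mode = "category_mean")), 12)
  # one very-low magnitude impact at a high interval: the floor, 1
  expect_equal(as.numeric(compute_bset("very_low", interval_min = 120)), 1)
  # all very-high at very-low intervals: the ceiling, 20, regardless of n
  for (n in c(1, 3, 7)) {
    expect_equal(as.numeric(compute_bset(rep("very_high", n),
                                         interval_min = rep(2, n))), 20)
  }
  expect_error(compute_bset(character(0), interval_min = numeric(0)),
               "undefined")
})

test_that("BSE/T is bounded in [1, 20] and order invariant", {
  set.seed(31)
  lv <- as.character(magnitude_categories()$level)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    mag <- sample(lv, n, replace = TRUE)
    iv <- runif(n, 0, 150)
    b <- as.numeric(compute_bset(mag, interval_min = iv))
    expect_gte(b, 1)
    expect_lte(b, 20)
    perm <- sample(n)
    expect_equal(as.numeric(compute_bset(mag[perm], interval_min = iv[perm])), b)
  }
})

test_that("adding an impact with contribution equal to the index leaves it fixed", {
  # index 12 = severity 3 x weight 4; add another moderate/very_low impact
  mag <- c("moderate", "high")
  iv <- c(10, 40) # weights 4 and 2 -> (12 + 8) / 2 = 10
  b <- as.numeric(compute_bset(mag, interval_min = iv))
  expect_equal(b, 10)
  # severity 5 x weight 2 = 10 contribution keeps the mean at 10
  b2 <- as.numeric(compute_bset(c(mag, "very_high"), interval_min = c(iv, 50)))
  expect_equal(b2, 10)
})

test_that("per-impact and category-mean modes agree on homogeneous fixtures", {
  set.seed(32)
  lv <- as.character(magnitude_categories()$level)
  iv_by_cat <- c(very_low = 5, low = 20, moderate = 50, high = 40,
                 very_high = 100)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    mag <- sample(lv, n, replace = TRUE)
    iv <- unname(iv_by_cat[mag]) # all impacts of a category share an interval
    a <- as.numeric(compute_bset(mag, interval_min = iv))
    b <- as.numeric(compute_bset(mag, interval_min = iv, mode = "category_mean"))
    expect_equal(a, b)
  }
})

test_that("the modes can differ when a category spans interval bands", {
  mag <- c("moderate", "moderate")
  iv <- c(10, 40) # per-impact: (3*4 + 3*2)/2 = 9
  a <- as.numeric(compute_bset(mag, interval_min = iv))
  expect_equal(a, 9)
  # category mean interval 25 -> low band, weight 3 -> (2*3*3)/2 = 9 here;
  # push the mean across a boundary instead
  iv2 <- c(10, 100) # mean 55 -> moderate band, weight 2 -> 6
  b <- as.numeric(compute_bset(mag, interval_min = iv2, mode = "category_mean"))
  expect_equal(b, 6)
  expect_equal(as.numeric(compute_bset(mag, interval_min = iv2)), 7.5)
})

test_that("game exposure matches the hand-traced three-impact fixture", {
  # OL fixture, stop factor 3.1:
  #   helmet/front   Q1 12:30 -> MPS 12.7 (low, sev 2);  interval 7.75  (w 4)
  #   ground/side    Q2 08:15 -> MPS 20.8 (mod, sev 3);  interval 61.675 (w 2)
  #   shoulder/boss  Q4 10:00 -> MPS 14.1 (low, sev 2);  interval 101.575 (w 1)
  rec <- game_exposure(ol_fixture(), "OL")
  expect_equal(rec$n_impacts, 3L)
  expect_equal(rec$n_low, 2L)
  expect_equal(rec$n_moderate, 1L)
  expect_equal(rec$bset, (2 * 4 + 3 * 2 + 2 * 1) / 3)
  expect_equal(rec$mean_interval_min, mean(c(7.75, 61.675, 101.575)))
  expect_equal(rec$bset_mode, "per_impact")
})

test_that("empty analysis sets yield undefined BSE/T, and 'other' is excluded", {
  log <- make_log(impact_row(position = "QB", status = "suspected",
                             event_type = NA_character_,
                             head_location = NA_character_,
                             elevation_level = NA_integer_))
  rec <- game_exposure(log, "QB")
  expect_equal(rec$n_impacts, 0L)
  expect_true(is.na(rec$bset))
  expect_equal(rec$n_suspected, 1L)

  log2 <- make_log(
    impact_row(position = "QB", event_type = "ground", head_location = "rear"),
    impact_row(position = "QB", event_type = "other", event_sublabel = "back",
               clock_remaining = 5)
  )
  rec2 <- game_exposure(log2, "QB")
  expect_equal(rec2$n_impacts, 1L)
})

test_that("season aggregation: single record, grand mean, conservation", {
  rec <- game_exposure(ol_fixture(), "OL")
  sa <- season_aggregate(rec)
  expect_equal(sa$per_game_mean, 3)
  expect_equal(sa$per_game_sd, 0)
  expect_equal(sa$per_season, 48)
  expect_equal(sa$bset_mean, rec$bset)
  expect_equal(attr(sa, "grand_mean_per_season"), 48)

  two <- dplyr::bind_rows(rec, dplyr::mutate(rec, game_id = "g2",
                                             n_impacts = 5L))
  sa2 <- season_aggregate(two)
  expect_equal(sa2$per_game_mean, 4)
  expect_equal(sa2$total_impacts, 8)
})

test_that("profile report groups positions and flags the TE overlap", {
  recs <- dplyr::bind_rows(lapply(position_codes(), function(p) {
    log <- make_log(impact_row(position = p))
    game_exposure(log, p)
  }))
  sa <- season_aggregate(recs)
  pr <- profile_report(sa)
  expect_equal(nrow(pr), 3)
  expect_setequal(pr$overlapping, c("", "TE", "TE"))
  expect_match(pr$positions[pr$profile == "profile_1"], "QB")

  # override merging everything into a single profile
  one <- profile_report(sa, membership = list(all = position_codes()))
  expect_equal(nrow(one), 1)
  expect_equal(one$overlapping, "")

  expect_error(profile_report(sa, membership = list(p1 = "QB")),
               "absent from membership")
})
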