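unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("homography recovers identity and pure scaling", {
  cal <- fit_homography(unit_square, unit_square)
  expect_equal(cal$H, diag(3), tolerance = 1e-8)
  expect_equal(cal$rmse, 0, tolerance = 1e-10)

  cal2 <- fit_homography(unit_square, 2 * unit_square)
  p <- apply_homography(cal2, rbind(c(0.25, 0.5), c(0.75, 0.25)))
  expect_equal(p, 2 * rbind(c(0.25, 0.5), c(0.75, 0.25)), tolerance = 1e-8)
  # distances double under the 2x map
  d0 <- sqrt(sum((c(0.25, 0.5) - c(0.75, 0.25))^2))
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 2 * d0, tolerance = 1e-8)
})

test_that("overdetermined fit equals the normal-equations oracle", {
  set.seed(11)
  H_true <- matrix(c(1.2, 0.1, 3, -0.05, 0.9, 1.5, 1e-4, -2e-4, 1), 3, 3,
                   byrow = TRUE)
  px <- cbind(runif(6, 0, 600), runif(6, 0, 400))
  field <- apply_homography(H_true, px) + matrix(rnorm(12, sd = 0.01), 6)
  cal <- fit_homography(px, field)

  # oracle: h minimizing ||A h|| with ||h|| = 1 is the eigenvector of the
  # smallest eigenvalue of t(A) %*% A, built here by brute force
  A <- matrix(0, 12, 9)
  for (i in 1:6) {
    x <- px[i, 1]; y <- px[i, 2]; X <- field[i, 1]; Y <- field[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, X * x, X * y, X)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, Y * x, Y * y, Y)
  }
  ev <- eigen(t(A) %*% A, symmetric = TRUE)
  h <- ev$vectors[, 9]
  H_oracle <- matrix(h, 3, 3, byrow = TRUE)
  H_oracle <- H_oracle / H_oracle[3, 3]
  expect_equal(cal$H, H_oracle, tolerance = 1e-5)
  res_oracle <- sqrt(rowSums((apply_homography(H_oracle, px) - field)^2))
  expect_equal(cal$residuals, res_oracle, tolerance = 1e-4)
})

test_that("collinear correspondences raise a calibration error", {
  line <- cbind(1:4, 2 * (1:4))
  expect_error(fit_homography(line, line), "collinear")
  expect_error(fit_homography(unit_square[1:3, ], unit_square[1:3, ]), ">= 4")
})

test_that("collision velocity follows displacement over elapsed time", {
  ident <- fit_homography(unit_square * 100, unit_square * 100)
  # 5 samples at 25 fps moving 0.26 m per frame -> 6.5 m/s
  tr <- frame_track(25, 0:4, x = 0.26 * (0:4), y = rep(0, 5))
  expect_equal(collision_velocity(tr, ident), 6.5)

  tr2 <- frame_track(25, 0:4, x = rep(3, 5), y = rep(4, 5))
  expect_equal(collision_velocity(tr2, ident), 0)

  tr3 <- frame_track(10, 0:1, x = c(0, 1), y = c(0, 0))
  expect_error(collision_velocity(tr3, ident), "insufficient")

  # 1.0 m over 0.2 s
  tr5 <- frame_track(10, 0:2, x = c(0, 0.5, 1), y = c(0, 0, 0))
  expect_equal(collision_velocity(tr5, ident), 5)
})

test_that("collision velocity is translation invariant and scales with the field", {
  sq <- unit_square * 50
  cal <- fit_homography(sq, sq)          # identity field
  cal2 <- fit_homography(sq, 3 * sq)     # 3x scaled field
  cal_t <- fit_homography(sq, sq + 10)   # rigid translation
  tr <- frame_track(30, 0:3, x = c(0, 1, 2, 3), y = c(5, 5, 6, 7))
  v <- collision_velocity(tr, cal)
  expect_equal(collision_velocity(tr, cal_t), v, tolerance = 1e-6)
  expect_equal(collision_velocity(tr, cal2), 3 * v, tolerance = 1e-6)
})

test_that("fall velocity combines corrected horizontal and vertical parts", {
  # 3-4-5 triangle: horizontal 3 m/s, vertical 4 m/s
  head <- frame_track(10, 0:2, x = c(0, 0.3, 0.6), y = c(0, 0, 0))
  marker <- frame_track(10, 0:2, x = c(0, 0, 0), y = c(0, 0, 0))
  vert <- c(1.0, 0.6, 0.2) # 0.4 m per 0.1 s frame
  expect_equal(fall_velocity(head, marker, vert), 5)

  # stationary everything
  still <- frame_track(10, 0:2, x = rep(1, 3), y = rep(2, 3))
  expect_equal(fall_velocity(still, still, c(0.5, 0.5, 0.5)), 0)

  # camera panning at 1 m/s, head apparent 3.5 m/s, no vertical motion
  head2 <- frame_track(10, 0:2, x = c(0, 0.35, 0.7), y = c(0, 0, 0))
  marker2 <- frame_track(10, 0:2, x = c(0, 0.1, 0.2), y = c(0, 0, 0))
  expect_equal(fall_velocity(head2, marker2, c(0.8, 0.8, 0.8)), 2.5)

  bad_marker <- frame_track(10, c(0, 2, 4), x = c(0, 0, 0), y = c(0, 0, 0))
  expect_error(fall_velocity(head, bad_marker, vert), "alignment")
})

test_that("ballistic mode uses free fall from the measured height", {
  head <- frame_track(10, 0:2, x = rep(0, 3), y = rep(0, 3))
  v <- fall_velocity(head, head, c(1.25, 0.8), mode = "ballistic", g = 10)
  expect_equal(v, 5) # sqrt(2 * 10 * 1.25)
})

test_that("head locations: sectors, crown, and mirror collapse", {
  expect_equal(as.character(assign_head_location(0, 3)$location), "front")
  expect_equal(as.character(assign_head_location(180, 2)$location), "rear")
  both <- assign_head_location(c(90, 270), 1)
  expect_equal(as.character(both$location), c("side", "side"))
  expect_equal(as.character(assign_head_location(22.5, 1)$location),
               "front_boss")
  crown <- assign_head_location(123, is_top = TRUE)
  expect_equal(as.character(crown$location), "crown")
  expect_true(is.na(crown$elevation_level))
  expect_error(assign_head_location(0, 6), "elevation_level")
  expect_error(assign_head_location(0, NA), "elevation_level")
})

test_that("head location is mirror symmetric for all azimuths", {
  az <- c(seq(0, 359.5, by = 0.5), 22.5, 67.5, 112.5, 157.5)
  a <- assign_head_location(az, 3)$location
  b <- assign_head_location(360 - az, 3)$location
  expect_equal(as.character(a), as.character(b))
})
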