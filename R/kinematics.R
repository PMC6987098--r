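# Velocity estimation from frame-track coordinates and head-location
# sector assignment.  The field is assumed planar, so pixel-to-field
# mapping is a 3x3 projective homography estimated by the direct linear
# transform (DLT) from >= 4 point correspondences.

#' Fit a pixel-to-field homography
#'
#' Estimates the 3x3 planar projective transform mapping image pixels to
#' field coordinates (meters) from point correspondences such as field
#' line intersections of known spacing. Uses the direct linear transform;
#' with more than four pairs the solution is total least squares (the
#' singular vector of the smallest singular value of the DLT design
#' matrix).
#'
#' @param px n x 2 matrix of pixel points (n >= 4, non-collinear).
#' @param field n x 2 matrix of the corresponding field points in meters.
#' @return Object of class `field_calibration`: list with `H` (3x3
#'   matrix, normalized so `H[3,3] == 1`), `residuals` (per-point
#'   reprojection distances in meters) and `rmse`.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' fit_homography(sq, 2 * sq)$H
fit_homography <- function(px, field) {
  px <- as.matrix(px); field <- as.matrix(field)
  if (nrow(px) < 4 || nrow(px) != nrow(field) || ncol(px) != 2 || ncol(field) != 2) {
    stop("need >= 4 pixel/field point pairs (n x 2 matrices)", call. = FALSE)
  }
  n <- nrow(px)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- px[i, 1]; y <- px[i, 2]; X <- field[i, 1]; Y <- field[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, X * x, X * y, X)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, Y * x, Y * y, Y)
  }
  sv <- svd(A, nu = 0, nv = 9)
  d <- sv$d
  # rank deficiency beyond the single homogeneous null vector means the
  # configuration is degenerate (e.g. collinear points)
  if (d[8] < max(d) * 1e-10) {
    stop("degenerate calibration: correspondences are (near-)collinear",
         call. = FALSE)
  }
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  mapped <- apply_homography(H, px)
  res <- sqrt(rowSums((mapped - field)^2))
  structure(list(H = H, residuals = res, rmse = sqrt(mean(res^2))),
            class = "field_calibration")
}

#' Apply a homography to points
#'
#' @param H 3x3 matrix or a `field_calibration`.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  if (inherits(H, "field_calibration")) H <- H$H
  pts <- matrix(as.numeric(pts), ncol = 2)
  hom <- cbind(pts, 1) %*% t(H)
  hom[, 1:2, drop = FALSE] / hom[, 3]
}

#' @export
print.field_calibration <- function(x, ...) {
  cat("<field_calibration> reprojection RMSE ",
      format(x$rmse, digits = 4), " m over ", length(x$residuals),
      " correspondences\n", sep = "")
  invisible(x)
}

#' Frame-track coordinates
#'
#' Ordered per-frame image coordinates of a tracked point (the player's
#' head, or a static scene marker standing in for camera motion).
#'
#' @param fps Video frame rate (frames/second).
#' @param frame Strictly increasing integer frame indices (>= 2).
#' @param x,y Pixel coordinates per frame.
#' @param scale_m_per_px Optional meters-per-pixel scale (e.g. from the
#'   known helmet width); used by [fall_velocity()] when no field
#'   calibration applies.
#' @return Object of class `frame_track`.
#' @export
frame_track <- function(fps, frame, x, y, scale_m_per_px = 1) {
  if (length(frame) < 2) stop("a frame track needs >= 2 samples", call. = FALSE)
  if (any(diff(frame) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  structure(list(fps = fps, frame = as.integer(frame),
                 xy = cbind(x = as.numeric(x), y = as.numeric(y)),
                 scale_m_per_px = scale_m_per_px),
            class = "frame_track")
}

#' Read a frame track from CSV
#'
#' Expects columns `frame`, `x_px`, `y_px` and optionally `role`
#' (`head`, `marker` or `surface`).
#'
#' @param path CSV path.
#' @param fps Frame rate.
#' @param role Which role to extract (ignored if no `role` column).
#' @param scale_m_per_px Passed to [frame_track()].
#' @return A `frame_track`.
#' @export
read_frame_track <- function(path, fps, role = "head", scale_m_per_px = 1) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("role" %in% names(raw)) raw <- raw[raw$role == role, , drop = FALSE]
  frame_track(fps, raw$frame, raw$x_px, raw$y_px, scale_m_per_px)
}

#' Collision inbound velocity from a pre-impact track
#'
#' Speed of the head over the three-to-five frames preceding a
#' player-to-player collision: field-plane distance between the first
#' and last tracked position divided by the elapsed time.
#'
#' @param track A [frame_track()] with 3-5 samples.
#' @param calibration A [fit_homography()] calibration mapping pixels to
#'   field meters.
#' @return Speed in m/s.
#' @export
collision_velocity <- function(track, calibration) {
  stopifnot(inherits(track, "frame_track"))
  n <- nrow(track$xy)
  if (n < 3) {
    stop("insufficient data: collision velocity needs 3-5 pre-impact frames",
         call. = FALSE)
  }
  pts <- apply_homography(calibration, track$xy[c(1, n), , drop = FALSE])
  dist_m <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  dt <- (track$frame[n] - track$frame[1]) / track$fps
  dist_m / dt
}

#' Fall (head-to-ground) resultant velocity
#'
#' Two-step estimate for falls: the horizontal component is the mean
#' per-frame head displacement minus the displacement of a static scene
#' marker (removing camera panning), scaled to meters; the vertical
#' component is the finite-difference rate of the measured head-to-ground
#' distances (or, in the opt-in `"ballistic"` mode, the free-fall speed
#' from the largest measured height). The resultant is
#' `sqrt(horizontal^2 + vertical^2)`.
#'
#' @param head_track,marker_track [frame_track()]s sharing identical
#'   frame indices (typically 3 frames before contact).
#' @param vertical_distances_m >= 2 head-to-ground distances (meters) at
#'   consecutive frames, e.g. measured against the known helmet width.
#' @param mode `"finite_diff"` (default) or `"ballistic"`.
#' @param g Gravitational acceleration for the ballistic mode (m/s^2).
#' @return Resultant speed in m/s.
#' @export
fall_velocity <- function(head_track, marker_track, vertical_distances_m,
                          mode = c("finite_diff", "ballistic"), g = 9.81) {
  mode <- match.arg(mode)
  stopifnot(inherits(head_track, "frame_track"),
            inherits(marker_track, "frame_track"))
  if (!identical(head_track$frame, marker_track$frame)) {
    stop("alignment error: head and marker tracks must share frame indices",
         call. = FALSE)
  }
  if (length(vertical_distances_m) < 2 && mode == "finite_diff") {
    stop("need >= 2 vertical distances for finite differencing", call. = FALSE)
  }
  dt <- diff(head_track$frame) / head_track$fps
  head_disp <- apply(head_track$xy, 2, diff) * head_track$scale_m_per_px
  marker_disp <- apply(marker_track$xy, 2, diff) * marker_track$scale_m_per_px
  head_disp <- matrix(head_disp, ncol = 2)
  marker_disp <- matrix(marker_disp, ncol = 2)
  rel_v <- (head_disp - marker_disp) / dt
  horizontal <- sqrt(sum(colMeans(rel_v)^2))
  vertical <- if (mode == "ballistic") {
    sqrt(2 * g * max(vertical_distances_m))
  } else {
    mean(abs(diff(vertical_distances_m))) * head_track$fps
  }
  sqrt(horizontal^2 + vertical^2)
}

#' Assign a head-location sector
#'
#' Maps an impact azimuth (transverse plane, eyes forward = 0 degrees)
#' to one of five named head locations via eight 45-degree sectors, with
#' left and right collapsed (an impact at 90 and one at 270 degrees are
#' both `side`). Impacts at the top of the helmet are `crown` regardless
#' of azimuth and carry no elevation level; all other locations carry an
#' elevation level 1-5 (base to top of helmet). The azimuth is folded to
#' `[0, 180]` before sectoring, so mirror symmetry is exact; on the
#' folded scale, sector edges at 22.5/67.5/112.5/157.5 degrees belong to
#' the sector above (22.5 is `front_boss`).
#'
#' @param azimuth_deg Azimuth(s) in degrees (any real; normalized mod 360).
#' @param elevation_level Elevation level(s) 1-5; ignored for crown.
#' @param is_top Logical; `TRUE` for impacts on the top of the helmet.
#' @return Tibble with `location` (factor) and `elevation_level`
#'   (`NA` for crown).
#' @export
#' @examples
#' assign_head_location(c(0, 90, 270, 180), elevation_level = 3)
assign_head_location <- function(azimuth_deg, elevation_level = NA_integer_,
                                 is_top = FALSE) {
  n <- max(length(azimuth_deg), length(elevation_level), length(is_top))
  azimuth_deg <- rep_len(azimuth_deg, n)
  elevation_level <- rep_len(as.integer(elevation_level), n)
  is_top <- rep_len(is_top, n)
  bad <- !is_top & (is.na(elevation_level) | elevation_level < 1L |
                      elevation_level > 5L)
  if (any(bad)) {
    stop("elevation_level must be 1-5 unless the impact is crown", call. = FALSE)
  }
  az <- azimuth_deg %% 360
  folded <- pmin(az, 360 - az)
  names5 <- c("front", "front_boss", "side", "rear_boss", "rear")
  idx <- findInterval(folded, c(22.5, 67.5, 112.5, 157.5)) + 1L
  loc <- names5[idx]
  loc[is_top] <- "crown"
  elevation_level[is_top] <- NA_integer_
  tibble::tibble(
    location = factor(loc, levels = head_location_codes()),
    elevation_level = elevation_level
  )
}
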