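# Ordinal category schemes shared across the pipeline: impact velocity
# levels, MPS magnitude levels (severity weights 1-5), and inter-impact
# interval levels (weights 4-1).  All bounds are half-open on the left of
# each upper bound so the levels form true partitions of continuous scales.

five_levels <- c("very_low", "low", "moderate", "high", "very_high")

#' Impact velocity levels
#'
#' The five ordinal velocity levels used to classify impact speeds, with
#' separate bounds for collisions (player-to-player events: helmet,
#' shoulder, hip/thigh) and falls (head-to-ground events). Bounds are
#' half-open: a level spans `[lower, upper)` in m/s, with the top level
#' unbounded above.
#'
#' @param kind `"collision"` or `"fall"`.
#' @return A tibble with columns `level` (ordered factor), `lower_mps`
#'   and `upper_mps` in m/s (`Inf` for the top level).
#' @export
#' @examples
#' velocity_levels("collision")
velocity_levels <- function(kind = c("collision", "fall")) {
  kind <- match.arg(kind)
  lower <- if (kind == "collision") c(0, 2, 4.5, 7, 9.5) else c(0, 2, 4, 6, 8)
  tibble::tibble(
    level = factor(five_levels, levels = five_levels, ordered = TRUE),
    lower_mps = lower,
    upper_mps = c(lower[-1], Inf)
  )
}

#' Categorize an impact speed into a velocity level
#'
#' @param speed_mps Non-negative speed(s) in m/s.
#' @param kind `"collision"` or `"fall"`; which bound set applies.
#' @return Ordered factor of levels (`very_low` ... `very_high`).
#' @export
#' @examples
#' categorize_velocity(5.0, "collision") # moderate
#' categorize_velocity(4.5, "fall")      # moderate
categorize_velocity <- function(speed_mps, kind = c("collision", "fall")) {
  kind <- match.arg(kind)
  if (any(!is.na(speed_mps) & speed_mps < 0)) {
    stop("`speed_mps` must be non-negative", call. = FALSE)
  }
  breaks <- velocity_levels(kind)$lower_mps[-1]
  idx <- findInterval(speed_mps, breaks) + 1L
  factor(five_levels[idx], levels = five_levels, ordered = TRUE)
}

#' MPS magnitude categories
#'
#' The five ordinal magnitude levels for brain-tissue maximum principal
#' strain (MPS, %), with their severity weights used by the BSE/T index.
#' The `risk_note` column carries the clinical interpretation attached to
#' each band (metadata only; never used in computation).
#'
#' @return A tibble with `level`, `lower_pct`, `upper_pct`,
#'   `severity_weight` (1-5) and `risk_note`.
#' @export
magnitude_categories <- function() {
  tibble::tibble(
    level = factor(five_levels, levels = five_levels, ordered = TRUE),
    lower_pct = c(0, 8, 17, 26, 35),
    upper_pct = c(8, 17, 26, 35, 100),
    severity_weight = 1:5,
    risk_note = c(
      "below levels associated with functional change",
      "strains associated with sub-concussive functional change",
      "50% risk of concussion injury (cerebrum white/grey matter)",
      "average estimates for sustaining concussive injury",
      "50% risk of loss of consciousness and persistent symptoms"
    )
  )
}

#' Categorize maximum principal strain into a magnitude level
#'
#' Bands are `[0,8)`, `[8,17)`, `[17,26)`, `[26,35)` and `[35,100]` % MPS.
#'
#' @param mps_percent Strain value(s) in percent, within `[0, 100]`.
#' @return Ordered factor of magnitude levels.
#' @export
#' @examples
#' categorize_mps(20.8) # moderate
categorize_mps <- function(mps_percent) {
  ok <- is.na(mps_percent) | (mps_percent >= 0 & mps_percent <= 100)
  if (!all(ok)) stop("`mps_percent` must lie in [0, 100]", call. = FALSE)
  idx <- findInterval(mps_percent, c(8, 17, 26, 35)) + 1L
  factor(five_levels[idx], levels = five_levels, ordered = TRUE)
}

#' Severity weight of a magnitude level
#'
#' @param level Magnitude level (character or factor).
#' @return Integer weight 1 (very_low) through 5 (very_high).
#' @export
severity_weight <- function(level) {
  match(as.character(level), five_levels)
}

#' Inter-impact interval categories
#'
#' The four ordinal interval levels (real minutes between impacts) with
#' the interval weights used by BSE/T: shorter intervals weigh more.
#' Bands are `[0,15)`, `[15,31)`, `[31,91)` and `[91, Inf)` minutes.
#'
#' @return A tibble with `level`, `lower_min`, `upper_min`, `weight`.
#' @export
interval_categories <- function() {
  lv <- c("very_low", "low", "moderate", "high")
  tibble::tibble(
    level = factor(lv, levels = lv, ordered = TRUE),
    lower_min = c(0, 15, 31, 91),
    upper_min = c(15, 31, 91, Inf),
    weight = 4:1
  )
}

#' Categorize a real inter-impact interval
#'
#' @param minutes Non-negative interval(s) in real minutes.
#' @return Ordered factor with levels `very_low`, `low`, `moderate`, `high`.
#' @export
#' @examples
#' categorize_interval(c(10, 20, 45, 120))
categorize_interval <- function(minutes) {
  if (any(!is.na(minutes) & minutes < 0)) {
    stop("`minutes` must be non-negative", call. = FALSE)
  }
  lv <- c("very_low", "low", "moderate", "high")
  idx <- findInterval(minutes, c(15, 31, 91)) + 1L
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Interval weight of an interval level
#'
#' @param level Interval level (character or factor).
#' @return Integer weight 4 (very_low) through 1 (high).
#' @export
interval_weight <- function(level) {
  5L - match(as.character(level), c("very_low", "low", "moderate", "high"))
}
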