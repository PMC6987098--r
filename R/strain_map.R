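# Mapping impact conditions to brain-tissue maximum principal strain
# (MPS) via exemplar reconstruction tables, plus the viscoelastic
# shear-relaxation utility for the brain tissue materials.

exemplar_key_cols <- function() {
  c("position", "event_type", "velocity_level", "head_location")
}

#' Construct an exemplar strain table
#'
#' An exemplar table maps impact conditions to the MPS (%) measured from
#' a physical reconstruction of a representative ("exemplar") impact.
#' Keys may be given at any specificity: `NA` in a key column means the
#' entry is collapsed over that dimension. Only the four primary event
#' types are strain-scorable.
#'
#' @param entries Tibble with columns `position`, `event_type`,
#'   `velocity_level`, `head_location` (any may be `NA`), `mps_percent`
#'   and optionally `provenance`.
#' @return A validated tibble of class `exemplar_table`.
#' @export
exemplar_table <- function(entries) {
  entries <- tibble::as_tibble(entries)
  for (col in exemplar_key_cols()) {
    if (!col %in% names(entries)) entries[[col]] <- NA_character_
  }
  if (!"mps_percent" %in% names(entries)) {
    stop("exemplar table requires an `mps_percent` column", call. = FALSE)
  }
  if (!"provenance" %in% names(entries)) entries$provenance <- NA_character_
  bad <- !is.na(entries$event_type) &
    !(entries$event_type %in% primary_event_types())
  if (any(bad)) {
    stop("exemplar entries must use primary event types (not 'other')",
         call. = FALSE)
  }
  bad <- is.na(entries$mps_percent) | entries$mps_percent < 0 |
    entries$mps_percent > 100
  if (any(bad)) stop("exemplar mps_percent must lie in [0, 100]", call. = FALSE)
  class(entries) <- c("exemplar_table", class(entries))
  entries
}

#' Bundled default exemplar strain table
#'
#' Mean MPS (%) from the published exemplar physical reconstructions,
#' keyed by position and primary event type, plus per-position entries
#' collapsed over event type. Two printed cells are typeset ambiguously
#' in the source table: the WR-helmet mean is bundled as 22.5 (its
#' confidence bound is the garbled cell), and the DB-helmet cell is NOT
#' bundled at all (its printed mean is on the wrong scale); DB helmet
#' lookups therefore fall back to the DB event-collapsed mean, with the
#' fallback recorded in the provenance. Supply a custom table to
#' override either cell.
#'
#' @return An [exemplar_table()].
#' @export
#' @examples
#' lookup_mps(bundled_exemplar_table(), position = "OL", event_type = "ground")
bundled_exemplar_table <- function() {
  pos <- c("QB", "RB", "WR", "TE", "OL", "DL", "LB", "DB")
  helmet <- c(24.1, 25.3, 22.5, 19.5, 12.7, 19.7, 18.4, NA)
  shoulder <- c(11.9, 16.3, 14.1, 17.0, 14.1, 17.6, 18.3, 18.0)
  hip_thigh <- c(NA, 10.4, 8.7, 11.5, 7.5, 9.6, 21.3, 14.9)
  ground <- c(27.4, 18.0, 25.2, 22.7, 20.8, 12.5, 17.3, 23.5)
  collapsed <- c(25.4, 17.1, 21.8, 19.1, 14.3, 16.3, 18.3, 21.1)
  per_event <- tidyr::pivot_longer(
    tibble::tibble(position = pos, helmet = helmet, shoulder = shoulder,
                   hip_thigh = hip_thigh, ground = ground),
    cols = -"position", names_to = "event_type", values_to = "mps_percent"
  )
  per_event <- per_event[!is.na(per_event$mps_percent), , drop = FALSE]
  per_event$provenance <- "exemplar reconstruction mean (32-game video analysis)"
  # no QB hip/thigh exemplar exists; the DB helmet mean is typeset on the
  # wrong scale in the source and is deliberately left unbundled
  coll <- tibble::tibble(
    position = pos, event_type = NA_character_, mps_percent = collapsed,
    provenance = "event-collapsed exemplar mean (32-game video analysis)"
  )
  out <- dplyr::bind_rows(per_event, coll)
  out$velocity_level <- NA_character_
  out$head_location <- NA_character_
  exemplar_table(out[, c(exemplar_key_cols(), "mps_percent", "provenance")])
}

# Fallback chain, most to least specific. Each element names the key
# columns that must match the impact; the remaining columns must be NA
# (collapsed) in the table entry.
mps_fallback_chain <- function() {
  list(
    exact = exemplar_key_cols(),
    position_event = c("position", "event_type"),
    position_collapsed = "position",
    event_collapsed = "event_type"
  )
}

#' Look up the exemplar MPS for one impact condition
#'
#' Finds the most specific matching entry, falling back from the exact
#' (position, event, velocity level, head location) key through
#' (position, event), the position's event-collapsed mean, and finally
#' the event type collapsed over positions.
#'
#' @param table An [exemplar_table()].
#' @param position,event_type,velocity_level,head_location Key fields of
#'   the impact condition (`NA` allowed below the exact level).
#' @return Named list with `mps_percent`, `provenance` and
#'   `fallback_level` (name of the chain step that matched).
#' @export
lookup_mps <- function(table, position = NA, event_type = NA,
                       velocity_level = NA, head_location = NA) {
  key <- list(position = position, event_type = event_type,
              velocity_level = velocity_level, head_location = head_location)
  for (step in names(mps_fallback_chain())) {
    need <- mps_fallback_chain()[[step]]
    if (any(vapply(key[need], is.na, TRUE))) next
    hit <- rep(TRUE, nrow(table))
    for (col in exemplar_key_cols()) {
      hit <- hit & if (col %in% need) {
        !is.na(table[[col]]) & table[[col]] == key[[col]]
      } else {
        is.na(table[[col]])
      }
    }
    if (any(hit)) {
      i <- which(hit)[1]
      return(list(mps_percent = table$mps_percent[i],
                  provenance = table$provenance[i],
                  fallback_level = step))
    }
  }
  stop("unmapped impact condition: no exemplar entry matches key (position=",
       position, ", event_type=", event_type, ", velocity_level=",
       velocity_level, ", head_location=", head_location,
       ") at any fallback level", call. = FALSE)
}

#' Assign exemplar MPS values to an analysis set
#'
#' For each confirmed primary-event impact, assigns the MPS of the most
#' specific matching exemplar entry (see [lookup_mps()]) and the derived
#' magnitude category.
#'
#' @param impacts Analysis-set impacts (see [select_analysis_set()]).
#' @param table An [exemplar_table()]; defaults to the bundled table.
#' @return `impacts` with `mps_percent`, `magnitude` (ordered factor)
#'   and `mps_provenance` columns filled.
#' @export
assign_mps <- function(impacts, table = bundled_exemplar_table()) {
  impacts <- tibble::as_tibble(impacts)
  if (nrow(impacts) == 0) {
    impacts$mps_percent <- numeric(0)
    impacts$magnitude <- categorize_mps(numeric(0))
    impacts$mps_provenance <- character(0)
    return(impacts)
  }
  if (any(is.na(impacts$event_type) |
            !(impacts$event_type %in% primary_event_types()))) {
    stop("assign_mps requires confirmed impacts of the four primary event ",
         "types; run select_analysis_set() first", call. = FALSE)
  }
  vl <- if ("velocity_level" %in% names(impacts)) {
    as.character(impacts$velocity_level)
  } else rep(NA_character_, nrow(impacts))
  hl <- if ("head_location" %in% names(impacts)) {
    as.character(impacts$head_location)
  } else rep(NA_character_, nrow(impacts))
  hits <- lapply(seq_len(nrow(impacts)), function(i) {
    lookup_mps(table, impacts$position[i], impacts$event_type[i], vl[i], hl[i])
  })
  impacts$mps_percent <- vapply(hits, `[[`, 1.0, "mps_percent")
  impacts$magnitude <- categorize_mps(impacts$mps_percent)
  impacts$mps_provenance <- vapply(hits, function(h) {
    paste0(h$fallback_level, ": ", h$provenance %||% "unspecified")
  }, "")
  impacts
}

#' Reconstruction velocity for an exemplar condition
#'
#' The inbound speed used when physically reconstructing an exemplar:
#' the impact's own speed when the condition holds a single impact, the
#' arithmetic mean for two or three, and the midrange of the velocity
#' level's nominal bounds for four or more. The open-ended top level has
#' no midrange; there the mean of the observed speeds is used, with a
#' warning.
#'
#' @param velocities_mps Speeds of the impacts in the condition (m/s).
#' @param kind `"collision"` or `"fall"`.
#' @param level Velocity level of the condition; inferred from the mean
#'   speed when omitted.
#' @return Reconstruction speed in m/s.
#' @export
#' @examples
#' exemplar_velocity(c(3, 3.2, 2.5, 4.1), "collision", "low") # 3.25
exemplar_velocity <- function(velocities_mps, kind = c("collision", "fall"),
                              level = NULL) {
  kind <- match.arg(kind)
  n <- length(velocities_mps)
  if (n == 0) stop("empty velocity collection", call. = FALSE)
  if (n == 1) return(velocities_mps)
  if (n <= 3) return(mean(velocities_mps))
  if (is.null(level)) level <- as.character(categorize_velocity(mean(velocities_mps), kind))
  lv <- velocity_levels(kind)
  row <- lv[as.character(lv$level) == as.character(level), ]
  if (!nrow(row)) stop("unknown velocity level: ", level, call. = FALSE)
  if (is.infinite(row$upper_mps)) {
    warning("top velocity level has no midrange; using the mean of the ",
            "observed speeds", call. = FALSE)
    return(mean(velocities_mps))
  }
  (row$lower_mps + row$upper_mps) / 2
}

#' Brain tissue viscoelastic material constants
#'
#' Shear-relaxation constants of the viscoelastic brain components used
#' by the finite-element model that produced the exemplar strains: the
#' short- and long-term shear moduli, the decay constant, and the bulk
#' modulus.
#'
#' @return Tibble with `material`, `G0_kPa`, `Ginf_kPa`, `beta_per_s`,
#'   `bulk_modulus_GPa`.
#' @export
brain_materials <- function() {
  tibble::tibble(
    material = c("cerebellum", "brain_stem", "white_matter", "grey_matter"),
    G0_kPa = c(10, 22.5, 12.5, 10),
    Ginf_kPa = c(2, 4.5, 2.5, 2),
    beta_per_s = c(80, 80, 80, 80),
    bulk_modulus_GPa = c(2.19, 2.19, 2.19, 2.19)
  )
}

#' Viscoelastic shear-relaxation modulus
#'
#' Evaluates `G(t) = Ginf + (G0 - Ginf) * exp(-beta * t)`: the
#' relaxation of the shear modulus from its short-term value `G0` to the
#' long-term value `Ginf` with decay constant `beta`.
#'
#' @param t Time(s) in seconds, `>= 0`.
#' @param material A material name from [brain_materials()], a one-row
#'   subset of it, or a list with `G0_kPa`, `Ginf_kPa`, `beta_per_s`.
#' @return Shear modulus in kPa, same length as `t`.
#' @export
#' @examples
#' shear_modulus(0, "grey_matter")     # 10 kPa
#' shear_modulus(0.01, "grey_matter")  # 2 + 8 * exp(-0.8)
shear_modulus <- function(t, material = "grey_matter") {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (is.character(material)) {
    mats <- brain_materials()
    row <- mats[mats$material == material, ]
    if (!nrow(row)) {
      stop("unknown material '", material, "'; see brain_materials()",
           call. = FALSE)
    }
    material <- row
  }
  g0 <- material$G0_kPa; ginf <- material$Ginf_kPa; beta <- material$beta_per_s
  if (g0 < ginf || ginf <= 0 || beta <= 0) {
    stop("material constants must satisfy G0 >= Ginf > 0 and beta > 0",
         call. = FALSE)
  }
  ginf + (g0 - ginf) * exp(-beta * t)
}
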