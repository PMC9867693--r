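#' Filtering thresholds and options
#'
#' One place for every alignment threshold, so the protocol window is data,
#' not code: the season/year window, the sunrise acceptance window, the
#' maximum travel distance, the minimum duration, buffer half-side, the
#' coordinate-equality precision and the survey-style location-name pattern.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of thresholds.
#' @export
filter_config <- function(...) {
  defaults <- list(
    protocols = c("stationary", "traveling", "historical"),
    sunrise_window_hours = 4,
    months = 3:7,
    year_range = c(2010L, 2017L),
    max_distance_km = 4,
    min_duration_min = 6,
    utc_offset_hours = 8,
    points_required = 10L,
    half_side_km = 1,
    coord_precision = 6L,
    bbs_name_pattern = "\\bBBS\\b",
    drop_empty_visits = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown filter_config fields: ", paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, overrides)
}

# A filter report row: which rule removed how many of which records.  Every
# removed record is attributed to exactly the first rule that rejected it, so
# |input| = |kept| + sum(n_removed) always reconciles.
filter_report_row <- function(rule, unit, removed_ids) {
  tibble::tibble(
    rule = rule, unit = unit, n_removed = length(removed_ids),
    removed = list(as.character(removed_ids))
  )
}

empty_report <- function() {
  tibble::tibble(
    rule = character(), unit = character(), n_removed = integer(),
    removed = list()
  )
}

# Apply an ordered list of keep-predicates with first-failing-rule
# attribution.  `rules` is a named list of logical vectors (TRUE = pass).
apply_rules <- function(ids, rules, unit) {
  keep <- rep(TRUE, length(ids))
  report <- empty_report()
  for (rule in names(rules)) {
    pass <- rules[[rule]] & !is.na(rules[[rule]])
    fail <- keep & !pass
    report <- dplyr::bind_rows(report, filter_report_row(rule, unit, ids[fail]))
    keep <- keep & pass
  }
  list(keep = keep, report = report)
}

#' Align checklists with the structured-survey protocol window
#'
#' Applies, in a fixed order with first-failing-rule attribution, the
#' alignment criteria: accepted protocol with complete and approved flags;
#' start time between local sunrise and four hours after sunrise; month and
#' year inside the survey window (March-July 2010-2017 by default); travel
#' distance at most 4 km (boundary inclusive); duration at least 6 min
#' (boundary inclusive).  Failing checklists are reported, never raised.
#'
#' @param checklists Nested checklist tibble from [read_checklists()] or the
#'   generator.  A numeric `sunrise_sec` column, when present, overrides the
#'   sunrise provider.
#' @param sunrise_provider `function(date, lat, lon, utc_offset_hours)`
#'   returning seconds after local midnight; defaults to [sunrise_noaa()].
#' @param config A [filter_config()] list.
#' @return List with `kept` (tibble) and `report` (per-rule attrition tibble
#'   with columns rule, unit, n_removed, removed).
#' @export
filter_checklists <- function(checklists, sunrise_provider = sunrise_noaa,
                              config = filter_config()) {
  cfg <- config
  if (nrow(checklists) == 0) {
    return(list(kept = checklists, report = empty_report()))
  }
  sunrise <- if ("sunrise_sec" %in% names(checklists)) {
    checklists$sunrise_sec
  } else {
    sunrise_provider(
      checklists$date, checklists$latitude, checklists$longitude,
      cfg$utc_offset_hours
    )
  }
  start_sec <- parse_hms(checklists$start_time)
  month <- as.integer(format(checklists$date, "%m"))
  year <- as.integer(format(checklists$date, "%Y"))

  rules <- list(
    protocol_flags = checklists$protocol %in% cfg$protocols &
      checklists$complete_flag & checklists$approved_flag,
    sunrise_window = start_sec >= sunrise &
      start_sec <= sunrise + cfg$sunrise_window_hours * 3600,
    season_year = month %in% cfg$months &
      year >= cfg$year_range[1] & year <= cfg$year_range[2],
    distance = checklists$distance_km <= cfg$max_distance_km,
    duration = checklists$duration_minutes >= cfg$min_duration_min
  )
  res <- apply_rules(checklists$event_id, rules, "checklist")
  list(kept = checklists[res$keep, , drop = FALSE], report = res$report)
}

#' Cull unusable observations from checklists
#'
#' Three rules, in order: (1) a checklist reporting any species as "X" (no
#' count) is removed whole; (2) species rows with a missing count are removed
#' individually, keeping the checklist; (3) group-shared duplicate checklists
#' are reduced to one representative per group identifier — deterministically
#' the lexicographically smallest event id.  Counts in the kept checklists
#' are converted to integers.
#'
#' @param checklists Nested checklist tibble (counts still character).
#' @return List with `kept` and `report`; the report mixes checklist-level
#'   rules (`x_token`, `group_duplicate`) with the observation-level
#'   `missing_count` rule (ids are "event_id/species").
#' @export
cull_observations <- function(checklists) {
  if (nrow(checklists) == 0) {
    return(list(kept = checklists, report = empty_report()))
  }
  has_x <- purrr::map_lgl(
    checklists$observations,
    function(o) any(!is.na(o$count) & o$count == "X")
  )
  report <- filter_report_row("x_token", "checklist", checklists$event_id[has_x])
  kept <- checklists[!has_x, , drop = FALSE]

  missing_ids <- unlist(purrr::map2(
    kept$event_id, kept$observations,
    function(id, o) {
      miss <- o$species[is.na(o$count)]
      if (length(miss)) paste(id, miss, sep = "/") else character(0)
    }
  ))
  kept$observations <- purrr::map(kept$observations, function(o) {
    o <- o[!is.na(o$count), , drop = FALSE]
    o$count <- as.integer(o$count)
    o
  })
  report <- dplyr::bind_rows(
    report,
    filter_report_row("missing_count", "observation", missing_ids)
  )

  grouped <- !is.na(kept$group_id)
  dup <- rep(FALSE, nrow(kept))
  if (any(grouped)) {
    representative <- tapply(kept$event_id[grouped], kept$group_id[grouped],
      FUN = min
    )
    dup[grouped] <- !(kept$event_id[grouped] %in% representative)
  }
  report <- dplyr::bind_rows(
    report,
    filter_report_row("group_duplicate", "checklist", kept$event_id[dup])
  )
  list(kept = kept[!dup, , drop = FALSE], report = report)
}

#' Select structured-survey sites for the comparison
#'
#' Keeps sites with exactly the full point complement (10 by default, so every
#' visit standardizes to 60 min) and without coastline intersection (a
#' per-site boolean attribute).
#'
#' @param sites Site tibble (site_id, centroid_lat, centroid_lon, n_points,
#'   coastal_flag, habitat).
#' @param config A [filter_config()] list (uses `points_required`).
#' @return List with `kept` and `report`.
#' @export
select_bbs_sites <- function(sites, config = filter_config()) {
  if (nrow(sites) == 0) {
    return(list(kept = sites, report = empty_report()))
  }
  rules <- list(
    point_count = sites$n_points == config$points_required,
    coastal = !sites$coastal_flag
  )
  res <- apply_rules(sites$site_id, rules, "site")
  list(kept = sites[res$keep, , drop = FALSE], report = res$report)
}

#' Drop far-distance-band detections from survey visits
#'
#' Removes per-point records in the excluded distance band (">100" m by
#' default) so pooled visit richness reflects the near bands only.
#'
#' @param visits Long visit tibble with a `band` column.
#' @param drop_band Band label to exclude.
#' @return The filtered visit tibble.
#' @export
filter_bbs_bands <- function(visits, drop_band = ">100") {
  visits[visits$band != drop_band, , drop = FALSE]
}

#' Assign checklists to survey sites by square buffer membership
#'
#' A checklist belongs to a site when its coordinates fall inside the
#' axis-aligned square of side `2 * half_side_km` centred on the site
#' centroid, under a local equirectangular projection (cos-latitude scaling of
#' longitude; planar error is negligible at the 2 km scale).  A checklist
#' inside k overlapping buffers yields k assignment pairs; checklists inside
#' no buffer are dropped and reported.
#'
#' @param checklists Nested checklist tibble.
#' @param sites Site tibble (kept sites).
#' @param half_side_km Buffer half-side in km (default 1, i.e. a 2 x 2 km
#'   square).
#' @return List with `assignments` (tibble site_id, event_id) and `report`
#'   (dropped checklists under rule `outside_buffers`).
#' @export
assign_checklists_to_sites <- function(checklists, sites, half_side_km = 1) {
  pairs <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    off <- local_km_offsets(
      checklists$latitude, checklists$longitude,
      sites$centroid_lat[i], sites$centroid_lon[i]
    )
    inside <- abs(off$dx) <= half_side_km & abs(off$dy) <= half_side_km
    tibble::tibble(
      site_id = sites$site_id[i],
      event_id = checklists$event_id[inside]
    )
  })
  dropped <- setdiff(checklists$event_id, pairs$event_id)
  list(
    assignments = pairs,
    report = filter_report_row("outside_buffers", "checklist", dropped)
  )
}

#' Exclude checklists that duplicate structured-survey records
#'
#' Survey volunteers sometimes resubmit their structured counts as
#' checklists.  Two rules, in order: location names matching the survey-style
#' pattern (default regex `\\bBBS\\b`, case-insensitive, catching names like
#' "BBS-A35-19"); and coordinates equal to any survey point coordinate at the
#' configured decimal precision (6 places by default).
#'
#' @param checklists Nested checklist tibble.
#' @param bbs_points Optional point-coordinate tibble (site_id, point_id,
#'   lat, lon); when `NULL` the coordinate rule is skipped.
#' @param config A [filter_config()] list (`bbs_name_pattern`,
#'   `coord_precision`).
#' @return List with `kept` and `report`.
#' @export
exclude_bbs_duplicates <- function(checklists, bbs_points = NULL,
                                   config = filter_config()) {
  if (nrow(checklists) == 0) {
    return(list(kept = checklists, report = empty_report()))
  }
  name_hit <- grepl(config$bbs_name_pattern, checklists$locality,
    perl = TRUE, ignore.case = TRUE
  )
  coord_hit <- rep(FALSE, nrow(checklists))
  if (!is.null(bbs_points) && nrow(bbs_points) > 0) {
    p <- config$coord_precision
    key <- paste(
      round(checklists$latitude, p), round(checklists$longitude, p)
    )
    pkey <- paste(round(bbs_points$lat, p), round(bbs_points$lon, p))
    coord_hit <- key %in% pkey
  }
  rules <- list(bbs_name = !name_hit, bbs_coordinates = !coord_hit)
  res <- apply_rules(checklists$event_id, rules, "checklist")
  list(kept = checklists[res$keep, , drop = FALSE], report = res$report)
}

#' Restrict records to the focal species set
#'
#' Keeps only species flagged diurnal and of resident or summer-visitor
#' status in the species-metadata table (the regularly-breeding diurnal
#' community).  Works on a nested checklist tibble (filters each
#' `observations` entry) or on any long tibble with a `species` column.
#'
#' @param records Nested checklists or a long tibble with `species`.
#' @param species_table Tibble (species, diurnal, status).
#' @return Same shape as `records`, restricted to focal species.
#' @export
filter_species <- function(records, species_table) {
  focal <- species_table$species[
    species_table$diurnal &
      species_table$status %in% c("resident", "summer_visitor")
  ]
  if ("observations" %in% names(records)) {
    records$observations <- purrr::map(
      records$observations,
      function(o) o[o$species %in% focal, , drop = FALSE]
    )
    records
  } else {
    records[records$species %in% focal, , drop = FALSE]
  }
}
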