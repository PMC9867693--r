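#' Column mapping for the EBD-dialect checklist TSV
#'
#' Maps the tab-separated checklist dialect's column headers (matched
#' case-insensitively) onto the internal checklist fields.  Override entries
#' to ingest files whose headers differ from the standard export.
#'
#' @param ... Named overrides, e.g. `locality = "LOCATION NAME"`.
#' @return Named character vector (internal field -> file column).
#' @export
ebd_dialect <- function(...) {
  d <- c(
    event_id = "SAMPLING EVENT IDENTIFIER",
    group_id = "GROUP IDENTIFIER",
    protocol = "PROTOCOL TYPE",
    date = "OBSERVATION DATE",
    start_time = "TIME OBSERVATIONS STARTED",
    duration_minutes = "DURATION MINUTES",
    distance_km = "EFFORT DISTANCE KM",
    latitude = "LATITUDE",
    longitude = "LONGITUDE",
    locality = "LOCALITY",
    complete_flag = "ALL SPECIES REPORTED",
    approved_flag = "APPROVED",
    species = "SCIENTIFIC NAME",
    count = "OBSERVATION COUNT"
  )
  overrides <- unlist(list(...))
  if (length(overrides)) d[names(overrides)] <- overrides
  d
}

# Canonicalize protocol strings to the internal enum.
canonical_protocol <- function(x) {
  x <- tolower(as.character(x))
  dplyr::case_when(
    grepl("stationary", x) ~ "stationary",
    grepl("travel", x) ~ "traveling",
    grepl("historical", x) ~ "historical",
    TRUE ~ "other"
  )
}

#' Read an EBD-dialect checklist file
#'
#' Reads a tab-separated file with one row per species observation and
#' aggregates rows into one checklist per unique sampling-event identifier.
#' Counts are kept as character ("X" and missing tokens survive ingest; they
#' are the business of [cull_observations()]).  Missing required columns are
#' named in the error; rows whose date or start time cannot be parsed raise a
#' row-level error with the file line number.
#'
#' @param path Path to the TSV file.
#' @param dialect Column mapping from [ebd_dialect()].
#' @return A nested tibble, one row per checklist, with an `observations`
#'   list-column of (species, count).
#' @export
read_checklists <- function(path, dialect = ebd_dialect()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  lookup <- setNames(names(raw), toupper(names(raw)))
  missing_cols <- setdiff(toupper(dialect), names(lookup))
  if (length(missing_cols)) {
    abort(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  col <- function(field) raw[[lookup[[toupper(dialect[[field]])]]]]

  if (nrow(raw) == 0) {
    return(tibble::tibble(
      event_id = character(), group_id = character(), protocol = character(),
      date = as.Date(character()), start_time = character(),
      duration_minutes = numeric(), distance_km = numeric(),
      latitude = numeric(), longitude = numeric(), locality = character(),
      complete_flag = logical(), approved_flag = logical(),
      observations = list()
    ))
  }

  dates <- as.Date(col("date"), format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) {
    abort(sprintf(
      "unparseable observation date on line(s) %s",
      paste(head(bad + 1L, 5), collapse = ", ")
    ))
  }
  start_sec <- parse_hms(col("start_time"))
  bad <- which(is.na(start_sec))
  if (length(bad)) {
    abort(sprintf(
      "unparseable start time on line(s) %s",
      paste(head(bad + 1L, 5), collapse = ", ")
    ))
  }

  long <- tibble::tibble(
    event_id = col("event_id"),
    group_id = dplyr::na_if(col("group_id"), ""),
    protocol = canonical_protocol(col("protocol")),
    date = dates,
    start_time = col("start_time"),
    duration_minutes = as.numeric(col("duration_minutes")),
    distance_km = dplyr::coalesce(
      suppressWarnings(as.numeric(col("distance_km"))), 0
    ),
    latitude = as.numeric(col("latitude")),
    longitude = as.numeric(col("longitude")),
    locality = col("locality"),
    complete_flag = col("complete_flag") %in% c("1", "TRUE", "true"),
    approved_flag = col("approved_flag") %in% c("1", "TRUE", "true"),
    species = col("species"),
    count = dplyr::na_if(col("count"), "")
  )
  if (any(is.na(long$duration_minutes) | long$duration_minutes <= 0)) {
    abort("duration minutes must be a positive number on every row")
  }

  # metadata is per-event, so nesting on (species, count) keyed by all other
  # columns yields exactly one row per event_id
  tidyr::nest(long, observations = c("species", "count")) |>
    dplyr::arrange(.data$event_id)
}

#' Read the structured-survey tables
#'
#' Readers for the structured-survey CSV trio (plus the optional point
#' coordinate table): `sites.csv` (site_id, centroid_lat, centroid_lon,
#' n_points, coastal_flag, habitat), `visits.csv` (site_id, year, visit,
#' point_id, species, band, count), `species.csv` (species, diurnal, status)
#' and `points.csv` (site_id, point_id, lat, lon).
#'
#' @param path CSV path.
#' @return A tibble with typed columns.
#' @export
read_bbs_sites <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      centroid_lat = readr::col_double(),
      centroid_lon = readr::col_double(),
      n_points = readr::col_integer(),
      coastal_flag = readr::col_logical(),
      habitat = readr::col_character()
    ), progress = FALSE
  )
}

#' @rdname read_bbs_sites
#' @export
read_bbs_visits <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      year = readr::col_integer(),
      visit = readr::col_integer(),
      point_id = readr::col_character(),
      species = readr::col_character(),
      band = readr::col_character(),
      count = readr::col_integer()
    ), progress = FALSE
  )
}

#' @rdname read_bbs_sites
#' @export
read_species_table <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      species = readr::col_character(),
      diurnal = readr::col_logical(),
      status = readr::col_character()
    ), progress = FALSE
  )
}

#' @rdname read_bbs_sites
#' @export
read_bbs_points <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      point_id = readr::col_character(),
      lat = readr::col_double(),
      lon = readr::col_double()
    ), progress = FALSE
  )
}
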