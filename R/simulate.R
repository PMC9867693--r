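#' Observer model for the detection process
#'
#' Observers modulate the per-species encounter rates multiplicatively:
#' `skill` captures identification/detection ability (trained structured-survey
#' volunteers sit at 1), `weather_penalty` captures reduced bird activity in
#' poor conditions.  Both lie in (0, 1].
#'
#' @param skill,weather_penalty Multipliers in (0, 1].
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(skill = 1, weather_penalty = 1) {
  if (!is.numeric(skill) || skill <= 0 || skill > 1) {
    abort("skill must lie in (0, 1]")
  }
  if (!is.numeric(weather_penalty) || weather_penalty <= 0 || weather_penalty > 1) {
    abort("weather_penalty must lie in (0, 1]")
  }
  structure(list(skill = skill, weather_penalty = weather_penalty),
    class = "observer_model"
  )
}

#' Simulate a bird community with known true richness
#'
#' Draws a ranked log-normal relative-abundance distribution (the standard
#' community-ecology default) and assigns each species a per-minute encounter
#' rate proportional to its relative abundance, so common species are detected
#' quickly and rare species generate singletons at short durations.
#'
#' @param species_count_true Positive integer, true richness.
#' @param distribution_params List with `meanlog` and `sdlog` for the
#'   log-normal rank-abundance draw.
#' @param seed Integer seed; identical seeds give identical communities.
#' @param detection_rates Optional explicit per-species encounter rates per
#'   minute (recycled), overriding the abundance-proportional default.
#' @param encounter_scale Mean per-species encounter rate per minute used for
#'   the default rates (`rate_s = encounter_scale * weight_s * S`).
#' @return Object of class `community_model` with fields `species`,
#'   `species_count_true`, `abundance_weights` (descending, summing to 1),
#'   `detection_rates`, `seed`.
#' @examples
#' cm <- simulate_community(135, seed = 1)
#' sum(cm$abundance_weights)
#' @export
simulate_community <- function(species_count_true,
                               distribution_params = list(meanlog = 0, sdlog = 1),
                               seed = 1L,
                               detection_rates = NULL,
                               encounter_scale = 0.02) {
  s <- species_count_true
  if (!is.numeric(s) || length(s) != 1 || s < 1 || s != round(s)) {
    abort("species_count_true must be a positive integer")
  }
  sdlog <- distribution_params$sdlog %||% 1
  meanlog <- distribution_params$meanlog %||% 0
  if (!is.numeric(sdlog) || sdlog < 0) abort("sdlog must be non-negative")
  w <- withr::with_seed(as.integer(seed), rlnorm(s, meanlog, sdlog))
  w <- sort(w, decreasing = TRUE)
  w <- w / sum(w)
  if (is.null(detection_rates)) {
    rates <- encounter_scale * w * s
  } else {
    rates <- rep_len(detection_rates, s)
  }
  if (any(rates <= 0)) abort("all detection rates must be strictly positive")
  structure(
    list(
      species = sprintf("SP%03d", seq_len(s)),
      species_count_true = as.integer(s),
      abundance_weights = w,
      detection_rates = rates,
      seed = as.integer(seed)
    ),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf(
    "<community_model> %d species; rate range [%.4f, %.4f]/min; seed %d\n",
    x$species_count_true, min(x$detection_rates), max(x$detection_rates), x$seed
  ))
  invisible(x)
}

# Detection + count draw shared by checklist and point-count simulation.
# Each species is an independent Poisson encounter process: detection
# probability 1 - exp(-rate * skill * weather * minutes); detected species get
# a zero-truncated Poisson count with the same mean intensity, so counts are
# positive and scale with abundance and duration.
detect_species <- function(community, observer, minutes) {
  lambda <- community$detection_rates * observer$skill *
    observer$weather_penalty * minutes
  det <- runif(community$species_count_true) < (1 - exp(-lambda))
  if (!any(det)) {
    return(tibble::tibble(species = character(), count = integer()))
  }
  tibble::tibble(
    species = community$species[det],
    count = as.integer(rztpois(sum(det), lambda[det]))
  )
}

#' Simulate one semi-structured checklist
#'
#' One survey event of `duration_minutes`: each species in the community is
#' detected with probability `1 - exp(-rate * skill * weather * duration)` and,
#' if detected, receives a zero-truncated Poisson count whose mean is
#' proportional to its abundance-linked rate times the duration.  The returned
#' row carries the full set of effort-metadata fields the filtering module
#' consumes.
#'
#' @param community A [simulate_community()] result.
#' @param observer An [observer_model()].
#' @param duration_minutes Positive survey duration.
#' @param seed Integer seed.
#' @param event_id,group_id,protocol,date,start_time,latitude,longitude,
#'   distance_km,locality Metadata fields; sensible defaults are supplied so a
#'   bare call produces a valid checklist.
#' @return A one-row tibble with an `observations` list-column of
#'   (species, count).
#' @export
simulate_checklist <- function(community, observer = observer_model(),
                               duration_minutes, seed = 1L,
                               event_id = "EV000001", group_id = NA_character_,
                               protocol = "traveling",
                               date = as.Date("2015-05-01"),
                               start_time = "06:00:00",
                               latitude = 23.5, longitude = 121,
                               distance_km = 1, locality = "Synthetic locality") {
  if (!is.numeric(duration_minutes) || duration_minutes <= 0) {
    abort("duration_minutes must be positive")
  }
  obs <- withr::with_seed(
    as.integer(seed),
    detect_species(community, observer, duration_minutes)
  )
  tibble::tibble(
    event_id = event_id, group_id = group_id, protocol = protocol,
    date = as.Date(date), start_time = start_time,
    duration_minutes = duration_minutes, distance_km = distance_km,
    latitude = latitude, longitude = longitude, locality = locality,
    complete_flag = TRUE, approved_flag = TRUE,
    observations = list(obs)
  )
}

#' Simulate a structured point-count site
#'
#' Emulates a BBS-style site: `years` x `visits_per_year` visits, each visit
#' surveying `points_per_visit` points for `minutes_per_point` minutes (the
#' defaults give the standard 10 x 6 min = 60 min visit).  Detections are
#' drawn per point with the same encounter-process model as checklists, and
#' each per-point record is assigned a distance band so band filtering can be
#' exercised downstream.
#'
#' @param community A [simulate_community()] result.
#' @param years Integer vector of survey years (default 2010:2017).
#' @param visits_per_year,points_per_visit,minutes_per_point Survey design.
#' @param seed Integer seed.
#' @param observer An [observer_model()]; structured surveys default to
#'   skill 1.
#' @param site_id,centroid_lat,centroid_lon,coastal_flag,habitat Site
#'   attributes.
#' @param band_probs Probabilities of the 0-25, 25-100 and >100 m bands for
#'   each detection record.
#' @return List with `site` (one-row tibble) and `visits` (long tibble:
#'   site_id, year, visit, point_id, species, band, count).
#' @export
simulate_bbs_site <- function(community, years = 2010:2017, visits_per_year = 2,
                              points_per_visit = 10, minutes_per_point = 6,
                              seed = 1L, observer = observer_model(),
                              site_id = "S001",
                              centroid_lat = 23.5, centroid_lon = 121,
                              coastal_flag = FALSE, habitat = "forest",
                              band_probs = c(0.3, 0.5, 0.2)) {
  if (visits_per_year < 1 || points_per_visit < 1 || minutes_per_point <= 0 ||
    length(years) < 1) {
    abort("all survey-design parameters must be positive")
  }
  bands <- c("0-25", "25-100", ">100")
  visits <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(years, function(yr) {
      purrr::map_dfr(seq_len(visits_per_year), function(v) {
        purrr::map_dfr(seq_len(points_per_visit), function(p) {
          obs <- detect_species(community, observer, minutes_per_point)
          if (nrow(obs) == 0) {
            return(tibble::tibble(
              point_id = character(), species = character(),
              band = character(), count = integer()
            ))
          }
          obs$point_id <- sprintf("%s-P%02d", site_id, p)
          obs$band <- sample(bands, nrow(obs), replace = TRUE, prob = band_probs)
          obs[, c("point_id", "species", "band", "count")]
        }) |>
          dplyr::mutate(year = yr, visit = v, .before = 1)
      })
    })
  })
  visits <- dplyr::mutate(visits, site_id = site_id, .before = 1)
  site <- tibble::tibble(
    site_id = site_id, centroid_lat = centroid_lat, centroid_lon = centroid_lon,
    n_points = as.integer(points_per_visit), coastal_flag = coastal_flag,
    habitat = habitat
  )
  list(site = site, visits = visits)
}
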