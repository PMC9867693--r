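#' Default configuration for the synthetic-data generator
#'
#' The defaults emulate the study conditions the pipeline assumes: a
#' 135-species log-normal community, 10-point / 6-min-per-point structured
#' visits twice a year over 2010-2017, and semi-structured checklists of
#' 6-200 min (log-uniform) submitted inside the sunrise-to-sunrise+4h window
#' by observers of heterogeneous skill.  Quality defects that the culling
#' rules must remove ("X" counts, missing counts, group-shared duplicates,
#' BBS-style location names, coordinates equal to survey points, non-focal
#' species, out-of-buffer locations) are injected at configurable rates.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list (YAML-serialisable) consumed by [simulate_dataset()].
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_sites = 6L,
    species_count_true = 135L,
    meanlog = 0, sdlog = 1,
    encounter_scale = 0.02,
    checklists_per_site = 20L,
    duration_range = c(6, 200),
    skill_range = c(0.4, 1),
    weather_range = c(0.7, 1),
    stationary_prob = 0.5,
    years = 2010:2017,
    visits_per_year = 2L,
    points_per_visit = 10L,
    minutes_per_point = 6L,
    utc_offset_hours = 8,
    base_lat = 22.8, base_lon = 120.9,
    site_spacing_deg = 0.25,
    # injection rates for records the filters must remove
    x_rate = 0.05,
    missing_rate = 0.05,
    group_share_rate = 0.10,
    bbs_name_rate = 0.03,
    bbs_coord_rate = 0.02,
    nonfocal_rate = 0.05,
    outside_rate = 0.10,
    coastal_rate = 0.10,
    short_points_rate = 0.10,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown sim_config fields: ", paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, overrides)
}

# Non-focal species pool: present in the region but outside the
# diurnal-breeder scope, so the species filter has something to remove.
nonfocal_species_table <- function() {
  tibble::tibble(
    species = c(sprintf("WV%02d", 1:8), sprintf("NO%02d", 1:7)),
    diurnal = c(rep(TRUE, 8), rep(FALSE, 7)),
    status = c(rep("winter_visitor", 8), rep("resident", 7))
  )
}

#' Generate a paired synthetic checklist + structured-survey dataset
#'
#' Builds one community with known true richness, a set of structured-survey
#' sites (each fully surveyed under the configured design by a skill-1
#' observer), and per-site batches of semi-structured checklists with
#' heterogeneous duration, skill and weather, then injects the configured
#' quality defects.  Everything is driven by a single seed; identical seed
#' and config give identical output.
#'
#' @param config A [sim_config()] list.
#' @param seed Optional integer overriding `config$seed`.
#' @return List of tibbles: `checklists` (nested, reader-shaped), `ebd`
#'   (long EBD-dialect table ready to write), `sites`, `visits`, `points`,
#'   `species` (metadata with diurnal/status flags), `truth` (per-checklist
#'   generating parameters and the true richness), plus the `community`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- as.integer(seed %||% cfg$seed)
  seeds <- derive_seeds(seed, 4L)

  community <- simulate_community(
    cfg$species_count_true,
    list(meanlog = cfg$meanlog, sdlog = cfg$sdlog),
    seed = seeds[1],
    encounter_scale = cfg$encounter_scale
  )
  nonfocal <- nonfocal_species_table()

  # --- sites, points and structured visits -------------------------------
  site_ids <- sprintf("S%03d", seq_len(cfg$n_sites))
  sites_setup <- withr::with_seed(seeds[2], tibble::tibble(
    site_id = site_ids,
    centroid_lat = cfg$base_lat + (seq_len(cfg$n_sites) - 1) * cfg$site_spacing_deg,
    centroid_lon = cfg$base_lon + runif(cfg$n_sites, -0.05, 0.05),
    n_points = ifelse(runif(cfg$n_sites) < cfg$short_points_rate,
      sample(6:9, cfg$n_sites, replace = TRUE), cfg$points_per_visit
    ),
    coastal_flag = runif(cfg$n_sites) < cfg$coastal_rate,
    habitat = sample(c("forest", "agriculture", "developed", "grassland", "wetland"),
      cfg$n_sites,
      replace = TRUE, prob = c(.6, .22, .12, .03, .03)
    )
  ))

  site_seeds <- derive_seeds(seeds[2] + 1L, cfg$n_sites)
  bbs <- purrr::map(seq_len(cfg$n_sites), function(i) {
    simulate_bbs_site(
      community,
      years = cfg$years, visits_per_year = cfg$visits_per_year,
      points_per_visit = sites_setup$n_points[i],
      minutes_per_point = cfg$minutes_per_point,
      seed = site_seeds[i],
      site_id = sites_setup$site_id[i],
      centroid_lat = sites_setup$centroid_lat[i],
      centroid_lon = sites_setup$centroid_lon[i],
      coastal_flag = sites_setup$coastal_flag[i],
      habitat = sites_setup$habitat[i]
    )
  })
  sites <- sites_setup
  visits <- purrr::map_dfr(bbs, "visits")

  points <- withr::with_seed(seeds[2] + 2L, purrr::map_dfr(
    seq_len(cfg$n_sites),
    function(i) {
      npt <- sites$n_points[i]
      tibble::tibble(
        site_id = sites$site_id[i],
        point_id = sprintf("%s-P%02d", sites$site_id[i], seq_len(npt)),
        lat = sites$centroid_lat[i] +
          runif(npt, -0.9, 0.9) / KM_PER_DEG_LAT,
        lon = sites$centroid_lon[i] +
          runif(npt, -0.9, 0.9) / km_per_deg_lon(sites$centroid_lat[i])
      )
    }
  ))

  # --- semi-structured checklists ----------------------------------------
  checklists <- withr::with_seed(seeds[3], {
    n_total <- cfg$n_sites * cfg$checklists_per_site
    cl_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    idx <- 0L
    rows <- purrr::map_dfr(seq_len(cfg$n_sites), function(i) {
      purrr::map_dfr(seq_len(cfg$checklists_per_site), function(j) {
        idx <<- idx + 1L
        duration <- exp(runif(1, log(cfg$duration_range[1]), log(cfg$duration_range[2])))
        obs_model <- observer_model(
          skill = runif(1, cfg$skill_range[1], cfg$skill_range[2]),
          weather_penalty = runif(1, cfg$weather_range[1], cfg$weather_range[2])
        )
        date <- as.Date(sprintf(
          "%d-%02d-%02d",
          sample(cfg$years, 1), sample(3:7, 1), sample(1:28, 1)
        ))
        # location: mostly inside the 2x2 km buffer, a fraction well outside
        if (runif(1) < cfg$outside_rate) {
          dx <- runif(1, 1.5, 3) * sample(c(-1, 1), 1)
          dy <- runif(1, 1.5, 3) * sample(c(-1, 1), 1)
        } else {
          dx <- runif(1, -0.85, 0.85)
          dy <- runif(1, -0.85, 0.85)
        }
        lat <- sites$centroid_lat[i] + dy / KM_PER_DEG_LAT
        lon <- sites$centroid_lon[i] + dx / km_per_deg_lon(sites$centroid_lat[i])
        if (runif(1) < cfg$bbs_coord_rate) {
          pt <- points[points$site_id == sites$site_id[i], ]
          k <- sample(nrow(pt), 1)
          lat <- pt$lat[k]
          lon <- pt$lon[k]
        }
        sunrise <- sunrise_noaa(date, lat, lon, cfg$utc_offset_hours)
        start <- format_hms(sunrise + runif(1, 0, 4 * 3600))
        protocol <- if (runif(1) < cfg$stationary_prob) "stationary" else "traveling"
        locality <- if (runif(1) < cfg$bbs_name_rate) {
          sprintf("BBS-A%02d-%02d", i, j)
        } else {
          sprintf("Locality %d-%d", i, j)
        }
        cl <- simulate_checklist(
          community, obs_model, duration,
          seed = cl_seeds[idx],
          event_id = sprintf("EV%06d", idx),
          protocol = protocol, date = date, start_time = start,
          latitude = lat, longitude = lon,
          distance_km = if (protocol == "stationary") 0 else runif(1, 0, 4),
          locality = locality
        )
        cl$site_id_true <- sites$site_id[i]
        cl$skill <- obs_model$skill
        cl$weather_penalty <- obs_model$weather_penalty
        cl
      })
    })

    # non-focal species injection
    rows$observations <- purrr::map(rows$observations, function(obs) {
      if (runif(1) < cfg$nonfocal_rate) {
        extra <- tibble::tibble(
          species = sample(nonfocal$species, 1), count = 1L
        )
        obs <- dplyr::bind_rows(obs, extra)
      }
      obs
    })

    # group-shared duplicates: a second observer submits the same event
    share <- which(runif(nrow(rows)) < cfg$group_share_rate)
    if (length(share)) {
      dup <- rows[share, ]
      gids <- sprintf("G%04d", seq_along(share))
      rows$group_id[share] <- gids
      dup$group_id <- gids
      dup$event_id <- sprintf("EV%06d", nrow(rows) + seq_along(share))
      rows <- dplyr::bind_rows(rows, dup)
    }
    rows
  })

  # count-quality injections, applied on the writable character counts
  checklists <- withr::with_seed(seeds[4], {
    checklists$observations <- purrr::map(checklists$observations, function(obs) {
      obs$count <- as.character(obs$count)
      if (nrow(obs) > 0 && runif(1) < cfg$x_rate) {
        obs$count[sample(nrow(obs), 1)] <- "X"
      }
      if (nrow(obs) > 1 && runif(1) < cfg$missing_rate) {
        obs$count[sample(nrow(obs), 1)] <- NA_character_
      }
      obs
    })
    checklists
  })

  truth <- tibble::tibble(
    event_id = checklists$event_id,
    site_id_true = checklists$site_id_true,
    skill = checklists$skill,
    weather_penalty = checklists$weather_penalty,
    duration_minutes = checklists$duration_minutes,
    true_richness = community$species_count_true
  )

  species <- dplyr::bind_rows(
    tibble::tibble(species = community$species, diurnal = TRUE, status = "resident"),
    nonfocal
  )

  reader_cols <- c(
    "event_id", "group_id", "protocol", "date", "start_time",
    "duration_minutes", "distance_km", "latitude", "longitude", "locality",
    "complete_flag", "approved_flag", "observations"
  )
  list(
    checklists = checklists[, reader_cols],
    ebd = ebd_table(checklists),
    sites = sites, visits = visits, points = points,
    species = species, truth = truth, community = community
  )
}

# Flatten nested checklists into the writable EBD-dialect long table.
ebd_table <- function(checklists) {
  long <- tidyr::unnest(
    checklists[, c(
      "event_id", "group_id", "protocol", "date", "start_time",
      "duration_minutes", "distance_km", "latitude", "longitude", "locality",
      "complete_flag", "approved_flag", "observations"
    )],
    "observations"
  )
  proto <- c(
    stationary = "eBird - Stationary Count",
    traveling = "eBird - Traveling Count",
    historical = "Historical"
  )
  tibble::tibble(
    `SAMPLING EVENT IDENTIFIER` = long$event_id,
    `GROUP IDENTIFIER` = long$group_id,
    `PROTOCOL TYPE` = unname(proto[long$protocol] %|na|% long$protocol),
    `OBSERVATION DATE` = format(long$date, "%Y-%m-%d"),
    `TIME OBSERVATIONS STARTED` = long$start_time,
    `DURATION MINUTES` = long$duration_minutes,
    `EFFORT DISTANCE KM` = long$distance_km,
    LATITUDE = long$latitude,
    LONGITUDE = long$longitude,
    LOCALITY = long$locality,
    `ALL SPECIES REPORTED` = as.integer(long$complete_flag),
    APPROVED = as.integer(long$approved_flag),
    `SCIENTIFIC NAME` = long$species,
    `OBSERVATION COUNT` = as.character(long$count)
  )
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Write a synthetic dataset to disk
#'
#' Writes the EBD-dialect TSV (`ebd.tsv`), the structured-survey CSVs
#' (`sites.csv`, `visits.csv`, `points.csv`, `species.csv`) and the truth
#' file (`truth.csv`) into `dir`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    ebd = file.path(dir, "ebd.tsv"),
    sites = file.path(dir, "sites.csv"),
    visits = file.path(dir, "visits.csv"),
    points = file.path(dir, "points.csv"),
    species = file.path(dir, "species.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_tsv(dataset$ebd, paths$ebd, na = "")
  readr::write_csv(dataset$sites, paths$sites)
  readr::write_csv(dataset$visits, paths$visits)
  readr::write_csv(dataset$points, paths$points)
  readr::write_csv(dataset$species, paths$species)
  readr::write_csv(dataset$truth, paths$truth)
  invisible(paths)
}
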