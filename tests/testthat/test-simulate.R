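test_that("community generation is normalized, ranked and reproducible", {
  cm <- simulate_community(135, list(meanlog = 0, sdlog = 1), seed = 7)
  expect_length(cm$abundance_weights, 135)
  expect_equal(sum(cm$abundance_weights), 1, tolerance = 1e-12)
  expect_true(all(diff(cm$abundance_weights) <= 0))
  expect_true(all(cm$detection_rates > 0))

  cm2 <- simulate_community(135, list(meanlog = 0, sdlog = 1), seed = 7)
  expect_identical(cm$abundance_weights, cm2$abundance_weights)

  single <- simulate_community(1, seed = 1)
  expect_equal(single$abundance_weights, 1)

  expect_error(simulate_community(0), "positive integer")
  expect_error(simulate_community(5, list(sdlog = -1)), "sdlog")
})

test_that("checklist detection follows the Poisson-encounter model limits", {
  cm <- simulate_community(25, seed = 3)
  long <- simulate_checklist(cm, observer_model(), 1e6, seed = 1)
  expect_equal(nrow(long$observations[[1]]), 25) # all species at huge effort
  short <- simulate_checklist(cm, observer_model(), 1e-7, seed = 1)
  expect_equal(nrow(short$observations[[1]]), 0)
  expect_error(simulate_checklist(cm, observer_model(), 0), "positive")
  expect_error(observer_model(skill = 0), "skill")
  expect_error(observer_model(weather_penalty = 1.5), "weather")
})

test_that("mean observed richness matches the closed-form detection expectation", {
  # rates fixed at 0.05/min, skill 1, 60 min: P(detect) = 1 - exp(-3)
  s_true <- 20
  cm <- simulate_community(s_true, seed = 5, detection_rates = 0.05)
  rich <- vapply(1:1000, function(i) {
    nrow(simulate_checklist(cm, observer_model(), 60, seed = i)$observations[[1]])
  }, numeric(1))
  expected <- s_true * (1 - exp(-3))
  mc_se <- sqrt(s_true * (1 - exp(-3)) * exp(-3)) / sqrt(1000)
  expect_lt(abs(mean(rich) - expected), 5 * mc_se + 0.05)
})

test_that("structured site simulation matches the survey design", {
  cm <- simulate_community(30, seed = 2)
  res <- simulate_bbs_site(cm,
    years = 2010:2017, visits_per_year = 2,
    points_per_visit = 10, minutes_per_point = 6, seed = 9
  )
  visits <- res$visits
  expect_equal(nrow(dplyr::distinct(visits, year, visit)), 16)
  expect_equal(res$site$n_points * 6, 60) # visit duration standardizes to 60 min
  expect_lte(dplyr::n_distinct(visits$point_id), 10)
  expect_true(all(visits$band %in% c("0-25", "25-100", ">100")))
  expect_true(all(visits$count >= 1))
  expect_error(simulate_bbs_site(cm, visits_per_year = 0), "positive")
})

test_that("higher observer skill yields stochastically larger visit richness", {
  cm <- simulate_community(40, seed = 11)
  rich_at_skill <- function(skill, seed) {
    v <- simulate_bbs_site(cm,
      years = 2015, visits_per_year = 1, seed = seed,
      observer = observer_model(skill = skill)
    )$visits
    dplyr::n_distinct(v$species)
  }
  lo <- vapply(1:40, function(s) rich_at_skill(0.3, s), numeric(1))
  hi <- vapply(1:40, function(s) rich_at_skill(1.0, s + 1000), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("dataset generation is seed-deterministic and self-consistent", {
  cfg <- sim_config(n_sites = 2, species_count_true = 20, checklists_per_site = 6)
  d1 <- simulate_dataset(cfg, seed = 31)
  d2 <- simulate_dataset(cfg, seed = 31)
  expect_identical(d1$ebd, d2$ebd)
  expect_identical(d1$visits, d2$visits)
  d3 <- simulate_dataset(cfg, seed = 32)
  expect_false(identical(d1$ebd, d3$ebd))

  # truth covers every checklist and the species table covers every record
  expect_setequal(d1$truth$event_id, d1$checklists$event_id)
  obs_species <- unique(unlist(purrr::map(d1$checklists$observations, "species")))
  expect_true(all(obs_species %in% d1$species$species))
  expect_true(all(d1$visits$species %in% d1$species$species))
})

test_that("generated files round-trip through ingest without synthesized defaults", {
  cfg <- sim_config(n_sites = 2, species_count_true = 15, checklists_per_site = 5)
  ds <- simulate_dataset(cfg, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  back <- read_checklists(paths$ebd)
  # the row-per-observation format represents exactly the non-empty checklists
  nonempty <- ds$checklists[
    purrr::map_int(ds$checklists$observations, nrow) > 0,
  ]
  expect_equal(nrow(back), nrow(nonempty))
  expect_setequal(back$event_id, nonempty$event_id)
  # every field the filtering module consumes is populated
  needed <- c(
    "event_id", "group_id", "protocol", "date", "start_time",
    "duration_minutes", "distance_km", "latitude", "longitude", "locality",
    "complete_flag", "approved_flag", "observations"
  )
  expect_true(all(needed %in% names(back)))
  orig <- nonempty[order(nonempty$event_id), ]
  expect_equal(back$duration_minutes, orig$duration_minutes, tolerance = 1e-9)
  expect_equal(back$protocol, orig$protocol)
  sites <- read_bbs_sites(paths$sites)
  expect_equal(sites, ds$sites, ignore_attr = TRUE)
  visits <- read_bbs_visits(paths$visits)
  expect_equal(nrow(visits), nrow(ds$visits))
})
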