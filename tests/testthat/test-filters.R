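test_that("alignment rules remove exactly the intended checklists, boundaries inclusive", {
  cls <- dplyr::bind_rows(
    make_checklist_row("EV01"), # valid
    make_checklist_row("EV02", protocol = "other"), # protocol
    make_checklist_row("EV03", complete_flag = FALSE), # flags
    make_checklist_row("EV04", start_time = "05:00:00"), # before sunrise (05:30)
    make_checklist_row("EV05", start_time = "09:31:00"), # after sunrise + 4 h
    make_checklist_row("EV06", date = as.Date("2015-02-10")), # month
    make_checklist_row("EV07", date = as.Date("2009-05-10")), # year
    make_checklist_row("EV08", distance_km = 4.5), # distance
    make_checklist_row("EV09", distance_km = 4.0), # boundary: kept (<= 4 km)
    make_checklist_row("EV10", duration_minutes = 5), # duration
    make_checklist_row("EV11", duration_minutes = 6) # boundary: kept (>= 6)
  )
  res <- filter_checklists(cls)
  expect_setequal(res$kept$event_id, c("EV01", "EV09", "EV11"))
  removed <- setNames(res$report$removed, res$report$rule)
  expect_setequal(removed$protocol_flags, c("EV02", "EV03"))
  expect_setequal(removed$sunrise_window, c("EV04", "EV05"))
  expect_setequal(removed$season_year, c("EV06", "EV07"))
  expect_equal(removed$distance, "EV08")
  expect_equal(removed$duration, "EV10")
  # attrition reconciles exactly
  expect_equal(nrow(cls), nrow(res$kept) + sum(res$report$n_removed))
})

test_that("each removed checklist is attributed to the first failing rule only", {
  cls <- dplyr::bind_rows(
    make_checklist_row("EV01", protocol = "other", duration_minutes = 2),
    make_checklist_row("EV02", distance_km = 9, duration_minutes = 2)
  )
  res <- filter_checklists(cls)
  expect_equal(res$report$removed[res$report$rule == "protocol_flags"][[1]], "EV01")
  expect_equal(res$report$removed[res$report$rule == "distance"][[1]], "EV02")
  expect_equal(res$report$removed[res$report$rule == "duration"][[1]], character(0))
})

test_that("the NOAA sunrise provider is used when no precomputed column exists", {
  cl <- make_checklist_row("EV01")
  cl$sunrise_sec <- NULL
  # Taiwan, May: sunrise a little after 05:00 local; 06:30 start is inside
  # the window, 04:30 is before sunrise, 11:00 is past sunrise + 4 h.
  sr <- sunrise_noaa(cl$date, cl$latitude, cl$longitude, 8)
  expect_gt(sr, 4.5 * 3600)
  expect_lt(sr, 6 * 3600)
  expect_equal(nrow(filter_checklists(cl)$kept), 1)
  expect_equal(nrow(filter_checklists(
    make_checklist_row("EV02", start_time = "04:00:00", sunrise_sec = NULL)
  )$kept), 0)
})

test_that("culling removes X checklists whole, missing counts singly, and group duplicates", {
  cls <- dplyr::bind_rows(
    make_checklist_row("EV01",
      counts = c(SP001 = 1, SP002 = 2, SP003 = 1, SP004 = 3, SP005 = 2)
    ),
    make_checklist_row("EV02"),
    make_checklist_row("EV03", group_id = "G1"),
    make_checklist_row("EV04", group_id = "G1")
  )
  cls$observations[[1]]$count[2] <- "X" # 5 species, one X -> drop whole
  cls$observations[[2]]$count[2] <- NA_character_ # one missing among 2
  res <- cull_observations(cls)
  expect_setequal(res$kept$event_id, c("EV02", "EV03"))
  expect_equal(nrow(res$kept$observations[[1]]), 1) # species row dropped
  expect_type(res$kept$observations[[1]]$count, "integer")
  rep <- setNames(res$report$removed, res$report$rule)
  expect_equal(rep$x_token, "EV01")
  expect_equal(rep$missing_count, "EV02/SP002")
  expect_equal(rep$group_duplicate, "EV04") # smallest event_id retained
})

test_that("site selection keeps full-complement non-coastal sites", {
  sites <- dplyr::bind_rows(
    make_site_row("S001"),
    make_site_row("S002", n_points = 8), # removed: short
    make_site_row("S003", coastal_flag = TRUE), # removed: coastal
    make_site_row("S004"),
    make_site_row("S005")
  )
  res <- select_bbs_sites(sites)
  expect_setequal(res$kept$site_id, c("S001", "S004", "S005"))
  expect_equal(sum(res$report$n_removed), 2)
  expect_equal(nrow(sites), nrow(res$kept) + sum(res$report$n_removed))
})

test_that("band filtering drops far-band records and pools the rest", {
  visits <- tibble::tibble(
    site_id = "S001", year = 2015L, visit = 1L,
    point_id = c("P01", "P01", "P02", "P02"),
    species = c("SP001", "SP002", "SP002", "SP003"),
    band = c(">100", "0-25", ">100", "25-100"),
    count = c(4L, 2L, 1L, 3L)
  )
  out <- filter_bbs_bands(visits)
  expect_false(any(out$band == ">100"))
  expect_false("SP001" %in% out$species) # only far-band records -> absent
  expect_equal(out$count[out$species == "SP002"], 2L) # near-band count only
  expect_equal(nrow(filter_bbs_bands(visits[0, ])), 0)
  expect_identical(filter_bbs_bands(out), out) # idempotent
})

test_that("buffer assignment uses the 2x2 km square under the local projection", {
  sites <- dplyr::bind_rows(
    make_site_row("S001", lat = 23.5, lon = 121),
    make_site_row("S002", lat = 23.5, lon = 121.012) # ~1.1 km east: overlaps
  )
  km_lon <- 111.320 * cos(23.5 * pi / 180)
  cls <- dplyr::bind_rows(
    make_checklist_row("EV01", latitude = 23.5, longitude = 121), # at centroid
    make_checklist_row("EV02",
      latitude = 23.5, longitude = 121 + 0.6 / km_lon
    ), # inside both buffers
    make_checklist_row("EV03",
      latitude = 23.5, longitude = 121 + 1.5 / km_lon
    ) # 1.5 km east of S001; also > 1 km west of S002? -> check below
  )
  res <- assign_checklists_to_sites(cls, sites[1, ], half_side_km = 1)
  expect_equal(res$assignments$event_id, c("EV01", "EV02"))
  expect_equal(res$report$removed[[1]], "EV03")

  both <- assign_checklists_to_sites(cls[2, ], sites, half_side_km = 1)
  expect_equal(nrow(both$assignments), 2) # one checklist, two overlapping buffers
  expect_setequal(both$assignments$site_id, c("S001", "S002"))
})

test_that("survey-duplicate checklists are excluded by name pattern and coordinates", {
  pts <- tibble::tibble(
    site_id = "S001", point_id = "S001-P01",
    lat = 23.512345, lon = 121.054321
  )
  cls <- dplyr::bind_rows(
    make_checklist_row("EV01", locality = "BBS-A35-19"),
    make_checklist_row("EV02",
      latitude = 23.512345, longitude = 121.054321
    ),
    make_checklist_row("EV03", locality = "Riverside park")
  )
  res <- exclude_bbs_duplicates(cls, pts)
  expect_equal(res$kept$event_id, "EV03")
  rep <- setNames(res$report$removed, res$report$rule)
  expect_equal(rep$bbs_name, "EV01")
  expect_equal(rep$bbs_coordinates, "EV02")
  # coordinate rule respects the configured precision
  near <- make_checklist_row("EV04",
    latitude = 23.5123451, longitude = 121.0543211
  )
  expect_equal(nrow(exclude_bbs_duplicates(near, pts)$kept), 0) # equal at 6 dp
  off <- make_checklist_row("EV05", latitude = 23.51235, longitude = 121.054321)
  expect_equal(nrow(exclude_bbs_duplicates(off, pts)$kept), 1)
  # without a points table only the name rule applies
  expect_equal(nrow(exclude_bbs_duplicates(cls, NULL)$kept), 2)
})

test_that("species filtering keeps only diurnal residents and summer visitors", {
  sp <- tibble::tibble(
    species = c("SP001", "NO01", "WV01", "SV01"),
    diurnal = c(TRUE, FALSE, TRUE, TRUE),
    status = c("resident", "resident", "winter_visitor", "summer_visitor")
  )
  long <- tibble::tibble(
    site_id = "S001", species = sp$species, count = 1:4
  )
  out <- filter_species(long, sp)
  expect_setequal(out$species, c("SP001", "SV01"))

  cl <- make_checklist_row("EV01",
    counts = c(SP001 = 2, NO01 = 1, WV01 = 3)
  )
  out2 <- filter_species(cl, sp)
  expect_equal(out2$observations[[1]]$species, "SP001")
})

test_that("filters are idempotent and order-insensitive in the kept set", {
  cls <- dplyr::bind_rows(
    make_checklist_row("EV01"),
    make_checklist_row("EV02", duration_minutes = 3),
    make_checklist_row("EV03", protocol = "other"),
    make_checklist_row("EV04", distance_km = 8),
    make_checklist_row("EV05")
  )
  once <- filter_checklists(cls)
  twice <- filter_checklists(once$kept)
  expect_identical(once$kept, twice$kept)
  expect_equal(sum(twice$report$n_removed), 0)

  shuffled <- cls[c(4, 2, 5, 1, 3), ]
  res_shuffled <- filter_checklists(shuffled)
  expect_setequal(res_shuffled$kept$event_id, once$kept$event_id)

  cull_once <- cull_observations(once$kept)
  cull_twice <- cull_observations(cull_once$kept)
  expect_equal(
    purrr::map(cull_once$kept$observations, as.data.frame),
    purrr::map(cull_twice$kept$observations, as.data.frame)
  )
})
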