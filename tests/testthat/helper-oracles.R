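# Independent oracles and fixture builders used across the suite.

# Brute-force Chao1: literal evaluation of the formulas from a raw count
# vector, written independently of the package's vectorised path.
oracle_chao1 <- function(counts, variant = "small_sample_corrected") {
  s <- length(counts)
  if (s == 0) {
    return(0)
  }
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  n <- sum(counts)
  add <- if (f2 > 0) f1 * f1 / (2 * f2) else f1 * (f1 - 1) / 2
  if (variant == "small_sample_corrected") add <- add * (n - 1) / n
  s + add
}

# All multisets of positive integers summing to exactly n (integer
# partitions), each one an abundance vector.
integer_partitions <- function(n, max_part = n) {
  if (n == 0) {
    return(list(integer(0)))
  }
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1]] <- c(k, rest)
    }
  }
  out
}

# Grid-search + zoom refinement oracle for the shifted power fit; independent
# of the Levenberg-Marquardt path.
oracle_power_fit <- function(x, y, coef_range = c(0.01, 2),
                             exp_range = c(-0.5, 1), levels = 6) {
  rss <- function(a, b) sum((y - (a * x^b - 1))^2)
  best <- c(mean(coef_range), mean(exp_range))
  ca <- coef_range
  cb <- exp_range
  for (l in seq_len(levels)) {
    as <- seq(ca[1], ca[2], length.out = 41)
    bs <- seq(cb[1], cb[2], length.out = 41)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(rss, grid$a, grid$b)
    best <- unlist(grid[which.min(vals), ])
    da <- diff(ca) / 10
    db <- diff(cb) / 10
    ca <- c(best[1] - da, best[1] + da)
    cb <- c(best[2] - db, best[2] + db)
  }
  unname(best)
}

# A minimal valid checklist row for filter fixtures; override any field.
make_checklist_row <- function(event_id = "EV000001", ...,
                               counts = c(SP001 = 2, SP002 = 1)) {
  row <- tibble::tibble(
    event_id = event_id,
    group_id = NA_character_,
    protocol = "traveling",
    date = as.Date("2015-05-10"),
    start_time = "06:30:00",
    duration_minutes = 30,
    distance_km = 1,
    latitude = 23.5,
    longitude = 121,
    locality = "Riverside park",
    complete_flag = TRUE,
    approved_flag = TRUE,
    sunrise_sec = 5 * 3600 + 30 * 60, # 05:30 precomputed sunrise
    observations = list(tibble::tibble(
      species = names(counts), count = as.character(counts)
    ))
  )
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

make_site_row <- function(site_id = "S001", n_points = 10L,
                          coastal_flag = FALSE, lat = 23.5, lon = 121,
                          habitat = "forest") {
  tibble::tibble(
    site_id = site_id, centroid_lat = lat, centroid_lon = lon,
    n_points = as.integer(n_points), coastal_flag = coastal_flag,
    habitat = habitat
  )
}

small_run_config <- function(seed = 1L, species_count_true = 40L,
                             n_sites = 4L, checklists_per_site = 15L, ...) {
  run_config(
    simulate = sim_config(
      n_sites = n_sites, species_count_true = species_count_true,
      checklists_per_site = checklists_per_site,
      coastal_rate = 0.1, short_points_rate = 0.1, ...
    ),
    compute_bands = FALSE,
    seed = seed
  )
}
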