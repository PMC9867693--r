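#' Configuration for a full pipeline run
#'
#' Exactly one of `simulate` (a [sim_config()] block) or `input` (a named
#' list of file paths: `ebd`, `sites`, `visits`, `species`, optionally
#' `points`) must be active.  All filter thresholds live in `filters`; the
#' standardized comparison duration defaults to 60 min.
#'
#' @param simulate Optional [sim_config()] list.
#' @param input Optional named list of input paths.
#' @param filters A [filter_config()] list.
#' @param chao1_variant Chao1 variant for all estimates.
#' @param standardized_duration Duration (min) at which the four comparisons
#'   are standardized.
#' @param n_sims Monte-Carlo draws for confidence bands.
#' @param compute_bands Whether to compute the Monte-Carlo bands.
#' @param band_grid Durations at which bands are evaluated.
#' @param seed Master seed for every source of randomness in the run.
#' @param out_dir Optional directory for the persisted CSV artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = sim_config(), input = NULL,
                       filters = filter_config(),
                       chao1_variant = c("small_sample_corrected", "classic"),
                       standardized_duration = 60,
                       n_sims = 10000L, compute_bands = TRUE,
                       band_grid = seq(6, 200, length.out = 98),
                       seed = 1L, out_dir = NULL) {
  chao1_variant <- match.arg(chao1_variant)
  if (is.null(simulate) == is.null(input)) {
    abort("exactly one of `simulate` or `input` must be supplied")
  }
  if (standardized_duration <= 0 || n_sims < 1) {
    abort("standardized_duration and n_sims must be positive")
  }
  structure(
    list(
      simulate = simulate, input = input, filters = filters,
      chao1_variant = chao1_variant,
      standardized_duration = standardized_duration,
      n_sims = as.integer(n_sims), compute_bands = compute_bands,
      band_grid = band_grid, seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with any of the [run_config()] fields; `simulate`
#'   and `filters` sub-blocks are merged over their defaults.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$input)) NULL else do.call(sim_config, y$simulate %||% list())
  filt <- do.call(filter_config, y$filters %||% list())
  args <- y[setdiff(names(y), c("simulate", "input", "filters"))]
  do.call(run_config, c(
    list(simulate = sim, input = y$input, filters = filt), args
  ))
}

bias_types <- c("obs_vs_obs", "est_vs_obs", "obs_vs_est", "est_vs_est")

#' Count checklists at or above parity with the reference
#'
#' @param bias_records Bias-record tibble from [bias_table()].
#' @param bias_type One of `"obs_vs_obs"`, `"est_vs_obs"`, `"obs_vs_est"`,
#'   `"est_vs_est"`.
#' @return Integer count of records of that type with bias >= 0 (boundary
#'   inclusive).
#' @export
count_nonnegative_bias <- function(bias_records, bias_type) {
  bias_type <- match.arg(bias_type, bias_types)
  sum(bias_records$bias_type == bias_type & bias_records$bias >= 0)
}

#' Run the full comparison pipeline
#'
#' Simulate (or ingest) -> filter with attrition logging -> per-checklist and
#' per-visit Chao1 -> site references -> four bias comparisons -> shifted
#' power-function fits -> standardized 60-min comparison, parity counts and
#' singleton diagnostics.  Identical config and seed give identical output;
#' any stage failure aborts with the stage name.
#'
#' @param config A [run_config()] (or a path to a YAML file for
#'   [load_run_config()]).
#' @param seed Optional integer overriding `config$seed`.
#' @param quiet Suppress per-rule attrition messages.
#' @return Object of class `richness_run`: list with `attrition`,
#'   `site_references`, `checklist_richness`, `bias_records`, `fits` (named
#'   list of `power_fit`), `fit_table`, `standardized`, `nonnegative_counts`,
#'   `singleton_relation`, `bands`, `config`, `seed`.
#' @export
run_pipeline <- function(config = run_config(), seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  cfg <- config
  seed <- as.integer(seed %||% cfg$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  attrition <- list()
  note <- function(stage, report) {
    if (nrow(report) == 0) {
      return(invisible())
    }
    for (k in seq_len(nrow(report))) {
      say(
        "[%s] %s: removed %d %s(s)", stage, report$rule[k],
        report$n_removed[k], report$unit[k]
      )
    }
    attrition[[length(attrition) + 1]] <<- dplyr::mutate(
      report,
      stage = stage, .before = 1
    )
  }

  # --- acquire -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    ds <- simulate_dataset(cfg$simulate, seed = seed)
    # write-and-read round trip so ingest is exercised on every run
    tmp <- file.path(tempdir(), sprintf("checkrich-sim-%d", seed))
    paths <- write_dataset(ds, tmp)
    checklists <- read_checklists(paths$ebd)
    sites <- ds$sites
    visits <- ds$visits
    points <- ds$points
    species_tbl <- ds$species
  } else {
    inp <- cfg$input
    for (f in c("ebd", "sites", "visits", "species")) {
      if (is.null(inp[[f]])) stop_stage("ingest", "input path `%s` missing", f)
    }
    checklists <- read_checklists(inp$ebd)
    sites <- read_bbs_sites(inp$sites)
    visits <- read_bbs_visits(inp$visits)
    species_tbl <- read_species_table(inp$species)
    points <- if (!is.null(inp$points)) read_bbs_points(inp$points) else NULL
  }
  say("[ingest] %d checklists, %d sites, %d visit records",
    nrow(checklists), nrow(sites), nrow(visits))

  # --- checklist filtering ------------------------------------------------
  fc <- filter_checklists(checklists, config = cfg$filters)
  note("align", fc$report)
  cu <- cull_observations(fc$kept)
  note("cull", cu$report)
  bd <- exclude_bbs_duplicates(cu$kept, points, cfg$filters)
  note("bbs_duplicates", bd$report)
  n_obs_before <- sum(purrr::map_int(bd$kept$observations, nrow))
  cl <- filter_species(bd$kept, species_tbl)
  n_obs_after <- sum(purrr::map_int(cl$observations, nrow))
  note("species_filter", tibble::tibble(
    rule = "nonfocal_species", unit = "observation",
    n_removed = n_obs_before - n_obs_after, removed = list(character())
  ))

  # --- structured-survey side --------------------------------------------
  ss <- select_bbs_sites(sites, cfg$filters)
  note("site_selection", ss$report)
  visits_kept <- visits[visits$site_id %in% ss$kept$site_id, , drop = FALSE]
  roster <- dplyr::distinct(visits_kept, .data$site_id, .data$year, .data$visit)
  visits_kept <- filter_bbs_bands(visits_kept)
  visits_kept <- filter_species(visits_kept, species_tbl)
  if (nrow(visits_kept) == 0) {
    stop_stage("site_reference", "no visit records remain after filtering")
  }
  site_refs <- site_reference(
    visits_kept, roster,
    variant = cfg$chao1_variant,
    drop_empty_visits = isTRUE(cfg$filters$drop_empty_visits)
  )

  # --- assignment and richness -------------------------------------------
  as_res <- assign_checklists_to_sites(cl, ss$kept, cfg$filters$half_side_km)
  note("assignment", as_res$report)
  assignments <- as_res$assignments

  obs_long <- tidyr::unnest(
    cl[, c("event_id", "observations")], "observations"
  )
  cl_rich <- richness_table(obs_long,
    unit_col = "event_id", species_col = "species", count_col = "count",
    variant = cfg$chao1_variant
  ) |>
    dplyr::rename(event_id = "unit_id")
  # checklists emptied by culling/species filtering still carry richness 0
  empty_ids <- setdiff(cl$event_id, cl_rich$event_id)
  if (length(empty_ids)) {
    cl_rich <- dplyr::bind_rows(cl_rich, tibble::tibble(
      event_id = empty_ids, s_obs = 0L, f1 = 0L, f2 = 0L, n = 0,
      chao1 = 0, variant = cfg$chao1_variant, singleton_pct = NA_real_
    ))
  }
  cl_rich <- dplyr::left_join(
    cl_rich,
    cl[, c("event_id", "duration_minutes")],
    by = "event_id"
  )

  # --- bias and effort models --------------------------------------------
  records <- bias_table(assignments, site_refs, cl_rich)
  if (nrow(records) == 0) {
    stop_stage(
      "bias",
      "no checklist-site pairs remain after filtering and assignment; %s",
      "relax the filters or enlarge the input"
    )
  }
  say("[bias] %d records (%d checklist-site pairs)",
    nrow(records), nrow(records) / 4L)

  fits <- purrr::map(setNames(bias_types, bias_types), function(type) {
    sub <- records[records$bias_type == type, , drop = FALSE]
    if (nrow(sub) < 3) {
      stop_stage("fit", "fewer than 3 bias points for %s", type)
    }
    fit_power(sub$duration_minutes, sub$bias)
  })
  fit_table <- purrr::imap_dfr(
    fits,
    function(f, type) dplyr::mutate(tidy(f), bias_type = type, .before = 1)
  )

  sd <- cfg$standardized_duration
  standardized <- purrr::imap_dfr(fits, function(f, type) {
    tibble::tibble(
      bias_type = type, duration = sd,
      bias = predict_bias(f, sd),
      completeness_pct = completeness_percent(f, sd),
      completeness_int = round(completeness_percent(f, sd)),
      crossing_duration = crossing_duration(f,
        x_min = min(f$data$x), x_max = max(f$data$x)
      )
    )
  })

  nonneg <- tibble::tibble(
    bias_type = bias_types,
    n_nonnegative = vapply(
      bias_types, function(t) count_nonnegative_bias(records, t), integer(1),
      USE.NAMES = FALSE
    ),
    n_records = vapply(
      bias_types, function(t) sum(records$bias_type == t), integer(1),
      USE.NAMES = FALSE
    )
  )

  singleton_rel <- records |>
    dplyr::filter(.data$bias_type == "est_vs_obs") |>
    dplyr::inner_join(
      cl_rich[, c("event_id", "singleton_pct")],
      by = "event_id"
    ) |>
    singleton_bias_relation()

  bands <- NULL
  if (isTRUE(cfg$compute_bands)) {
    band_seeds <- derive_seeds(seed + 7L, length(fits))
    bands <- purrr::imap(fits, function(f, type) {
      mc_confidence_band(
        f, cfg$band_grid,
        n_sims = cfg$n_sims,
        seed = band_seeds[match(type, names(fits))]
      )
    })
  }

  attrition_tbl <- if (length(attrition)) {
    dplyr::bind_rows(attrition)
  } else {
    dplyr::mutate(empty_report(), stage = character(), .before = 1)
  }

  run <- structure(
    list(
      attrition = attrition_tbl,
      site_references = site_refs,
      checklist_richness = cl_rich,
      assignments = assignments,
      bias_records = records,
      fits = fits,
      fit_table = fit_table,
      standardized = standardized,
      nonnegative_counts = nonneg,
      singleton_relation = singleton_rel,
      bands = bands,
      config = cfg,
      seed = seed
    ),
    class = "richness_run"
  )
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' Persist the artifacts of a pipeline run
#'
#' Writes every reported figure's backing table as CSV (attrition, site
#' references, checklist richness, bias records, fit summaries, standardized
#' comparison, parity counts, singleton relation, confidence bands) plus a
#' machine-readable `run_summary.json`.
#'
#' @param run A `richness_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  att <- run$attrition
  att$removed <- vapply(att$removed, paste, character(1), collapse = ";")
  readr::write_csv(att, file.path(dir, "attrition.csv"))
  readr::write_csv(run$site_references, file.path(dir, "site_references.csv"))
  readr::write_csv(run$checklist_richness, file.path(dir, "checklist_richness.csv"))
  readr::write_csv(run$bias_records, file.path(dir, "bias_records.csv"))
  readr::write_csv(run$fit_table, file.path(dir, "fits.csv"))
  readr::write_csv(run$standardized, file.path(dir, "standardized.csv"))
  readr::write_csv(run$nonnegative_counts, file.path(dir, "nonnegative_counts.csv"))
  readr::write_csv(run$singleton_relation, file.path(dir, "singleton_relation.csv"))
  if (!is.null(run$bands)) {
    bands <- purrr::imap_dfr(
      run$bands,
      function(b, type) dplyr::mutate(tibble::as_tibble(b), bias_type = type, .before = 1)
    )
    readr::write_csv(bands, file.path(dir, "bands.csv"))
  }
  summary <- list(
    seed = run$seed,
    standardized = run$standardized,
    nonnegative_counts = run$nonnegative_counts,
    singleton_relation = run$singleton_relation
  )
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.richness_run <- function(x, ...) {
  cat("<richness_run>  seed", x$seed, "\n")
  cat(sprintf(
    "  %d bias records across %d sites; %d checklists\n",
    nrow(x$bias_records), nrow(x$site_references),
    length(unique(x$bias_records$event_id))
  ))
  cat(sprintf("  standardized comparison at %g min:\n", x$standardized$duration[1]))
  for (k in seq_len(nrow(x$standardized))) {
    cat(sprintf(
      "    %-10s bias %+.3f  completeness %3d%%\n",
      x$standardized$bias_type[k], x$standardized$bias[k],
      x$standardized$completeness_int[k]
    ))
  }
  invisible(x)
}
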