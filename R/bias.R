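#' Per-site reference richness from structured visits
#'
#' Pools each visit across its points (summing counts per species), computes
#' per-visit observed richness and the per-visit Chao1 estimate, and averages
#' both over all visits: `A_i` is the mean observed and `B_i` the mean
#' estimated richness of site i.  Visits conducted but yielding no records
#' after band/species filtering contribute richness 0 to the means (they can
#' be dropped instead via `drop_empty_visits`); supplying `visit_index` (the
#' roster of conducted visits) is what makes such empty visits visible.
#'
#' @param visits Long visit tibble (site_id, year, visit, species, count),
#'   already band- and species-filtered.
#' @param visit_index Optional roster tibble (site_id, year, visit) of all
#'   conducted visits; defaults to the visits present in `visits`.
#' @param variant Chao1 variant, see [chao1()].
#' @param drop_empty_visits If TRUE, visits with zero detections are excluded
#'   from the means instead of contributing 0.
#' @return Tibble (site_id, A_i, B_i, n_visits).
#' @export
site_reference <- function(visits, visit_index = NULL,
                           variant = c("small_sample_corrected", "classic"),
                           drop_empty_visits = FALSE) {
  variant <- match.arg(variant)
  pooled <- visits |>
    dplyr::summarise(
      count = sum(.data$count),
      .by = c("site_id", "year", "visit", "species")
    )
  per_visit <- pooled |>
    dplyr::summarise(
      s_obs = dplyr::n(),
      f1 = sum(.data$count == 1),
      f2 = sum(.data$count == 2),
      n = sum(.data$count),
      .by = c("site_id", "year", "visit")
    ) |>
    dplyr::mutate(est = chao1_value(.data$s_obs, .data$f1, .data$f2, .data$n, variant))

  if (is.null(visit_index)) {
    visit_index <- dplyr::distinct(
      visits, .data$site_id, .data$year, .data$visit
    )
  }
  full <- dplyr::left_join(
    visit_index, per_visit,
    by = c("site_id", "year", "visit")
  ) |>
    dplyr::mutate(
      s_obs = dplyr::coalesce(.data$s_obs, 0L),
      est = dplyr::coalesce(.data$est, 0)
    )
  if (drop_empty_visits) full <- full[full$s_obs > 0, , drop = FALSE]
  if (nrow(full) == 0) abort("site_reference(): no visits to average")

  full |>
    dplyr::summarise(
      A_i = mean(.data$s_obs),
      B_i = mean(.data$est),
      n_visits = dplyr::n(),
      .by = "site_id"
    )
}

#' Relative bias of a richness value against a reference
#'
#' `bias = (numerator - reference) / reference`: 0 means parity with the
#' reference, -1 means nothing was recorded.  Vectorized; no clamping.
#'
#' @param numerator_richness Observed or estimated richness (non-negative).
#' @param reference Positive reference richness (e.g. `A_i` or `B_i`).
#' @param site_id Optional identifiers used in the error message when a
#'   non-positive reference is encountered.
#' @return Numeric vector of biases (each >= -1 for non-negative numerators).
#' @export
bias <- function(numerator_richness, reference, site_id = NULL) {
  bad <- !is.na(reference) & reference <= 0
  if (any(bad)) {
    where <- if (!is.null(site_id)) {
      paste0(" (site ", paste(unique(site_id[bad]), collapse = ", "), ")")
    } else {
      ""
    }
    abort(paste0("reference richness must be positive", where))
  }
  (numerator_richness - reference) / reference
}

#' All four bias records for every assigned checklist
#'
#' For each (checklist, site) assignment pair, emits the four relative-bias
#' comparisons: observed checklist richness vs mean observed reference
#' (`obs_vs_obs`), Chao1 checklist estimate vs mean observed (`est_vs_obs`),
#' observed vs mean Chao1 reference (`obs_vs_est`), and estimate vs estimate
#' (`est_vs_est`).  A checklist assigned to k overlapping sites contributes
#' k records of each type.
#'
#' @param assignments Tibble (site_id, event_id) from
#'   [assign_checklists_to_sites()].
#' @param site_references Tibble (site_id, A_i, B_i) from [site_reference()].
#' @param checklist_richness Tibble (unit_id or event_id, duration_minutes,
#'   s_obs, chao1), e.g. from [richness_table()] joined with durations.
#' @return Tibble (site_id, event_id, duration_minutes, bias_type,
#'   numerator, reference, bias).
#' @export
bias_table <- function(assignments, site_references, checklist_richness) {
  cr <- checklist_richness
  if (!"event_id" %in% names(cr) && "unit_id" %in% names(cr)) {
    cr <- dplyr::rename(cr, event_id = "unit_id")
  }
  joined <- assignments |>
    dplyr::inner_join(site_references, by = "site_id") |>
    dplyr::inner_join(
      cr[, c("event_id", "duration_minutes", "s_obs", "chao1")],
      by = "event_id"
    )
  long <- dplyr::bind_rows(
    dplyr::mutate(joined,
      bias_type = "obs_vs_obs",
      numerator = .data$s_obs, reference = .data$A_i
    ),
    dplyr::mutate(joined,
      bias_type = "est_vs_obs",
      numerator = .data$chao1, reference = .data$A_i
    ),
    dplyr::mutate(joined,
      bias_type = "obs_vs_est",
      numerator = .data$s_obs, reference = .data$B_i
    ),
    dplyr::mutate(joined,
      bias_type = "est_vs_est",
      numerator = .data$chao1, reference = .data$B_i
    )
  )
  long |>
    dplyr::mutate(
      bias = bias(.data$numerator, .data$reference, .data$site_id)
    ) |>
    dplyr::select(
      "site_id", "event_id", "duration_minutes", "bias_type",
      "numerator", "reference", "bias"
    ) |>
    dplyr::arrange(.data$event_id, .data$site_id, .data$bias_type)
}

#' Relationship between singleton percentage and bias
#'
#' Singleton-heavy checklists inflate Chao1, which shows up as a positive
#' association between the singleton percentage and the bias value.  Reports
#' the Spearman rank correlation and the ordinary-least-squares slope of
#' bias on singleton percentage with its p-value; the sign is the headline.
#'
#' @param data Data frame holding both columns.
#' @param bias_col,singleton_col Column names.
#' @return One-row tibble (n, spearman_rho, spearman_p, slope, slope_se,
#'   slope_p).  With a constant singleton percentage the slope is reported
#'   as 0 and the correlation as missing.
#' @export
singleton_bias_relation <- function(data, bias_col = "bias",
                                    singleton_col = "singleton_pct") {
  x <- data[[singleton_col]]
  y <- data[[bias_col]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || var(x) == 0) {
    return(tibble::tibble(
      n = n, spearman_rho = NA_real_, spearman_p = NA_real_,
      slope = if (n >= 3) 0 else NA_real_,
      slope_se = NA_real_, slope_p = NA_real_
    ))
  }
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    n = n,
    spearman_rho = unname(sp$estimate),
    spearman_p = sp$p.value,
    slope = sm["x", "Estimate"],
    slope_se = sm["x", "Std. Error"],
    slope_p = sm["x", "Pr(>|t|)"]
  )
}
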