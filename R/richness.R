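#' Build the sufficient statistics of an abundance sample
#'
#' Collapses a set of (species, count) observations into the statistics the
#' Chao1 estimator needs: observed richness `s_obs`, the numbers of singletons
#' `f1` and doubletons `f2`, and the total count `n`.  Rows for the same
#' species are summed before tallying, so a species reported twice with counts
#' 2 and 1 is a single species with count 3, not a singleton.
#'
#' @param observations A data frame with columns `species` and `count`
#'   (positive integers; culling must already have removed "X" and missing
#'   counts), or a named numeric vector of counts.
#' @return An object of class `abundance_sample`: a list with `counts` (named
#'   integer vector), `s_obs`, `f1`, `f2`, `n`.
#' @examples
#' make_sample(data.frame(species = c("A", "B", "C", "D"), count = c(1, 1, 2, 3)))
#' @export
make_sample <- function(observations) {
  if (is.data.frame(observations)) {
    species <- as.character(observations$species)
    count <- observations$count
  } else {
    species <- names(observations)
    count <- unname(observations)
  }
  count <- suppressWarnings(as.numeric(count))
  if (length(count) && (anyNA(count) || any(count <= 0) || any(count != round(count)))) {
    abort("all counts must be positive integers; apply cull_observations() first")
  }
  counts <- vapply(split(count, species), sum, numeric(1))
  structure(
    list(
      counts = counts,
      s_obs = length(counts),
      f1 = sum(counts == 1),
      f2 = sum(counts == 2),
      n = sum(counts)
    ),
    class = "abundance_sample"
  )
}

#' @export
print.abundance_sample <- function(x, ...) {
  cat(sprintf(
    "<abundance_sample> S_obs = %d, f1 = %d, f2 = %d, n = %d\n",
    x$s_obs, x$f1, x$f2, x$n
  ))
  invisible(x)
}

# Scalar-statistics core shared by chao1() and the batch interface.
# classic:            S + f1^2 / (2 f2)              (f2 > 0)
#                     S + f1 (f1 - 1) / 2            (f2 = 0)
# small_sample_corrected multiplies the added term by (n - 1) / n, the
# convention of the iNEXT / SpadeR family.
chao1_value <- function(s_obs, f1, f2, n,
                        variant = c("small_sample_corrected", "classic")) {
  variant <- match.arg(variant)
  corr <- if (variant == "small_sample_corrected") (n - 1) / pmax(n, 1) else 1
  add <- ifelse(f2 > 0, f1^2 / (2 * f2), f1 * (f1 - 1) / 2)
  ifelse(s_obs == 0, 0, s_obs + corr * add)
}

#' Chao1 nonparametric species-richness estimate
#'
#' The Chao1 estimator infers undetected species from the rare tail of an
#' abundance sample: with `f1` singletons and `f2` doubletons among `S_obs`
#' observed species it estimates a lower bound for true richness.  The classic
#' form adds `f1^2 / (2 f2)` (or `f1 (f1 - 1) / 2` when no doubletons were
#' seen); the small-sample-corrected form — the default, matching the
#' iNEXT-family convention — multiplies the added term by `(n - 1) / n`.
#' When there are no singletons the estimate equals `S_obs` exactly.
#'
#' @param sample An [make_sample()] result, or a data frame / named vector
#'   accepted by it.
#' @param variant `"small_sample_corrected"` (default) or `"classic"`.
#' @return An object of class `richness_estimate`: list with `estimate`,
#'   `variant`, `s_obs`, `f1`, `f2`, `n`, and `empty` (TRUE when the sample
#'   had no observations, in which case the estimate is 0 and a warning is
#'   raised rather than an error).
#' @examples
#' s <- make_sample(c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 5))
#' chao1(s, "classic")$estimate # 8.25
#' chao1(s)$estimate # 8.0625
#' @export
chao1 <- function(sample, variant = c("small_sample_corrected", "classic")) {
  variant <- match.arg(variant)
  if (!inherits(sample, "abundance_sample")) sample <- make_sample(sample)
  empty <- sample$s_obs == 0
  if (empty) warn("empty sample: Chao1 estimate reported as 0")
  structure(
    list(
      estimate = chao1_value(sample$s_obs, sample$f1, sample$f2, sample$n, variant),
      variant = variant,
      s_obs = sample$s_obs, f1 = sample$f1, f2 = sample$f2, n = sample$n,
      empty = empty
    ),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "<richness_estimate> Chao1 (%s) = %.4f  [S_obs = %d, f1 = %d, f2 = %d, n = %d]\n",
    x$variant, x$estimate, x$s_obs, x$f1, x$f2, x$n
  ))
  invisible(x)
}

#' Percentage of observed species that are singletons
#'
#' Singleton-heavy samples are the signature of under-sampling (short
#' durations) and drive Chao1 upward; this diagnostic is `100 * f1 / S_obs`.
#'
#' @inheritParams chao1
#' @return Percentage in \[0, 100\]; `NA` for an empty sample.
#' @export
singleton_percentage <- function(sample) {
  if (!inherits(sample, "abundance_sample")) sample <- make_sample(sample)
  if (sample$s_obs == 0) {
    return(NA_real_)
  }
  100 * sample$f1 / sample$s_obs
}

#' Batch richness estimation over a long observation table
#'
#' Tidy batch interface: one row per (unit, species, count) in, one row per
#' unit out with the Chao1 sufficient statistics, estimate and singleton
#' percentage.  Duplicate (unit, species) rows are summed first.
#'
#' @param data Data frame with at least the three named columns.
#' @param unit_col,species_col,count_col Column names (strings).
#' @param variant Chao1 variant, see [chao1()].
#' @return A tibble with columns `unit_id`, `s_obs`, `f1`, `f2`, `n`,
#'   `chao1`, `variant`, `singleton_pct`, one row per unit.
#' @export
richness_table <- function(data, unit_col = "unit_id", species_col = "species",
                           count_col = "count",
                           variant = c("small_sample_corrected", "classic")) {
  variant <- match.arg(variant)
  df <- tibble::tibble(
    unit_id = as.character(data[[unit_col]]),
    species = as.character(data[[species_col]]),
    count = as.numeric(data[[count_col]])
  )
  if (nrow(df) && (anyNA(df$count) || any(df$count <= 0))) {
    abort("richness_table() requires positive counts; apply culling first")
  }
  df |>
    dplyr::summarise(count = sum(.data$count), .by = c("unit_id", "species")) |>
    dplyr::summarise(
      s_obs = dplyr::n(),
      f1 = sum(.data$count == 1),
      f2 = sum(.data$count == 2),
      n = sum(.data$count),
      .by = "unit_id"
    ) |>
    dplyr::mutate(
      chao1 = chao1_value(.data$s_obs, .data$f1, .data$f2, .data$n, variant),
      variant = variant,
      singleton_pct = ifelse(.data$s_obs > 0, 100 * .data$f1 / .data$s_obs, NA_real_)
    )
}
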