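#' Tidy a shifted-power-function fit
#'
#' @param x A `power_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: term, estimate, std.error,
#'   statistic, p.value.
#' @method tidy power_fit
#' @export
tidy.power_fit <- function(x, ...) {
  tibble::tibble(
    term = c("coef", "exp"),
    estimate = c(x$coef, x$exp),
    std.error = c(x$se_coef, x$se_exp),
    statistic = c(x$t_coef, x$t_exp),
    p.value = c(x$p_coef, x$p_exp)
  )
}

#' Glance at a shifted-power-function fit
#'
#' @param x A `power_fit`.
#' @param ... Unused.
#' @return One-row tibble: sigma (residual SE), df.residual, nobs,
#'   converged, iterations.
#' @method glance power_fit
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$residual_se,
    df.residual = x$dof,
    nobs = x$n_points,
    converged = x$converged,
    iterations = x$iterations
  )
}
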