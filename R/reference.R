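#' Published effort-curve parameter estimates for the Taiwan comparison
#'
#' Previously published least-squares estimates of the shifted power function
#' `bias = coef * duration^exp - 1` for the four eBird-vs-BBS richness
#' comparisons in Taiwan (564 checklists across 92 survey sites, so 562
#' residual degrees of freedom in each fit).  Useful as worked-example
#' inputs: evaluating these curves at the standardized 60-min duration
#' reproduces the published completeness percentages.
#'
#' @return Tibble with one row per comparison (`obs_vs_obs`, `est_vs_obs`,
#'   `obs_vs_est`, `est_vs_est`) and columns `coef`, `exp`, `se_coef`,
#'   `se_exp`, `residual_se`, `dof`.
#' @examples
#' ref <- reference_power_fits()
#' fit <- power_fit(ref$coef[1], ref$exp[1])
#' round(completeness_percent(fit, 60)) # 56
#' @export
reference_power_fits <- function() {
  tibble::tibble(
    comparison = c("obs_vs_obs", "est_vs_obs", "obs_vs_est", "est_vs_est"),
    coef = c(0.1729, 0.3879, 0.1473, 0.3301),
    exp = c(0.2853, 0.1414, 0.2837, 0.1402),
    se_coef = c(0.0151, 0.0380, 0.0129, 0.0326),
    se_exp = c(0.0250, 0.0310, 0.0250, 0.0312),
    residual_se = c(0.2692, 0.4621, 0.2290, 0.3954),
    dof = 562L
  )
}
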