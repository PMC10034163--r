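#' Analytic power for a two-sample MR analysis
#'
#' Power of the two-sided level-`alpha` Wald test of the causal effect,
#' using the standard approximation that the causal estimate has
#' standard error `1 / sqrt(n * r2)` where `n` is the outcome sample
#' size and `r2` the fraction of exposure variance explained by the
#' instruments:
#' `power = Phi(sqrt(n * r2) * |beta| - z_{1 - alpha/2})`.
#'
#' @param n Outcome sample size (> 0).
#' @param r2 Variance in the exposure explained by the instruments, in
#'   (0, 1).
#' @param beta Hypothesized causal effect (per SD of exposure).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @examples
#' # a 3,301-person outcome GWAS with instruments explaining 2% of the
#' # exposure gives 80% power at a causal effect of 0.345
#' mr_power(n = 3301, r2 = 0.02, beta = 0.345)
#' @export
mr_power <- function(n, r2, beta, alpha = 0.05) {
  check_number(n, "n", lower = 1e-9)
  if (!is.numeric(r2) || length(r2) != 1 || is.na(r2) || r2 <= 0 || r2 >= 1) {
    abort("`r2` must lie strictly within (0, 1)")
  }
  check_number(beta, "beta")
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  pnorm(sqrt(n * r2) * abs(beta) - qnorm(1 - alpha / 2))
}

#' Minimum detectable causal effect at a target power
#'
#' Inverts [mr_power()]:
#' `beta = (z_power + z_{1 - alpha/2}) / sqrt(n * r2)`.
#'
#' @inheritParams mr_power
#' @param target_power Desired power, in (`alpha`, 1).
#' @return The smallest |beta| detectable at `target_power`.
#' @examples
#' minimum_detectable_effect(n = 3301, r2 = 0.02)  # ~0.345
#' @export
minimum_detectable_effect <- function(n, r2, target_power = 0.8,
                                      alpha = 0.05) {
  check_number(n, "n", lower = 1e-9)
  if (!is.numeric(r2) || length(r2) != 1 || is.na(r2) || r2 <= 0 || r2 >= 1) {
    abort("`r2` must lie strictly within (0, 1)")
  }
  if (target_power <= alpha || target_power >= 1) {
    abort("`target_power` must lie in (alpha, 1)")
  }
  (qnorm(target_power) + qnorm(1 - alpha / 2)) / sqrt(n * r2)
}
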