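# Causal-effect estimators on a harmonized set. All work from the
# per-variant Wald ratios b_j = beta_outcome/beta_exposure with
# first-order weights w_j = beta_exposure^2 / se_outcome^2 (the
# exposure-side sampling error is ignored in the weights; this is the
# convention of standard two-sample MR software and is documented so
# second-order weights can be added later).

new_mr_result <- function(method, beta, se, pval, n_snp, extra = list(),
                          exposure_id = NA_character_,
                          outcome_id = NA_character_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - qnorm(0.975) * se,
                 ci_high = beta + qnorm(0.975) * se,
                 pval = pval, n_snp = n_snp, extra = extra,
                 exposure_id = exposure_id, outcome_id = outcome_id),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("<mr_result> %s: beta = %.*f (95%% CI %.*f to %.*f), p = %.3g, nSNP = %d\n",
              x$method, digits, x$beta, digits, x$ci_low, digits, x$ci_high,
              x$pval, x$n_snp))
  if (x$method == "egger") {
    cat(sprintf("  intercept = %.*f (p = %.3g)\n", digits,
                x$extra$intercept, x$extra$intercept_pval))
  }
  invisible(x)
}

#' Tidy an MR estimate
#'
#' `tidy()` returns the estimate as a one-row tibble (method, beta, se,
#' 95% CI bounds, p-value, number of instruments); `glance()` adds the
#' method-specific diagnostics (Egger intercept and its p-value,
#' heterogeneity scale) where present.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(method = x$method, beta = x$beta, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high,
         pval = x$pval, n_snp = x$n_snp)
}

#' @rdname tidy.mr_result
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  out <- tidy(x)
  out$egger_intercept <- x$extra$intercept %||% NA_real_
  out$egger_intercept_pval <- x$extra$intercept_pval %||% NA_real_
  out$heterogeneity_phi <- x$extra$phi %||% NA_real_
  out
}

# Ratio estimates and first-order weights from a harmonized set.
ratio_table <- function(dat, require_n = 2) {
  dat <- retained_pairs(dat)
  if (any(dat$beta_exposure == 0)) {
    dat <- dat[dat$beta_exposure != 0, ]
  }
  if (nrow(dat) < require_n) {
    abort(sprintf("need at least %d estimable instrument pairs, have %d",
                  require_n, nrow(dat)))
  }
  tibble(variant_id = dat$variant_id,
         b = dat$beta_outcome / dat$beta_exposure,
         se_b = dat$se_outcome / abs(dat$beta_exposure),
         w = dat$beta_exposure^2 / dat$se_outcome^2,
         beta_exposure = dat$beta_exposure,
         se_exposure = dat$se_exposure,
         beta_outcome = dat$beta_outcome,
         se_outcome = dat$se_outcome)
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, with the first-order (delta-method) standard error
#' `se_outcome / |beta_exposure|`. Invariant to flipping the effect
#' allele (both effects change sign).
#'
#' @param beta_exposure,se_exposure Instrument-exposure effect and SE.
#' @param beta_outcome,se_outcome Instrument-outcome effect and SE
#'   (harmonized orientation).
#' @return An `mr_result` with method `"wald"`.
#' @examples
#' wald_ratio(0.1, 0.02, 0.2, 0.05)
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (beta_exposure == 0) abort("Wald ratio undefined for a zero exposure effect")
  beta <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  new_mr_result("wald", beta, se, normal_pval(beta, se), 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Combines the per-variant Wald ratios with first-order inverse-
#' variance weights. The fixed-effects standard error is
#' `1/sqrt(sum w)`. The multiplicative random-effects model scales it
#' by `sqrt(max(1, Q/(J-1)))`, with Q the Cochran heterogeneity
#' statistic, so the random-effects SE is never smaller than the
#' fixed-effects one. `mode = "auto"` applies the study's switching
#' rule: random effects when more than 4 instruments are available or
#' when there is no significant heterogeneity (Q p-value >= 0.10),
#' fixed effects otherwise. P-values are two-sided normal.
#'
#' @param dat An `mr_harmonized` tibble with >= 2 retained pairs.
#' @param mode `"auto"`, `"fixed"`, or `"random"`.
#' @return An `mr_result` (method `"ivw_fe"` or `"ivw_re"`); `extra`
#'   carries `Q`, `Q_df`, `Q_pval` and the scale `phi`.
#' @export
mr_ivw <- function(dat, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  rt <- ratio_table(dat, require_n = 2)
  J <- nrow(rt)
  beta <- sum(rt$w * rt$b) / sum(rt$w)
  se_fe <- 1 / sqrt(sum(rt$w))
  Q <- sum(rt$w * (rt$b - beta)^2)
  Q_df <- J - 1
  Q_pval <- pchisq(Q, Q_df, lower.tail = FALSE)
  phi <- max(1, Q / Q_df)
  if (mode == "auto") {
    mode <- if (J > 4 || Q_pval >= 0.10) "random" else "fixed"
  }
  se <- if (mode == "random") se_fe * sqrt(phi) else se_fe
  new_mr_result(if (mode == "random") "ivw_re" else "ivw_fe",
                beta, se, normal_pval(beta, se), J,
                extra = list(Q = Q, Q_df = Q_df, Q_pval = Q_pval, phi = phi),
                exposure_id = attr(dat, "exposure_id"),
                outcome_id = attr(dat, "outcome_id"))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept, weights `1/se_outcome^2`, after
#' orienting every pair so the exposure effect is positive. The slope
#' estimates the causal effect; a nonzero intercept indicates
#' directional horizontal pleiotropy (under the InSIDE assumption).
#' Slope and intercept are tested on t with J - 2 degrees of freedom.
#'
#' @param dat An `mr_harmonized` tibble with >= 3 retained pairs.
#' @return An `mr_result` (method `"egger"`); `extra` carries
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(dat) {
  rt <- ratio_table(dat, require_n = 3)
  J <- nrow(rt)
  s <- sign(rt$beta_exposure)
  x <- s * rt$beta_exposure
  y <- s * rt$beta_outcome
  if (sd(x) == 0) {
    abort("MR-Egger needs variation in instrument strength; all oriented exposure effects are identical")
  }
  fit <- lm(y ~ x, weights = 1 / rt$se_outcome^2)
  cf <- summary(fit)$coefficients
  slope <- cf["x", "Estimate"]
  slope_se <- cf["x", "Std. Error"]
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"]
  slope_p <- 2 * pt(-abs(slope / slope_se), df = J - 2)
  int_p <- 2 * pt(-abs(int / int_se), df = J - 2)
  new_mr_result("egger", slope, slope_se, slope_p, J,
                extra = list(intercept = int, intercept_se = int_se,
                             intercept_pval = int_p),
                exposure_id = attr(dat, "exposure_id"),
                outcome_id = attr(dat, "outcome_id"))
}

# Weighted median of values `b` with weights `w`: sort, form cumulative
# midpoint positions s_j = cumsum(w')_j - w'_j/2 on normalized weights,
# and linearly interpolate b over s at 0.5.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(b, se_b, point_fun, n_boot, seed) {
  with_seed_if(seed, {
    draws <- matrix(rnorm(n_boot * length(b), mean = b, sd = se_b),
                    nrow = n_boot, byrow = TRUE)
    sd(apply(draws, 1, point_fun))
  })
}

#' Weighted-median estimator
#'
#' The median of the inverse-variance-weighted empirical distribution
#' of the per-variant Wald ratios; consistent when instruments carrying
#' at least half the weight are valid, so it tolerates up to 50% of
#' information from invalid instruments. The standard error comes from
#' a parametric bootstrap: each ratio is redrawn from
#' Normal(b_j, se_bj), the weighted median recomputed, and the SD over
#' `n_boot` draws taken.
#'
#' @param dat An `mr_harmonized` tibble with >= 3 retained pairs.
#' @param n_boot Bootstrap draws for the standard error.
#' @param seed Optional seed for the bootstrap.
#' @return An `mr_result` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = NULL) {
  rt <- ratio_table(dat, require_n = 3)
  beta <- weighted_median_point(rt$b, rt$w)
  se <- boot_se(rt$b, rt$se_b,
                function(bb) weighted_median_point(bb, rt$w),
                n_boot, seed)
  new_mr_result("weighted_median", beta, se, normal_pval(beta, se),
                nrow(rt),
                exposure_id = attr(dat, "exposure_id"),
                outcome_id = attr(dat, "outcome_id"))
}

# Mode of the weighted kernel density over ratio estimates: Gaussian
# kernel, Silverman-style bandwidth on the ratios, argmax on a grid.
weighted_mode_point <- function(b, w, bandwidth_factor = 1, grid_n = 512) {
  spread <- min(sd(b), IQR(b) / 1.34)
  h <- bandwidth_factor * 0.9 * spread * length(b)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(b[1])   # all ratios identical
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  w <- w / sum(w)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - b) / h)) / h,
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' Clusters the Wald ratios by smoothing them with a weighted Gaussian
#' kernel density and takes the density's mode — the estimate supported
#' by the largest cluster of instruments, which is consistent when the
#' plurality of weight sits on valid instruments. Bandwidth is
#' `bandwidth_factor * 0.9 * min(sd, IQR/1.34) * J^(-1/5)`; the mode is
#' located on a 512-point grid spanning the ratios plus three
#' bandwidths. Standard error by the same parametric bootstrap as the
#' weighted median. If all ratios coincide their common value is
#' returned directly.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the default bandwidth.
#' @param grid_n Grid resolution for locating the mode.
#' @return An `mr_result` (method `"weighted_mode"`).
#' @export
mr_weighted_mode <- function(dat, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL, grid_n = 512) {
  rt <- ratio_table(dat, require_n = 3)
  beta <- weighted_mode_point(rt$b, rt$w, bandwidth_factor, grid_n)
  se <- boot_se(rt$b, rt$se_b,
                function(bb) weighted_mode_point(bb, rt$w, bandwidth_factor,
                                                 grid_n),
                n_boot, seed)
  new_mr_result("weighted_mode", beta, se, normal_pval(beta, se),
                nrow(rt),
                exposure_id = attr(dat, "exposure_id"),
                outcome_id = attr(dat, "outcome_id"))
}

#' Run all estimators on one harmonized set
#'
#' Computes the five reported methods — fixed- and random-effects IVW,
#' MR-Egger, weighted median and weighted mode — and marks the primary
#' estimate: the IVW variant chosen by the switching rule (random
#' effects when J > 4 or there is no significant heterogeneity at
#' Q p >= 0.10, fixed effects otherwise), unless `ivw_mode` forces one.
#'
#' @param dat An `mr_harmonized` tibble with >= 3 retained pairs.
#' @param ivw_mode `"auto"`, `"fixed"` or `"random"` — which IVW row is
#'   primary.
#' @param n_boot,seed Bootstrap controls for median/mode.
#' @return A tibble with one row per method (columns of
#'   [glance.mr_result()] plus a logical `primary`).
#' @export
mr_estimate_all <- function(dat, ivw_mode = "auto", n_boot = 1000,
                            seed = NULL) {
  primary_ivw <- mr_ivw(dat, mode = ivw_mode)
  res <- list(mr_ivw(dat, mode = "fixed"),
              mr_ivw(dat, mode = "random"),
              mr_egger(dat),
              mr_weighted_median(dat, n_boot = n_boot, seed = seed),
              mr_weighted_mode(dat, n_boot = n_boot,
                               seed = if (is.null(seed)) NULL else seed + 1L))
  out <- purrr::map_dfr(res, glance)
  out$primary <- out$method == primary_ivw$method
  out
}
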