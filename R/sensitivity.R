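# Heterogeneity, outlier and robustness diagnostics. All use the same
# first-order ratio estimates and weights as the estimators, so the
# per-variant Q contributions sum exactly to Cochran's Q and the radial
# slope coincides with the fixed-effects IVW estimate.

#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of `w_j (b_j - beta_ivw_fe)^2` with the
#' first-order IVW weights, referred to chi-square with J - 1 degrees
#' of freedom. A p-value below 0.10 is conventionally read as
#' significant heterogeneity among the per-variant causal estimates.
#'
#' @param dat An `mr_harmonized` tibble with >= 2 retained pairs.
#' @return A list of class `mr_q`: `Q`, `df`, `pval`, and
#'   `per_variant_q` (named, summing exactly to `Q`).
#' @export
cochran_q <- function(dat) {
  rt <- ratio_table(dat, require_n = 2)
  beta <- sum(rt$w * rt$b) / sum(rt$w)
  qj <- rt$w * (rt$b - beta)^2
  names(qj) <- rt$variant_id
  Q <- sum(qj)
  df <- nrow(rt) - 1
  structure(list(Q = Q, df = df,
                 pval = pchisq(Q, df, lower.tail = FALSE),
                 per_variant_q = qj),
            class = "mr_q")
}

#' @export
print.mr_q <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n", x$Q, x$df, x$pval))
  invisible(x)
}

#' Radial heterogeneity scan for outlying instruments
#'
#' The radial reformulation regresses `b_j * sqrt(w_j)` on `sqrt(w_j)`
#' through the origin; with first-order weights the fitted slope equals
#' the fixed-effects IVW estimate exactly, and each instrument's
#' squared residual is its Q contribution
#' `Q_j = w_j (b_j - beta)^2`. An instrument is flagged as an outlier
#' when the upper chi-square(1) tail of `Q_j` falls below the per-SNP
#' level — Bonferroni `0.05/J` by default, or a fixed level.
#'
#' @param dat An `mr_harmonized` tibble with >= 3 retained pairs.
#' @param alpha Family-wise level before the per-SNP split (default
#'   0.05).
#' @param alpha_per_snp `"bonferroni"` (`alpha/J`) or `"fixed"`
#'   (`alpha` per instrument).
#' @return A list of class `mr_radial`: `beta` (radial slope), `Q`,
#'   `df`, `pval`, `per_variant_q`, `per_variant_pval`, `outlier_ids`,
#'   `alpha_used`.
#' @export
radial_scan <- function(dat, alpha = 0.05,
                        alpha_per_snp = c("bonferroni", "fixed")) {
  alpha_per_snp <- match.arg(alpha_per_snp)
  rt <- ratio_table(dat, require_n = 3)
  J <- nrow(rt)
  # zero-intercept WLS of b*sqrt(w) on sqrt(w) collapses to the IVW mean
  beta <- sum(rt$w * rt$b) / sum(rt$w)
  qj <- rt$w * (rt$b - beta)^2
  names(qj) <- rt$variant_id
  pj <- pchisq(qj, 1, lower.tail = FALSE)
  cut <- if (alpha_per_snp == "bonferroni") alpha / J else alpha
  structure(list(beta = beta, Q = sum(qj), df = J - 1,
                 pval = pchisq(sum(qj), J - 1, lower.tail = FALSE),
                 per_variant_q = qj, per_variant_pval = pj,
                 outlier_ids = rt$variant_id[pj < cut],
                 alpha_used = cut),
            class = "mr_radial")
}

#' @export
print.mr_radial <- function(x, ...) {
  cat(sprintf("Radial scan: slope %.4f, Q = %.3f (p = %.3g), %d outlier(s)\n",
              x$beta, x$Q, x$pval, length(x$outlier_ids)))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

# Leave-one-out fixed-effects IVW estimates from running sums; O(J).
loo_beta <- function(b, w) {
  (sum(w * b) - w * b) / (sum(w) - w)
}

#' Simulation-based pleiotropy residual test (MR-PRESSO style)
#'
#' Tests for horizontal pleiotropy via the residual sum of squares of
#' each instrument about the IVW estimate computed *without* it:
#' `RSS = sum_j w_j (b_j - beta_{-j})^2`. The null distribution comes
#' from parametric simulation: outcome effects are redrawn around the
#' leave-one-out causal prediction (`Normal(beta_exposure_j * beta_{-j},
#' se_outcome_j^2)`), exposure effects around their estimates, and the
#' RSS recomputed `n_sim` times. Three components are reported:
#'
#' * **global test** — continuity-corrected fraction of simulated RSS at
#'   or above the observed;
#' * **outlier test** — the same comparison per instrument on its own
#'   residual term, thresholded at `outlier_alpha` (default Bonferroni
#'   0.05/J);
#' * **distortion test** — when outliers are found, the shift between
#'   the IVW estimate on all instruments and on non-outliers, compared
#'   with the shifts produced by removing random subsets of the same
#'   size.
#'
#' @param dat An `mr_harmonized` tibble with >= 4 retained pairs.
#' @param n_sim Simulated datasets for the null distribution.
#' @param seed Optional seed; identical seed and input give identical
#'   results.
#' @param outlier_alpha Per-instrument significance level; default
#'   `0.05 / J`.
#' @return A list of class `mr_presso`: `global_rss_obs`,
#'   `global_pval`, `per_variant_pvals`, `outlier_ids`, `beta_raw`,
#'   `beta_corrected`, `distortion_pval`, `n_sim`, `seed`.
#' @export
mr_presso <- function(dat, n_sim = 1000, seed = NULL, outlier_alpha = NULL) {
  rt <- tryCatch(ratio_table(dat, require_n = 4),
                 error = function(e) abort(
                   "mr_presso needs at least 4 estimable instrument pairs"))
  J <- nrow(rt)
  outlier_alpha <- outlier_alpha %||% (0.05 / J)
  beta_minus <- loo_beta(rt$b, rt$w)
  obs_terms <- rt$w * (rt$b - beta_minus)^2
  rss_obs <- sum(obs_terms)

  sims <- with_seed_if(seed, {
    # J x n_sim matrices; one column per simulated dataset
    g_star <- matrix(rnorm(J * n_sim, rt$beta_exposure, rt$se_exposure),
                     nrow = J)
    G_star <- matrix(rnorm(J * n_sim, rt$beta_exposure * beta_minus,
                           rt$se_outcome),
                     nrow = J)
    list(g = g_star, G = G_star)
  })
  b_star <- sims$G / sims$g
  w_star <- sims$g^2 / rt$se_outcome^2
  sw <- colSums(w_star)
  swb <- colSums(w_star * b_star)
  beta_minus_star <- sweep(-w_star * b_star, 2, swb, "+") /
    sweep(-w_star, 2, sw, "+")
  sim_terms <- w_star * (b_star - beta_minus_star)^2
  rss_star <- colSums(sim_terms)

  global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  per_pval <- (1 + rowSums(sim_terms >= obs_terms)) / (n_sim + 1)
  names(per_pval) <- rt$variant_id
  outlier_ids <- rt$variant_id[per_pval < outlier_alpha]

  beta_raw <- sum(rt$w * rt$b) / sum(rt$w)
  beta_corrected <- beta_raw
  distortion_pval <- NA_real_
  n_out <- length(outlier_ids)
  if (n_out > 0 && n_out < J) {
    keep <- !(rt$variant_id %in% outlier_ids)
    beta_corrected <- sum(rt$w[keep] * rt$b[keep]) / sum(rt$w[keep])
    obs_shift <- abs(beta_raw - beta_corrected)
    shifts <- with_seed_if(if (is.null(seed)) NULL else seed + 1L,
      vapply(seq_len(n_sim), function(i) {
        drop <- sample(which(keep), n_out)
        bk <- rt$b[-drop]; wk <- rt$w[-drop]
        abs(beta_raw - sum(wk * bk) / sum(wk))
      }, numeric(1)))
    distortion_pval <- (1 + sum(shifts >= obs_shift)) / (n_sim + 1)
  }
  structure(list(global_rss_obs = rss_obs, global_pval = global_pval,
                 per_variant_pvals = per_pval, outlier_ids = outlier_ids,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("Pleiotropy residual test: RSS = %.3f, global p = %.3g, %d outlier(s)\n",
              x$global_rss_obs, x$global_pval, length(x$outlier_ids)))
  if (length(x$outlier_ids) > 0) {
    cat(sprintf("  corrected beta %.4f (raw %.4f), distortion p = %.3g\n",
                x$beta_corrected, x$beta_raw, x$distortion_pval))
  }
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect (IVW, auto mode) J times, each time
#' omitting one instrument. The result is flagged robust when every
#' leave-one-out estimate keeps the sign of the full-set estimate and
#' every leave-one-out 95% CI overlaps the full-set CI.
#'
#' @param dat An `mr_harmonized` tibble with >= 3 retained pairs.
#' @param ivw_mode Passed to [mr_ivw()] for each reduced set.
#' @return A tibble of class `mr_loo` with one row per omitted variant
#'   (`omitted`, `beta`, `se`, `ci_low`, `ci_high`, `pval`) plus
#'   attributes `full` (the full-set `mr_result`) and `robust`.
#' @export
leave_one_out <- function(dat, ivw_mode = "auto") {
  rt <- ratio_table(dat, require_n = 3)
  live <- retained_pairs(dat)
  live <- live[live$beta_exposure != 0, ]
  full <- mr_ivw(live, mode = ivw_mode)
  rows <- purrr::map_dfr(seq_len(nrow(live)), function(j) {
    r <- mr_ivw(live[-j, ], mode = ivw_mode)
    tibble(omitted = live$variant_id[j], beta = r$beta, se = r$se,
           ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval)
  })
  robust <- all(sign(rows$beta) == sign(full$beta)) &&
    all(rows$ci_low <= full$ci_high & rows$ci_high >= full$ci_low)
  structure(rows, full = full, robust = robust,
            class = c("mr_loo", class(rows)))
}

#' Remove diagnosed outliers from a harmonized set
#'
#' Marks the union of radial-scan and residual-test outliers as
#' `dropped_outlier` so estimation proceeds on the cleaned set, and
#' logs the removed ids.
#'
#' @param dat An `mr_harmonized` tibble.
#' @param outlier_ids Character vector of variant ids to drop.
#' @return The `mr_harmonized` tibble with actions updated; attribute
#'   `"outliers_removed"` lists the ids.
#' @export
remove_outliers <- function(dat, outlier_ids) {
  live <- !startsWith(dat$action, "dropped")
  dat$action[live & dat$variant_id %in% outlier_ids] <- "dropped_outlier"
  out <- restore_harmonized(dat, dat)
  attr(out, "outliers_removed") <- outlier_ids
  out
}
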