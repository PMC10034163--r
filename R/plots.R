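# ggplot2 visualisations of a harmonized set and its diagnostics.

#' Scatter plot of instrument effects with fitted MR slopes
#'
#' Outcome effects against exposure effects (pairs oriented so the
#' exposure effect is positive), with error bars at +/- 1 SE and one
#' fitted line per method (through the origin for everything except
#' MR-Egger, which keeps its intercept).
#'
#' @param dat An `mr_harmonized` tibble.
#' @param results Optional tibble from [mr_estimate_all()]; computed
#'   (without bootstrap standard errors) when absent.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(dat, results = NULL) {
  live <- retained_pairs(dat)
  s <- sign(live$beta_exposure)
  df <- tibble(x = s * live$beta_exposure, y = s * live$beta_outcome,
               se_x = live$se_exposure, se_y = live$se_outcome)
  if (is.null(results)) results <- mr_estimate_all(dat, n_boot = 100)
  lines <- tibble(method = results$method, slope = results$beta,
                  intercept = ifelse(results$method == "egger",
                                     results$egger_intercept, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$se_y,
                                        ymax = .data$y + .data$se_y),
                           linewidth = 0.3, colour = "grey55") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x - .data$se_x,
                                         xmax = .data$x + .data$se_x),
                            linewidth = 0.3, colour = "grey55") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome", colour = "method") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-instrument Wald ratios and summary estimates
#'
#' @param dat An `mr_harmonized` tibble.
#' @param results Optional tibble from [mr_estimate_all()].
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(dat, results = NULL) {
  rt <- ratio_table(dat, require_n = 1)
  if (is.null(results)) results <- mr_estimate_all(dat, n_boot = 100)
  rows <- dplyr::bind_rows(
    tibble(label = rt$variant_id, beta = rt$b,
           lo = rt$b - qnorm(0.975) * rt$se_b,
           hi = rt$b + qnorm(0.975) * rt$se_b, kind = "SNP"),
    tibble(label = results$method, beta = results$beta,
           lo = results$ci_low, hi = results$ci_high, kind = "summary"))
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$label,
                                     colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::labs(x = "causal estimate (95% CI)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Funnel plot of instrument precision against Wald ratios
#'
#' Asymmetry about the summary estimate suggests directional
#' pleiotropy.
#'
#' @param dat An `mr_harmonized` tibble.
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(dat) {
  rt <- ratio_table(dat, require_n = 1)
  ivw <- sum(rt$w * rt$b) / sum(rt$w)
  df <- tibble(b = rt$b, precision = 1 / rt$se_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = ivw, linetype = 2) +
    ggplot2::labs(x = "Wald ratio", y = "precision (1/SE)") +
    ggplot2::theme_minimal()
}

#' Leave-one-out plot
#'
#' One row per omitted instrument with the re-estimated effect and its
#' 95% CI; the full-set estimate is the dashed line.
#'
#' @param loo An `mr_loo` result from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_mr_loo <- function(loo) {
  full <- attr(loo, "full")
  df <- as_tibble(loo)
  df$omitted <- factor(df$omitted, levels = rev(df$omitted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$omitted)) +
    ggplot2::geom_vline(xintercept = full$beta, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::labs(x = "IVW estimate omitting one SNP (95% CI)",
                  y = "omitted SNP") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a harmonized set draws the scatter plot; on a
#' leave-one-out result, the leave-one-out plot.
#'
#' @param object An `mr_harmonized` or `mr_loo` object.
#' @param ... Passed to the underlying `plot_mr_*` function.
#' @return A ggplot object.
#' @method autoplot mr_harmonized
#' @export
autoplot.mr_harmonized <- function(object, ...) plot_mr_scatter(object, ...)

#' @rdname autoplot.mr_harmonized
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) plot_mr_loo(object)
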