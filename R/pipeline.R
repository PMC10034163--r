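#' Configuration for a bidirectional MR analysis
#'
#' @param direction `"forward"`, `"reverse"`, or `"both"`.
#' @param profiles List of [threshold_profile()]s to run (default both
#'   the loose and the strict profile).
#' @param fdr_alpha Significance level on FDR-adjusted IVW p-values.
#' @param fdr_family `"per_pair_methods"` adjusts the five method
#'   p-values within each exposure-outcome pair (correction by the
#'   number of MR methods); `"per_outcome_exposures"` adjusts IVW
#'   p-values across exposures within each outcome and profile.
#' @param min_iv Minimum surviving instruments for a pair to be
#'   analysed (>= 3); pairs below it are excluded with a logged reason.
#' @param min_f Weak-instrument F cutoff.
#' @param maf_limit Palindrome minor-allele-frequency cutoff.
#' @param n_boot Bootstrap draws for median/mode standard errors.
#' @param n_sim Simulations for the pleiotropy residual test.
#' @param seed Seed for all stochastic steps.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(direction = c("both", "forward", "reverse"),
                      profiles = list(threshold_profile("loose"),
                                      threshold_profile("strict")),
                      fdr_alpha = 0.05,
                      fdr_family = c("per_pair_methods",
                                     "per_outcome_exposures"),
                      min_iv = 3, min_f = 10, maf_limit = 0.42,
                      n_boot = 1000, n_sim = 1000, seed = NULL) {
  direction <- match.arg(direction)
  fdr_family <- match.arg(fdr_family)
  check_number(fdr_alpha, "fdr_alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(min_iv, "min_iv", lower = 3)
  check_number(min_f, "min_f", lower = 0)
  check_number(maf_limit, "maf_limit", lower = 0, upper = 0.5)
  structure(list(direction = direction, profiles = profiles,
                 fdr_alpha = fdr_alpha, fdr_family = fdr_family,
                 min_iv = as.integer(min_iv), min_f = min_f,
                 maf_limit = maf_limit, n_boot = n_boot, n_sim = n_sim,
                 seed = seed),
            class = "mr_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] so the family policy lives in one place).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  p.adjust(pvals, method = "BH")
}

provenance_row <- function(step, n_before, n_after, detail = "") {
  tibble(step = step, n_before = as.integer(n_before),
         n_after = as.integer(n_after), detail = detail)
}

#' Run one exposure-outcome MR analysis end to end
#'
#' Executes the full per-pair workflow: p-value filtering under the
#' profile, optional frequency supplementation, optional confounder
#' screening and (for protein exposures) pQTL annotation filtering,
#' weak-instrument filtering, LD clumping, harmonization, the
#' intermediate-frequency palindrome rule, radial + residual-test
#' outlier removal, all five estimators, and heterogeneity /
#' pleiotropy / leave-one-out diagnostics. If fewer than
#' `config$min_iv` instruments survive at any point the pair is
#' excluded with the reason recorded; every filter appends a row to the
#' provenance log.
#'
#' @param exposure,outcome `mr_sumstats` tibbles.
#' @param profile A [threshold_profile()].
#' @param config An [mr_config()].
#' @param panel Optional `mr_panel` for clumping (skipped when `NULL`).
#' @param catalog Optional `mr_catalog` for frequency supplementation,
#'   confounder screening and pQTL filtering (skipped when `NULL`).
#' @param direction Label carried into results.
#' @return A list of class `mr_analysis`: `results` (tibble, one row
#'   per method, or `NULL` when excluded), `excluded` (reason string or
#'   `NA`), `diagnostics` (one-row tibble), `provenance` (filter log),
#'   `harmonized` (the final harmonized set), ids and labels.
#' @export
run_pair <- function(exposure, outcome, profile = threshold_profile("loose"),
                     config = mr_config(), panel = NULL, catalog = NULL,
                     direction = "forward") {
  prov <- list()
  log_step <- function(step, before, after, detail = "") {
    prov[[length(prov) + 1]] <<- provenance_row(step, before, after, detail)
  }
  exclude <- function(reason) {
    structure(list(results = NULL, excluded = reason,
                   diagnostics = NULL, provenance = dplyr::bind_rows(prov),
                   harmonized = NULL,
                   exposure_id = trait_id(exposure),
                   outcome_id = trait_id(outcome),
                   profile = profile$name, direction = direction),
              class = "mr_analysis")
  }

  x <- exposure
  n0 <- nrow(x)
  x <- filter_by_pvalue(x, profile)
  log_step("p_value_filter", n0, nrow(x),
           sprintf("p < %g", profile$p_threshold))
  if (nrow(x) < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))

  if (!is.null(catalog)) {
    n0 <- nrow(x)
    x <- supplement_eaf(x, catalog)
    log_step("supplement_eaf", n0, nrow(x),
             sprintf("%d frequencies filled",
                     sum(x$eaf_supplemented %in% TRUE)))
    n0 <- nrow(x)
    x <- screen_confounders(x, catalog)
    log_step("confounder_screen", n0, nrow(x))
    if (nrow(x) < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))
    if (trait_type(exposure) == "protein") {
      n0 <- nrow(x)
      x <- filter_pqtl_instruments(x, catalog)
      log_step("pqtl_filter", n0, nrow(x))
      if (nrow(x) < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))
    }
  }

  n0 <- nrow(x)
  x <- filter_weak_instruments(x, min_f = config$min_f)
  log_step("weak_instrument_filter", n0, nrow(x),
           sprintf("F >= %g", config$min_f))
  if (nrow(x) < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))

  if (!is.null(panel)) {
    n0 <- nrow(x)
    x <- ld_clump(x, panel, profile)
    log_step("ld_clump", n0, nrow(x),
             sprintf("r2 < %g, %d kb", profile$clump_r2,
                     profile$clump_window_kb))
    if (nrow(x) < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))
  }

  h <- harmonize(x, outcome, direction = direction)
  h <- drop_intermediate_palindromes(h, maf_limit = config$maf_limit)
  n_retained <- sum(!startsWith(h$action, "dropped"))
  log_step("harmonize", nrow(x), n_retained,
           sprintf("palindrome MAF > %g dropped", config$maf_limit))
  if (n_retained < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))

  # outlier pass: union of radial and residual-test flags
  seed <- config$seed
  rad <- radial_scan(h)
  pres <- if (n_retained >= 4)
    mr_presso(h, n_sim = config$n_sim, seed = seed) else NULL
  outliers <- union(rad$outlier_ids,
                    if (is.null(pres)) character(0) else pres$outlier_ids)
  if (length(outliers) > 0) {
    h <- remove_outliers(h, outliers)
    n_retained <- sum(!startsWith(h$action, "dropped"))
    log_step("outlier_removal", n_retained + length(outliers), n_retained,
             paste(outliers, collapse = ","))
    if (n_retained < config$min_iv) return(exclude(sprintf("IVs < %d", config$min_iv)))
  }

  est <- mr_estimate_all(h, ivw_mode = "auto", n_boot = config$n_boot,
                         seed = seed)
  est$exposure_id <- trait_id(exposure)
  est$outcome_id <- trait_id(outcome)
  est$direction <- direction
  est$profile <- profile$name
  est$n_outliers_removed <- length(outliers)

  q <- cochran_q(h)
  loo <- leave_one_out(h)
  ivw_row <- est[est$primary, ][1, ]
  diagnostics <- tibble(
    exposure_id = trait_id(exposure), outcome_id = trait_id(outcome),
    direction = direction, profile = profile$name,
    n_snp = ivw_row$n_snp,
    Q = q$Q, Q_pval = q$pval,
    egger_intercept = est$egger_intercept[est$method == "egger"],
    egger_intercept_pval = est$egger_intercept_pval[est$method == "egger"],
    presso_global_pval = if (is.null(pres)) NA_real_ else pres$global_pval,
    n_outliers_removed = length(outliers),
    loo_robust = attr(loo, "robust"))

  structure(list(results = est, excluded = NA_character_,
                 diagnostics = diagnostics,
                 provenance = dplyr::bind_rows(prov),
                 harmonized = h, loo = loo,
                 exposure_id = trait_id(exposure),
                 outcome_id = trait_id(outcome),
                 profile = profile$name, direction = direction),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("<mr_analysis> %s -> %s [%s, %s]\n", x$exposure_id,
              x$outcome_id, x$direction, x$profile))
  if (!is.na(x$excluded)) {
    cat("  excluded:", x$excluded, "\n")
  } else {
    print(x$results[c("method", "beta", "se", "pval", "n_snp")])
  }
  invisible(x)
}

#' Run the full bidirectional analysis over trait combinations
#'
#' Runs [run_pair()] for every exposure-outcome combination under every
#' configured threshold profile, and — when `config$direction` is
#' `"both"` — again with the roles swapped. IVW p-values are then
#' FDR-adjusted within the configured family and results flagged
#' significant when the adjusted IVW p-value falls below
#' `config$fdr_alpha`. A pair excluded in one direction can still
#' appear in the other.
#'
#' @param exposures,outcomes Lists of `mr_sumstats` (a bare
#'   `mr_sumstats` is accepted).
#' @param config An [mr_config()].
#' @param panel,catalog Optional, as in [run_pair()]; used for both
#'   directions.
#' @return A list of class `mr_scan`: `results` (tibble over all
#'   analysed combinations, with `pval_fdr` and `significant` on the
#'   IVW rows), `exclusions` (tibble of excluded combinations with
#'   reasons), `diagnostics`, and `analyses` (the raw `mr_analysis`
#'   objects).
#' @export
run_bidirectional <- function(exposures, outcomes, config = mr_config(),
                              panel = NULL, catalog = NULL) {
  as_list <- function(x) if (inherits(x, "mr_sumstats")) list(x) else x
  exposures <- as_list(exposures)
  outcomes <- as_list(outcomes)
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1)

  combos <- list()
  add_combos <- function(exps, outs, direction) {
    for (e in exps) for (o in outs) for (p in config$profiles) {
      combos[[length(combos) + 1]] <<- list(e = e, o = o, p = p,
                                            d = direction)
    }
  }
  if (config$direction %in% c("forward", "both")) {
    add_combos(exposures, outcomes, "forward")
  }
  if (config$direction %in% c("reverse", "both")) {
    add_combos(outcomes, exposures, "reverse")
  }

  analyses <- purrr::map(combos, function(cc) {
    tryCatch(run_pair(cc$e, cc$o, profile = cc$p, config = config,
                      panel = panel, catalog = catalog, direction = cc$d),
             error = function(err) {
               structure(list(results = NULL,
                              excluded = conditionMessage(err),
                              diagnostics = NULL, provenance = NULL,
                              harmonized = NULL,
                              exposure_id = trait_id(cc$e),
                              outcome_id = trait_id(cc$o),
                              profile = cc$p$name, direction = cc$d),
                         class = "mr_analysis")
             })
  })

  ok <- purrr::map_lgl(analyses, ~ is.na(.x$excluded))
  results <- purrr::map_dfr(analyses[ok], "results")
  exclusions <- purrr::map_dfr(analyses[!ok], function(a) {
    tibble(exposure_id = a$exposure_id, outcome_id = a$outcome_id,
           direction = a$direction, profile = a$profile,
           reason = a$excluded)
  })
  diagnostics <- purrr::map_dfr(analyses[ok], "diagnostics")

  if (nrow(results) > 0) {
    results$pval_fdr <- NA_real_
    if (config$fdr_family == "per_pair_methods") {
      # correct by the number of MR methods within each trait pair;
      # both IVW variants count as one method (the primary one enters)
      fam <- results$primary | !grepl("^ivw", results$method)
      results$pval_fdr[fam] <- stats::ave(
        results$pval[fam],
        paste(results$exposure_id[fam], results$outcome_id[fam],
              results$direction[fam], results$profile[fam]),
        FUN = fdr_adjust)
    } else {
      results$pval_fdr[results$primary] <- stats::ave(
        results$pval[results$primary],
        paste(results$outcome_id[results$primary],
              results$direction[results$primary],
              results$profile[results$primary]),
        FUN = fdr_adjust)
    }
    results$significant <- results$primary &
      !is.na(results$pval_fdr) & results$pval_fdr < config$fdr_alpha
  }
  structure(list(results = results, exclusions = exclusions,
                 diagnostics = diagnostics, analyses = analyses),
            class = "mr_scan")
}

#' @export
print.mr_scan <- function(x, ...) {
  cat(sprintf("<mr_scan> %d analysed combinations, %d excluded\n",
              length(x$analyses) - nrow(x$exclusions), nrow(x$exclusions)))
  if (nrow(x$results) > 0) {
    sig <- x$results[x$results$significant %in% TRUE, ]
    cat(sprintf("  %d significant IVW result(s) after FDR\n", nrow(sig)))
  }
  invisible(x)
}
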