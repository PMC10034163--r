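#' Named instrument-selection threshold profiles
#'
#' Two profiles govern instrument selection. The `loose` profile —
#' p < 1e-5 with clumping at r-squared < 0.01 in a 10,000-kb window —
#' is the locus-wide setting common in microbiome MR, where genome-wide
#' significant variants are too few to instrument most taxa. The
#' `strict` profile — p < 5e-6, r-squared < 0.001, same window —
#' approximates the traditional MR setting and serves as a validation
#' pass. Any field can be overridden.
#'
#' @param name `"loose"` or `"strict"`.
#' @param p_threshold,clump_r2,clump_window_kb Optional overrides.
#' @return A list of class `threshold_profile`.
#' @examples
#' threshold_profile("strict")
#' @export
threshold_profile <- function(name = c("loose", "strict"),
                              p_threshold = NULL, clump_r2 = NULL,
                              clump_window_kb = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    loose  = list(p_threshold = 1e-5, clump_r2 = 0.01,  clump_window_kb = 10000L),
    strict = list(p_threshold = 5e-6, clump_r2 = 0.001, clump_window_kb = 10000L))
  out <- list(name = name,
              p_threshold = p_threshold %||% defaults$p_threshold,
              clump_r2 = clump_r2 %||% defaults$clump_r2,
              clump_window_kb = as.integer(clump_window_kb %||%
                                             defaults$clump_window_kb))
  check_number(out$p_threshold, "p_threshold", lower = 0, upper = 1)
  check_number(out$clump_r2, "clump_r2", lower = 0, upper = 1)
  check_number(out$clump_window_kb, "clump_window_kb", lower = 1)
  structure(out, class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat(sprintf("<threshold_profile> %s: p < %g, clump r2 < %g, window %d kb\n",
              x$name, x$p_threshold, x$clump_r2, x$clump_window_kb))
  invisible(x)
}

# Re-attach sumstats metadata after a dplyr verb stripped it.
restore_sumstats <- function(x, template) {
  structure(as_tibble(x),
            trait_id = attr(template, "trait_id"),
            trait_type = attr(template, "trait_type"),
            class = c("mr_sumstats", class(as_tibble(x))))
}

#' Filter variants by association p-value
#'
#' Retains rows with `pval` strictly below the profile threshold (a
#' boundary p equal to the threshold is excluded); row order is
#' preserved. An empty result is allowed and flagged downstream by the
#' minimum-instrument rule.
#'
#' @param stats An `mr_sumstats` tibble.
#' @param profile A [threshold_profile()].
#' @return The filtered `mr_sumstats`.
#' @export
filter_by_pvalue <- function(stats, profile = threshold_profile("loose")) {
  restore_sumstats(stats[stats$pval < profile$p_threshold, ], stats)
}

#' Greedy LD clumping against a reference panel
#'
#' Repeatedly takes the remaining variant with the smallest p-value as
#' the index (ties broken by chromosome then position) and removes every
#' remaining variant on the same chromosome within the profile window
#' whose squared genotype correlation with the index, computed from the
#' panel, exceeds the profile r-squared. Variants absent from the panel
#' are dropped with a warning before clumping.
#'
#' @inheritParams filter_by_pvalue
#' @param panel An `mr_panel` covering the variants.
#' @return The clumped `mr_sumstats`; attribute `"clump_removed"` lists
#'   removed variant ids with the index that removed each.
#' @export
ld_clump <- function(stats, panel, profile = threshold_profile("loose")) {
  in_panel <- stats$variant_id %in% panel$variants$variant_id
  if (any(!in_panel)) {
    warn(sprintf("%d variants absent from the reference panel were dropped",
                 sum(!in_panel)))
  }
  x <- stats[in_panel, ]
  if (nrow(x) == 0) {
    out <- restore_sumstats(x, stats)
    attr(out, "clump_removed") <- tibble(variant_id = character(),
                                         index_id = character())
    return(out)
  }
  ord <- order(x$pval, suppressWarnings(as.numeric(x$chrom)), x$chrom, x$pos)
  remaining <- ord
  keep <- integer(0)
  removed <- list()
  window_bp <- profile$clump_window_kb * 1000
  while (length(remaining) > 0) {
    idx <- remaining[1]
    keep <- c(keep, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- x$chrom[remaining] == x$chrom[idx]
    in_window <- abs(x$pos[remaining] - x$pos[idx]) <= window_bp
    cand <- remaining[same_chr & in_window]
    if (length(cand) > 0) {
      r2 <- vapply(cand, function(j)
        panel_r2(panel, x$variant_id[idx], x$variant_id[j]), numeric(1))
      drop <- cand[r2 > profile$clump_r2]
      if (length(drop) > 0) {
        removed[[length(removed) + 1]] <-
          tibble(variant_id = x$variant_id[drop],
                 index_id = x$variant_id[idx])
        remaining <- setdiff(remaining, drop)
      }
    }
  }
  out <- restore_sumstats(x[sort(keep), ], stats)
  attr(out, "clump_removed") <- if (length(removed) > 0)
    dplyr::bind_rows(removed) else tibble(variant_id = character(),
                                          index_id = character())
  out
}

#' Per-variant instrument-strength F statistic
#'
#' The single-variant approximation `F = beta^2 / se^2`; sign-invariant,
#' zero when beta is zero. Vectorized.
#'
#' @param beta,se Effect estimate(s) and standard error(s); `se > 0`.
#' @return Numeric vector of F statistics.
#' @examples
#' f_statistic(0.1, 0.0316)
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) abort("`se` must be positive")
  beta^2 / se^2
}

#' Per-variant exposure variance explained
#'
#' `2 f (1 - f) beta^2`, the variance a biallelic variant with effect
#' `beta` and effect-allele frequency `f` explains in a variance-1
#' trait; maximal at f = 0.5 for fixed beta.
#'
#' @param beta Effect estimate(s).
#' @param eaf Effect-allele frequency in \[0, 1\]; missing values error —
#'   supplement frequencies first (see [supplement_eaf()]).
#' @return Numeric vector of variance fractions.
#' @examples
#' variance_explained(0.3, 0.2)
#' @export
variance_explained <- function(beta, eaf) {
  if (any(is.na(eaf))) {
    abort("`eaf` is missing for some variants; run supplement_eaf() first")
  }
  2 * eaf * (1 - eaf) * beta^2
}

#' Drop weak instruments
#'
#' Retains variants whose F statistic is at least `min_f` (the
#' conventional weak-instrument screen keeps F >= 10; the boundary is
#' inclusive).
#'
#' @param stats An `mr_sumstats` tibble.
#' @param min_f Minimum F; `0` keeps everything.
#' @return The filtered `mr_sumstats` with an `f_stat` column added.
#' @export
filter_weak_instruments <- function(stats, min_f = 10) {
  f <- f_statistic(stats$beta, stats$se)
  out <- stats
  out$f_stat <- f
  restore_sumstats(out[f >= min_f, ], stats)
}

#' Screen instruments for confounder associations
#'
#' Removes variants that the annotation catalog links to a probable
#' confounder at genome-wide significance: any trait association with
#' p below `p_assoc` whose trait name contains one of the confounder
#' terms (case-insensitive substring). Variants absent from the catalog
#' are retained. The defaults screen for cancer/tumor traits.
#'
#' @param stats An `mr_sumstats` tibble.
#' @param catalog An `mr_catalog`.
#' @param p_assoc Association p-value threshold (default 5e-8).
#' @param confounder_terms Character vector of terms to match.
#' @return The screened `mr_sumstats`; attribute `"confounder_removed"`
#'   names the removed variants and the matched trait.
#' @export
screen_confounders <- function(stats, catalog, p_assoc = 5e-8,
                               confounder_terms = c("cancer", "tumor",
                                                    "tumour")) {
  pattern <- paste(tolower(confounder_terms), collapse = "|")
  hits <- catalog[!is.na(catalog$pval) & catalog$pval < p_assoc &
                    grepl(pattern, tolower(catalog$trait)), ]
  bad <- stats$variant_id %in% hits$variant_id
  out <- restore_sumstats(stats[!bad, ], stats)
  attr(out, "confounder_removed") <-
    hits[hits$variant_id %in% stats$variant_id, c("variant_id", "trait", "pval")]
  out
}

#' Supplement missing effect-allele frequencies from a catalog
#'
#' Fills missing `eaf` from the catalog's reference frequency, matched
#' on variant id. When the catalog records which allele its frequency
#' refers to, a frequency stored for the other allele is complemented;
#' without an allele annotation the frequency is assumed to already be
#' on the effect allele. Variants still missing a frequency afterwards
#' are flagged in the `eaf_supplemented` column as `NA`.
#'
#' @param stats An `mr_sumstats` tibble.
#' @param catalog An `mr_catalog` with `eaf_ref` entries.
#' @return `stats` with `eaf` filled where possible and a logical
#'   `eaf_supplemented` column (`TRUE` filled, `FALSE` already present,
#'   `NA` still missing).
#' @export
supplement_eaf <- function(stats, catalog) {
  ref <- catalog[!is.na(catalog$eaf_ref),
                 c("variant_id", "eaf_ref", "eaf_allele")]
  ref <- ref[!duplicated(ref$variant_id), ]
  out <- as_tibble(stats)
  out$eaf_supplemented <- FALSE
  miss <- which(is.na(out$eaf))
  for (i in miss) {
    j <- match(out$variant_id[i], ref$variant_id)
    if (is.na(j)) {
      out$eaf_supplemented[i] <- NA
      next
    }
    allele <- ref$eaf_allele[j]
    if (is.na(allele) || allele == out$effect_allele[i]) {
      out$eaf[i] <- ref$eaf_ref[j]
    } else if (allele == out$other_allele[i]) {
      out$eaf[i] <- 1 - ref$eaf_ref[j]
    } else {
      out$eaf_supplemented[i] <- NA
      next
    }
    out$eaf_supplemented[i] <- TRUE
  }
  restore_sumstats(out, stats)
}

#' Retain annotated, non-eQTL instruments (cis-pQTL filter)
#'
#' For protein exposures, keeps only variants the catalog marks as
#' annotated in a regulatory database and not as expression QTLs —
#' the operational definition of a well-identified cis-pQTL instrument.
#' Unannotated variants and variants absent from the catalog are
#' removed.
#'
#' @param stats An `mr_sumstats` tibble.
#' @param catalog An `mr_catalog`.
#' @return The filtered `mr_sumstats`; attribute `"pqtl_removed"` gives
#'   each removed variant and the rule that removed it.
#' @export
filter_pqtl_instruments <- function(stats, catalog) {
  info <- catalog[!duplicated(catalog$variant_id),
                  c("variant_id", "is_eqtl", "regulome_annotated")]
  j <- match(stats$variant_id, info$variant_id)
  annotated <- !is.na(j) & info$regulome_annotated[j] %in% TRUE
  eqtl <- !is.na(j) & info$is_eqtl[j] %in% TRUE
  keep <- annotated & !eqtl
  reason <- dplyr::case_when(!annotated ~ "unannotated",
                             eqtl ~ "eqtl",
                             TRUE ~ NA_character_)
  out <- restore_sumstats(stats[keep, ], stats)
  attr(out, "pqtl_removed") <- tibble(variant_id = stats$variant_id[!keep],
                                      reason = reason[!keep])
  out
}
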