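#' Harmonize exposure instruments with outcome associations
#'
#' Aligns the outcome effect of every instrument to the exposure's
#' effect allele so the per-variant Wald ratio (outcome effect divided
#' by exposure effect) is well defined. For each instrument found in the
#' outcome statistics:
#'
#' * same allele pair, same orientation — kept as is (`aligned`);
#' * same pair with effect/other swapped — outcome beta negated and
#'   outcome frequency complemented (`flipped`);
#' * strand complement of either orientation (A<->T, C<->G applied to
#'   both alleles) — resolved the same way;
#' * palindromic pairs (A/T or C/G), where orientation and strand are
#'   confounded — oriented by allele frequency: exposure and outcome
#'   frequencies on the same side of 0.5 means aligned, opposite sides
#'   means flipped; a palindromic pair missing either frequency is kept
#'   but flagged for [drop_intermediate_palindromes()];
#' * any other allele pair — dropped (`dropped_incompatible`);
#' * instruments absent from the outcome — dropped (`dropped_missing`).
#'
#' @param instruments `mr_sumstats` of selected exposure instruments.
#' @param outcome `mr_sumstats` for the outcome trait.
#' @param direction `"forward"` or `"reverse"`, a label carried through
#'   to results.
#' @return A tibble of class `mr_harmonized` with one row per input
#'   instrument: `variant_id`, exposure effect `beta_exposure` /
#'   `se_exposure`, aligned outcome effect `beta_outcome` /
#'   `se_outcome`, `eaf` (exposure orientation), `eaf_outcome`,
#'   `palindromic`, and `action`. Rows whose action starts with
#'   `dropped` are excluded by every estimator. Attributes carry
#'   `exposure_id`, `outcome_id` and `direction`.
#' @examples
#' sim <- simulate_pair(sim_config(n_variants = 5, seed = 1))
#' harmonize(sim$exposure, sim$outcome)
#' @export
harmonize <- function(instruments, outcome, direction = "forward") {
  stopifnot(nrow(instruments) > 0)
  j <- match(instruments$variant_id, outcome$variant_id)

  n <- nrow(instruments)
  action <- rep(NA_character_, n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)
  palin <- is_palindromic(instruments$effect_allele,
                          instruments$other_allele)

  for (i in seq_len(n)) {
    if (is.na(j[i])) {
      action[i] <- "dropped_missing"
      next
    }
    o <- outcome[j[i], ]
    ea <- instruments$effect_allele[i]
    oa <- instruments$other_allele[i]
    if (palin[i]) {
      # strand is unresolvable from alleles; outcome pair must be the
      # same palindromic pair, orientation inferred from frequencies
      same_pair <- setequal(c(o$effect_allele, o$other_allele), c(ea, oa))
      if (!same_pair) {
        action[i] <- "dropped_incompatible"
        next
      }
      fe <- instruments$eaf[i]
      fo <- o$eaf
      if (is.na(fe) || is.na(fo)) {
        # orientation unknown; keep nominally aligned, flagged for the
        # palindrome filter to drop
        action[i] <- "aligned"
        beta_out[i] <- o$beta; se_out[i] <- o$se; eaf_out[i] <- fo
        next
      }
      flipped <- (fe < 0.5) != (fo < 0.5)
      action[i] <- if (flipped) "flipped" else "aligned"
      beta_out[i] <- if (flipped) -o$beta else o$beta
      se_out[i] <- o$se
      eaf_out[i] <- if (flipped) 1 - fo else fo
      next
    }
    o_ea <- o$effect_allele
    o_oa <- o$other_allele
    if (o_ea == ea && o_oa == oa) {
      action[i] <- "aligned"
    } else if (o_ea == oa && o_oa == ea) {
      action[i] <- "flipped"
    } else {
      c_ea <- complement_alleles(o_ea)
      c_oa <- complement_alleles(o_oa)
      if (c_ea == ea && c_oa == oa) {
        action[i] <- "aligned"
      } else if (c_ea == oa && c_oa == ea) {
        action[i] <- "flipped"
      } else {
        action[i] <- "dropped_incompatible"
        next
      }
    }
    flip <- action[i] == "flipped"
    beta_out[i] <- if (flip) -o$beta else o$beta
    se_out[i] <- o$se
    eaf_out[i] <- if (flip) 1 - o$eaf else o$eaf
  }

  out <- tibble(variant_id = instruments$variant_id,
                chrom = instruments$chrom,
                pos = instruments$pos,
                beta_exposure = instruments$beta,
                se_exposure = instruments$se,
                pval_exposure = instruments$pval,
                beta_outcome = beta_out,
                se_outcome = se_out,
                eaf = instruments$eaf,
                eaf_outcome = eaf_out,
                palindromic = palin,
                action = action)
  structure(out,
            exposure_id = trait_id(instruments),
            outcome_id = trait_id(outcome),
            direction = direction,
            class = c("mr_harmonized", class(out)))
}

restore_harmonized <- function(x, template) {
  structure(as_tibble(x),
            exposure_id = attr(template, "exposure_id"),
            outcome_id = attr(template, "outcome_id"),
            direction = attr(template, "direction"),
            class = c("mr_harmonized", class(as_tibble(x))))
}

#' Retained (non-dropped) pairs of a harmonized set
#' @param dat An `mr_harmonized` tibble.
#' @return The subset with estimable pairs, same class.
#' @export
retained_pairs <- function(dat) {
  restore_harmonized(dat[!startsWith(dat$action, "dropped"), ], dat)
}

#' Drop palindromic pairs with intermediate allele frequency
#'
#' After harmonization, palindromic pairs whose minor-allele frequency
#' (`min(eaf, 1 - eaf)` in the exposure orientation) exceeds `maf_limit`
#' cannot be reliably oriented and are dropped
#' (`dropped_palindromic`). A palindromic pair with a missing frequency
#' is likewise dropped (`dropped_palindromic_na`) since the rule cannot
#' be checked. Non-palindromic pairs are untouched. Set
#' `palindromic_only = FALSE` to apply the frequency rule to every
#' variant.
#'
#' @param dat An `mr_harmonized` tibble.
#' @param maf_limit Minor-allele-frequency cutoff; the default drops
#'   MAF > 0.42.
#' @param palindromic_only Restrict the rule to palindromic pairs
#'   (default) or apply it to all.
#' @return The `mr_harmonized` tibble with actions updated.
#' @export
drop_intermediate_palindromes <- function(dat, maf_limit = 0.42,
                                          palindromic_only = TRUE) {
  live <- !startsWith(dat$action, "dropped")
  scope <- if (palindromic_only) dat$palindromic else rep(TRUE, nrow(dat))
  maf <- pmin(dat$eaf, 1 - dat$eaf)
  dat$action[live & scope & !is.na(maf) & maf > maf_limit] <-
    "dropped_palindromic"
  dat$action[live & dat$palindromic & is.na(maf)] <- "dropped_palindromic_na"
  restore_harmonized(dat, dat)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s (%s): %d pairs retained, %d dropped\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              attr(x, "direction"),
              sum(!startsWith(x$action, "dropped")),
              sum(startsWith(x$action, "dropped"))))
  NextMethod()
}
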