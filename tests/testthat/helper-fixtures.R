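# Shared fixture builders. Everything is constructed in code; no data
# files are read except the temporary ones a test writes itself.

# A harmonized set built directly from numeric vectors (all pairs
# retained, aligned). Lets estimator tests state instrument effects
# without running the harmonizer.
make_harmonized <- function(beta_exposure, se_exposure,
                            beta_outcome, se_outcome,
                            eaf = rep(0.3, length(beta_exposure)),
                            palindromic = rep(FALSE, length(beta_exposure)),
                            action = rep("aligned", length(beta_exposure)),
                            variant_id = sprintf("rs%04d",
                                                 seq_along(beta_exposure))) {
  out <- tibble::tibble(
    variant_id = variant_id,
    chrom = "1", pos = seq_along(beta_exposure) * 1000L,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    pval_exposure = 2 * stats::pnorm(-abs(beta_exposure / se_exposure)),
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf = eaf, eaf_outcome = eaf,
    palindromic = palindromic, action = action)
  structure(out, exposure_id = "exposure", outcome_id = "outcome",
            direction = "forward",
            class = c("mr_harmonized", class(out)))
}

# Harmonized set with chosen Wald ratios and exactly equal weights:
# beta_exposure = 1, se_outcome = 1 gives w = 1 and b = beta_outcome.
make_ratios <- function(b, se_b = rep(1, length(b))) {
  make_harmonized(beta_exposure = rep(1, length(b)),
                  se_exposure = rep(0.01, length(b)),
                  beta_outcome = b, se_outcome = se_b)
}

# Fast path from a simulate_pair() result to a harmonized set: the
# generator emits exposure and outcome on the same allele orientation,
# so pairing is a column bind.
sim_to_harmonized <- function(sim, instruments_only = TRUE) {
  e <- sim$exposure
  o <- sim$outcome
  if (instruments_only) {
    keep <- sim$truth$is_instrument
    e <- e[keep, ]
    o <- o[keep, ]
  }
  make_harmonized(e$beta, e$se, o$beta, o$se, eaf = e$eaf,
                  variant_id = e$variant_id)
}

# Minimal valid summary-stat tibble for IO tests.
toy_sumstats_df <- function(n = 5) {
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1000L,
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    eaf = seq(0.1, 0.5, length.out = n),
    beta = seq(-0.2, 0.2, length.out = n),
    se = rep(0.05, n),
    pval = seq(1e-8, 1e-4, length.out = n),
    n = rep(10000, n))
}

toy_catalog <- function() {
  as_catalog(tibble::tibble(
    variant_id = c("rs1", "rs1", "rs2", "rs3", "rs4"),
    trait = c("lung cancer", "height", "height", "breast tumour", "bmi"),
    pval = c(1e-9, 1e-10, 1e-12, 1e-6, 1e-9),
    is_eqtl = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    regulome_annotated = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    eaf_ref = c(0.3, 0.3, 0.4, NA, 0.25),
    eaf_allele = c("A", "A", "C", NA, "T")))
}
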