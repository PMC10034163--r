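test_that("threshold profiles carry the documented defaults", {
  loose <- threshold_profile("loose")
  strict <- threshold_profile("strict")
  expect_equal(c(loose$p_threshold, loose$clump_r2, loose$clump_window_kb),
               c(1e-5, 0.01, 10000))
  expect_equal(c(strict$p_threshold, strict$clump_r2, strict$clump_window_kb),
               c(5e-6, 0.001, 10000))
  over <- threshold_profile("loose", p_threshold = 1e-6)
  expect_equal(over$p_threshold, 1e-6)
})

test_that("p-value filtering uses a strict inequality and preserves order", {
  df <- toy_sumstats_df(3)
  df$pval <- c(1e-6, 2e-5, 1e-5)   # last sits exactly on the boundary
  ss <- as_sumstats(df)
  kept <- filter_by_pvalue(ss, threshold_profile("loose"))
  expect_equal(kept$variant_id, "rs1")

  df$pval <- rep(0.5, 3)
  expect_equal(nrow(filter_by_pvalue(as_sumstats(df))), 0)

  # idempotent
  expect_equal(as.data.frame(filter_by_pvalue(kept)), as.data.frame(kept))
})

test_that("F statistic and variance explained match their formulas", {
  expect_equal(f_statistic(0.1, 0.0316), 0.1^2 / 0.0316^2)
  expect_equal(round(f_statistic(0.1, 0.0316), 2), 10.01)
  expect_equal(f_statistic(0, 1), 0)
  expect_equal(f_statistic(-0.2, 0.05), 16)   # sign-invariant
  expect_error(f_statistic(0.1, 0), "positive")

  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_equal(variance_explained(1, 0), 0)
  expect_equal(variance_explained(0.3, 0.2), 0.0288)
  expect_error(variance_explained(0.3, NA), "supplement_eaf")
  # maximal at f = 0.5 for fixed beta
  f <- seq(0.05, 0.95, by = 0.05)
  expect_equal(f[which.max(variance_explained(0.3, f))], 0.5)
})

test_that("the weak-instrument filter keeps F >= 10 inclusively", {
  df <- toy_sumstats_df(3)
  df$beta <- c(sqrt(9.9), sqrt(10), sqrt(50))  # se = 1 gives F directly
  df$se <- 1
  ss <- as_sumstats(df)
  kept <- filter_weak_instruments(ss)
  expect_equal(kept$variant_id, c("rs2", "rs3"))
  expect_equal(nrow(filter_weak_instruments(ss, min_f = 1e6)), 0)
  expect_equal(filter_weak_instruments(ss, min_f = 0)$variant_id,
               ss$variant_id)
  # idempotent
  expect_equal(filter_weak_instruments(kept)$variant_id, kept$variant_id)
})

test_that("greedy clumping keeps the most significant variant per clump", {
  # two variants in perfect LD, 1 kb apart: the smaller p-value wins
  cfg <- sim_config(n_variants = 4, ld_blocks = list(list(size = 2, r2 = 1)),
                    n_individuals = 100, seed = 31)
  panel <- simulate_panel(cfg)
  df <- toy_sumstats_df(4)
  df$variant_id <- panel$variants$variant_id
  df$chrom <- panel$variants$chrom
  df$pos <- panel$variants$pos
  df$pval <- c(1e-6, 1e-8, 1e-7, 1e-7)
  ss <- as_sumstats(df)
  kept <- ld_clump(ss, panel, threshold_profile("loose"))
  expect_true("rs0002" %in% kept$variant_id)   # the 1e-8 index
  expect_false("rs0001" %in% kept$variant_id)
  # independent variants on other chromosomes survive
  expect_true(all(c("rs0003", "rs0004") %in% kept$variant_id))
})

test_that("block-structured panels clump to one index per block", {
  cfg <- sim_config(n_variants = 10,
                    ld_blocks = list(list(size = 5, r2 = 0.9),
                                     list(size = 5, r2 = 0.9)),
                    n_individuals = 2000, seed = 32)
  panel <- simulate_panel(cfg)
  df <- toy_sumstats_df(10)
  df$variant_id <- panel$variants$variant_id
  df$chrom <- panel$variants$chrom
  df$pos <- panel$variants$pos
  set.seed(33)
  df$pval <- 10^(-runif(10, 5, 9))
  ss <- as_sumstats(df)
  profile <- threshold_profile("loose")   # clump_r2 = 0.01
  kept <- ld_clump(ss, panel, profile)
  expect_equal(nrow(kept), 2)

  # oracle: exhaustive greedy on the empirical r2 matrix
  r2m <- cor(t(panel$genotypes))^2
  remaining <- order(df$pval)
  oracle <- character(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    oracle <- c(oracle, df$variant_id[idx])
    same <- df$chrom[remaining] == df$chrom[idx] &
      abs(df$pos[remaining] - df$pos[idx]) <= 1e7
    remaining <- remaining[!(same & r2m[idx, remaining] > profile$clump_r2)]
  }
  expect_setequal(kept$variant_id, oracle)

  # retained pairs on the same chromosome within the window are
  # mutually independent at the profile r2
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i < j && kept$chrom[i] == kept$chrom[j]) {
      expect_lte(cor(panel$genotypes[kept$variant_id[i], ],
                     panel$genotypes[kept$variant_id[j], ])^2,
                 profile$clump_r2)
    }
  }
  # every clump keeps its smallest p-value
  expect_true(min(df$pval) %in% kept$pval)
  # idempotent
  expect_equal(ld_clump(kept, panel, profile)$variant_id, kept$variant_id)
})

test_that("variants absent from the panel are dropped with a warning", {
  cfg <- sim_config(n_variants = 3, n_individuals = 50, seed = 35)
  panel <- simulate_panel(cfg)
  df <- toy_sumstats_df(3)
  df$variant_id <- c(panel$variants$variant_id[1:2], "rs_missing")
  ss <- as_sumstats(df)
  expect_warning(kept <- ld_clump(ss, panel), "absent")
  expect_equal(nrow(kept), 2)
})

test_that("confounder screening removes genome-wide confounder hits only", {
  df <- toy_sumstats_df(4)
  ss <- as_sumstats(df)
  cat <- toy_catalog()
  kept <- screen_confounders(ss, cat)
  # rs1: lung cancer at 1e-9 -> removed; rs3: tumour at 1e-6 -> retained
  expect_false("rs1" %in% kept$variant_id)
  expect_true(all(c("rs2", "rs3", "rs4") %in% kept$variant_id))
  expect_equal(attr(kept, "confounder_removed")$variant_id, "rs1")
  # a variant absent from the catalog is retained; filter is idempotent
  expect_equal(screen_confounders(kept, cat)$variant_id, kept$variant_id)
})

test_that("frequency supplementation honors the stored allele", {
  df <- toy_sumstats_df(4)           # rs1 EA/OA = A/G, rs4 EA/OA = T/C
  df$eaf <- NA
  ss <- as_sumstats(df)
  out <- supplement_eaf(ss, toy_catalog())
  expect_equal(out$eaf[out$variant_id == "rs1"], 0.3)    # same allele
  expect_equal(out$eaf[out$variant_id == "rs4"], 0.25)   # stored for EA = T
  # rs2 catalog allele C == its effect allele
  expect_equal(out$eaf[out$variant_id == "rs2"], 0.4)
  # rs3 has no usable frequency -> flagged missing
  expect_true(is.na(out$eaf[out$variant_id == "rs3"]))
  expect_true(is.na(out$eaf_supplemented[out$variant_id == "rs3"]))

  # complement rule: frequency stored for the other allele
  cat2 <- as_catalog(tibble::tibble(
    variant_id = "rs1", trait = "none", pval = 0.5, is_eqtl = FALSE,
    regulome_annotated = TRUE, eaf_ref = 0.3, eaf_allele = "G"))
  out2 <- supplement_eaf(ss, cat2)
  expect_equal(out2$eaf[out2$variant_id == "rs1"], 0.7)
})

test_that("the cis-pQTL filter keeps annotated non-eQTL variants", {
  df <- toy_sumstats_df(5)
  ss <- as_sumstats(df)
  kept <- filter_pqtl_instruments(ss, toy_catalog())
  # rs1/rs4 annotated non-eQTL; rs2 eQTL; rs3 unannotated; rs5 absent
  expect_setequal(kept$variant_id, c("rs1", "rs4"))
  removed <- attr(kept, "pqtl_removed")
  expect_equal(removed$reason[removed$variant_id == "rs2"], "eqtl")
  expect_equal(removed$reason[removed$variant_id == "rs3"], "unannotated")
  expect_equal(removed$reason[removed$variant_id == "rs5"], "unannotated")
  expect_equal(filter_pqtl_instruments(kept, toy_catalog())$variant_id,
               kept$variant_id)
})
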