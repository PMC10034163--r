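#' Configuration for the synthetic GWAS generator
#'
#' Bundles and validates the parameters of the two-sample summary-
#' statistic generative model (see [simulate_pair()]). Defaults emulate
#' the scale of a microbiome-abundance exposure GWAS paired with a
#' protein-level outcome GWAS: an exposure sample of 18,340, an outcome
#' sample of 3,301, common variants (effect-allele frequency 0.05-0.5 on
#' the minor-allele side) and per-variant exposure effects of a few
#' percent of a standard deviation.
#'
#' @param n_variants Number of designated instrument variants (>= 3).
#' @param n_null_variants Background variants with zero exposure effect.
#' @param n_exposure,n_outcome GWAS sample sizes driving standard errors.
#' @param causal_beta True causal effect of exposure on outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   effects) or `"directional"` (mean `pleiotropy_sd` direct effects),
#'   applied to the invalid subset only.
#' @param pleiotropy_sd Standard deviation (and, for directional mode,
#'   mean) of pleiotropic direct effects; >= 0.
#' @param invalid_fraction Fraction of instruments given a pleiotropic
#'   direct effect, in \[0, 1\].
#' @param eaf_range Numeric length-2, allele-frequency range, within
#'   (0, 0.5].
#' @param gamma_sd Spread of true instrument-exposure effects; > 0.
#' @param ld_blocks Optional list of `list(size =, r2 =)` blocks used by
#'   [simulate_panel()]; variants not covered by a block are mutually
#'   independent.
#' @param n_individuals Individuals in the simulated reference panel.
#' @param noise_scale Multiplier on sampling noise of estimated effects;
#'   0 gives the noiseless large-sample limit (standard errors are still
#'   reported at their analytic values).
#' @param seed Integer seed governing all randomness, or `NULL` to use
#'   the current RNG stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 20,
                       n_null_variants = 0,
                       n_exposure = 18340,
                       n_outcome = 3301,
                       causal_beta = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.1,
                       invalid_fraction = 0,
                       eaf_range = c(0.05, 0.5),
                       gamma_sd = 0.15,
                       ld_blocks = NULL,
                       n_individuals = 500,
                       noise_scale = 1,
                       seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  check_number(n_variants, "n_variants", lower = 3)
  check_number(n_null_variants, "n_null_variants", lower = 0)
  check_number(n_exposure, "n_exposure", lower = 1)
  check_number(n_outcome, "n_outcome", lower = 1)
  check_number(causal_beta, "causal_beta")
  check_number(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  check_number(invalid_fraction, "invalid_fraction", lower = 0, upper = 1)
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] > 0.5 ||
      eaf_range[1] > eaf_range[2]) {
    abort("`eaf_range` must be [low, high] within (0, 0.5]")
  }
  check_number(gamma_sd, "gamma_sd", lower = 1e-12)
  check_number(n_individuals, "n_individuals", lower = 2)
  check_number(noise_scale, "noise_scale", lower = 0)
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, function(b) b$size, numeric(1))
    r2s <- vapply(ld_blocks, function(b) b$r2, numeric(1))
    if (any(sizes < 1) || any(r2s < 0 | r2s > 1)) {
      abort("`ld_blocks` entries need size >= 1 and r2 in [0, 1]")
    }
    if (sum(sizes) > n_variants + n_null_variants) {
      abort("`ld_blocks` sizes exceed the total variant count")
    }
  }
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(n_variants = as.integer(n_variants),
                 n_null_variants = as.integer(n_null_variants),
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 causal_beta = causal_beta,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 eaf_range = eaf_range, gamma_sd = gamma_sd,
                 ld_blocks = ld_blocks,
                 n_individuals = as.integer(n_individuals),
                 noise_scale = noise_scale, seed = seed),
            class = "sim_config")
}

# Block membership for every variant: covered by ld_blocks in order,
# remaining variants are singleton blocks with r2 = 0. Blocks sit on
# separate chromosomes (cycled through 1..22) so cross-block clumping
# windows never overlap; within-block variants are 1 kb apart.
sim_block_layout <- function(config) {
  total <- config$n_variants + config$n_null_variants
  sizes <- if (is.null(config$ld_blocks)) integer(0) else
    vapply(config$ld_blocks, function(b) as.integer(b$size), integer(1))
  r2s <- if (is.null(config$ld_blocks)) numeric(0) else
    vapply(config$ld_blocks, function(b) b$r2, numeric(1))
  n_single <- total - sum(sizes)
  sizes <- c(sizes, rep(1L, n_single))
  r2s <- c(r2s, rep(0, n_single))
  block <- rep(seq_along(sizes), sizes)
  within <- unlist(lapply(sizes, seq_len))
  tibble(variant_id = sprintf("rs%04d", seq_len(total)),
         block = block,
         block_r2 = r2s[block],
         chrom = as.character((block - 1L) %% 22L + 1L),
         pos = as.integer(1e6 * block + 1000L * within))
}

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Generates summary statistics under the standard two-sample MR model.
#' Each instrument j has a true effect on the exposure, `gamma_j`, drawn
#' from Normal(0, `gamma_sd`^2) truncated away from zero at 0.01; null
#' background variants have `gamma_j = 0`. The true effect on the
#' outcome is `causal_beta * gamma_j + alpha_j`, where the direct
#' (pleiotropic) effect `alpha_j` is nonzero only for the invalid
#' subset: Normal(0, `pleiotropy_sd`^2) under balanced pleiotropy,
#' Normal(`pleiotropy_sd`, `pleiotropy_sd`^2) *on the
#' exposure-increasing allele* under directional pleiotropy (the draw
#' is multiplied by `sign(gamma_j)`). Directional pleiotropy is only
#' meaningful relative to an allele orientation: defining it on the
#' exposure-increasing allele makes the per-variant ratio estimates
#' shift coherently upward, which is what biases IVW and produces a
#' positive Egger intercept in expectation.
#' Estimated effects add sampling noise with the allele-frequency /
#' sample-size standard error of a variance-1 trait,
#' `se = 1 / sqrt(2 f (1 - f) n)`, and two-sided normal p-values.
#'
#' Randomness is drawn in a fixed documented order (frequencies, exposure
#' effects, invalid flags, pleiotropic effects, exposure noise, outcome
#' noise) so a given seed is fully reproducible.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (each an
#'   `mr_sumstats` tibble) and `truth`, a tibble with the per-variant
#'   ground truth (`gamma`, `alpha`, `invalid`, `eaf`, `is_instrument`)
#'   plus attribute `causal_beta`.
#' @examples
#' sim <- simulate_pair(sim_config(n_variants = 10, causal_beta = 0.3,
#'                                 seed = 1))
#' sim$truth
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_block_layout(config)
  total <- nrow(layout)
  n_iv <- config$n_variants
  is_instrument <- c(rep(TRUE, n_iv), rep(FALSE, total - n_iv))

  with_seed_if(config$seed, {
    f <- runif(total, config$eaf_range[1], config$eaf_range[2])
    gamma <- numeric(total)
    g <- rnorm(n_iv, 0, config$gamma_sd)
    g <- sign(g) * pmax(abs(g), 0.01)   # truncate away from degenerate ratios
    gamma[is_instrument] <- g
    n_invalid <- round(config$invalid_fraction * n_iv)
    invalid <- rep(FALSE, total)
    if (n_invalid > 0) invalid[sample(seq_len(n_iv), n_invalid)] <- TRUE
    alpha <- numeric(total)
    if (config$pleiotropy_mode != "none" && any(invalid)) {
      if (config$pleiotropy_mode == "directional") {
        # direct effect on the exposure-increasing allele
        alpha[invalid] <- sign(gamma[invalid]) *
          rnorm(sum(invalid), config$pleiotropy_sd, config$pleiotropy_sd)
      } else {
        alpha[invalid] <- rnorm(sum(invalid), 0, config$pleiotropy_sd)
      }
    } else {
      invalid[] <- FALSE
    }
    se_exp <- 1 / sqrt(2 * f * (1 - f) * config$n_exposure)
    se_out <- 1 / sqrt(2 * f * (1 - f) * config$n_outcome)
    beta_exp <- gamma + config$noise_scale * rnorm(total, 0, se_exp)
    beta_out <- config$causal_beta * gamma + alpha +
      config$noise_scale * rnorm(total, 0, se_out)
  })

  alleles <- tibble(effect_allele = rep(c("A", "C", "A", "G"),
                                        length.out = total),
                    other_allele = rep(c("G", "T", "C", "T"),
                                       length.out = total))
  base <- dplyr::bind_cols(layout[c("variant_id", "chrom", "pos")], alleles)
  make_ss <- function(beta, se, n, trait_id, trait_type) {
    as_sumstats(dplyr::mutate(base, eaf = f, beta = beta, se = se,
                              pval = pmax(normal_pval(beta, se), 1e-300),
                              n = n),
                trait_id = trait_id, trait_type = trait_type)
  }
  truth <- tibble(variant_id = layout$variant_id,
                  gamma = gamma, alpha = alpha, invalid = invalid,
                  eaf = f, is_instrument = is_instrument)
  attr(truth, "causal_beta") <- config$causal_beta
  list(exposure = make_ss(beta_exp, se_exp, config$n_exposure,
                          "sim_exposure", "microbe_taxon"),
       outcome = make_ss(beta_out, se_out, config$n_outcome,
                         "sim_outcome", "protein"),
       truth = truth)
}

#' Simulate a reference genotype panel with block LD structure
#'
#' Variants share the chromosome/position layout of [simulate_pair()]
#' under the same config. Within a block, each individual's two
#' haplotype alleles are copied from a latent block haplotype with
#' probability `r2^(1/4)` (and redrawn from the allele frequency
#' otherwise). Each variant then correlates with the latent haplotype
#' by `r2^(1/4)`, so any two block members correlate by `sqrt(r2)` and
#' their squared correlation hits the block target; across blocks
#' genotypes are independent.
#'
#' @param config A [sim_config()]; its `ld_blocks` define the structure.
#' @param seed Optional seed overriding `config$seed` (offset internally
#'   so the panel stream differs from the summary-statistic stream).
#' @return An `mr_panel`.
#' @export
simulate_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_block_layout(config)
  n_ind <- config$n_individuals
  seed <- seed %||% (if (is.null(config$seed)) NULL else config$seed + 1L)
  geno <- with_seed_if(seed, {
    f <- runif(nrow(layout), config$eaf_range[1], config$eaf_range[2])
    g <- matrix(0L, nrow(layout), n_ind)
    for (b in unique(layout$block)) {
      idx <- which(layout$block == b)
      fb <- f[idx[1]]   # one frequency per block keeps the calibration exact
      p_copy <- layout$block_r2[idx[1]]^(1 / 4)
      # two latent haplotypes per individual, shared within the block
      hap1 <- rbinom(n_ind, 1, fb)
      hap2 <- rbinom(n_ind, 1, fb)
      for (j in idx) {
        keep1 <- runif(n_ind) < p_copy
        keep2 <- runif(n_ind) < p_copy
        a1 <- ifelse(keep1, hap1, rbinom(n_ind, 1, fb))
        a2 <- ifelse(keep2, hap2, rbinom(n_ind, 1, fb))
        g[j, ] <- a1 + a2
      }
    }
    g
  })
  as_panel(geno, layout[c("variant_id", "chrom", "pos")])
}
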