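---
title: "Models and methods behind mrlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlink)
```

# The causal model

Two-sample Mendelian randomization treats genetic variants as
instruments for an exposure. Writing $\gamma_j$ for the effect of
variant $j$ on the exposure (estimated in one GWAS sample) and
$\Gamma_j$ for its effect on the outcome (estimated in an independent
sample), a valid instrument satisfies

$$\Gamma_j = \beta\,\gamma_j,$$

with $\beta$ the causal effect of the exposure on the outcome. Each
instrument yields a Wald ratio $b_j = \Gamma_j/\gamma_j$; estimators
differ in how they pool the $b_j$ when some instruments are invalid,
i.e. carry a direct (horizontally pleiotropic) effect $\alpha_j$ so
that $\Gamma_j = \beta\gamma_j + \alpha_j$.

Three assumptions underpin the design: relevance (the instrument
affects the exposure), independence (it is not associated with
confounders of the exposure–outcome relation), and exclusion
restriction (it affects the outcome only through the exposure).
Instrument selection targets relevance (p-value and F filters) and
independence (confounder screening); the estimator portfolio and the
pleiotropy diagnostics address exclusion-restriction violations.

# Estimators

All estimators use first-order weights
$w_j = \gamma_j^2/\mathrm{se}(\Gamma_j)^2$, equivalently
$1/\mathrm{se}(b_j)^2$ with
$\mathrm{se}(b_j)=\mathrm{se}(\Gamma_j)/|\gamma_j|$. Ignoring the
exposure-side sampling error in the weights is the convention of
standard two-sample MR software; it keeps the fixed-effects IVW
estimate algebraically identical to the zero-intercept weighted
least-squares slope of $\Gamma$ on $\gamma$, which the test suite
asserts to ten significant digits.

* **IVW (fixed effects)**: $\hat\beta = \sum w_j b_j / \sum w_j$ with
  $\mathrm{se} = (\sum w_j)^{-1/2}$.
* **IVW (multiplicative random effects)**: the same point estimate;
  the standard error is scaled by $\sqrt{\max(1, Q/(J-1))}$ where $Q$
  is Cochran's statistic, so it never undercuts the fixed-effects
  error. The flooring at 1 is the usual convention for the
  multiplicative model.
* **Switching rule**: `mr_ivw(mode = "auto")` uses random effects when
  $J > 4$ *or* when there is no significant heterogeneity
  ($Q$ p-value $\ge 0.10$), and fixed effects otherwise. This rule is
  the one this pipeline standardizes on; note it inverts the more
  common convention of reserving random effects for heterogeneous
  sets, which is why `mode = "fixed"`/`"random"` overrides are
  exposed.
* **MR-Egger**: weighted regression of $\Gamma_j$ on $\gamma_j$ with a
  free intercept after orienting every pair so $\gamma_j > 0$;
  inference on $t_{J-2}$. The intercept estimates the average
  directional pleiotropy under the InSIDE assumption (instrument
  strength independent of direct effects); the slope remains a
  consistent causal estimate in its presence. Egger additionally needs
  variation in instrument strength — the implementation refuses a set
  whose oriented $\gamma_j$ are all equal, where the design matrix is
  singular.
* **Weighted median**: the 0.5 point of the weighted empirical
  distribution of sorted ratios, interpolating the cumulative midpoint
  positions $s_j = \sum_{k\le j} w'_k - w'_j/2$; consistent while
  instruments carrying at least half the weight are valid.
* **Weighted mode**: the argmax of a weighted Gaussian kernel density
  over the $b_j$, bandwidth
  $h = \texttt{bandwidth\_factor}\times 0.9\min(\mathrm{sd},
  \mathrm{IQR}/1.34)\,J^{-1/5}$, located on a 512-point grid spanning
  $[\min b - 3h, \max b + 3h]$. Doubling the grid moves the estimate
  by less than $h/10$ (asserted in the tests). If every ratio
  coincides the common value is returned directly.

Weighted-median and weighted-mode standard errors come from a
parametric bootstrap (default 1,000 draws, seeded): each $b_j$ is
redrawn from $N(b_j, \mathrm{se}(b_j)^2)$ and the estimator
recomputed. All confidence intervals are normal-theory
$\hat\beta \pm 1.96\,\mathrm{se}$, matching the reporting style of
published MR tables; Egger p-values use $t_{J-2}$, IVW the normal.

# Diagnostics

**Cochran's Q** is $\sum_j w_j (b_j - \hat\beta_{\rm IVW})^2$ on
$J-1$ degrees of freedom, with p < 0.10 read as significant
heterogeneity. The per-variant terms sum to $Q$ exactly.

**Radial scan**: regressing $b_j\sqrt{w_j}$ on $\sqrt{w_j}$ through
the origin reproduces the fixed-effects IVW slope exactly under
first-order weights (an algebraic identity the tests assert), and its
squared residuals are the per-variant $Q_j$. A variant is an outlier
when its $\chi^2_1$ tail probability falls below $0.05/J$ — the
Bonferroni split of the 0.05 family level over the instruments. The
same per-SNP level is the default for the residual test below, since
the two diagnostics are meant to flag the same variants.

**Residual (MR-PRESSO style) test**: the observed statistic is
$\mathrm{RSS} = \sum_j w_j (b_j - \hat\beta_{-j})^2$ with
$\hat\beta_{-j}$ the leave-one-out IVW estimate. Its null
distribution is simulated parametrically: $\Gamma^*_j \sim
N(\gamma_j\hat\beta_{-j}, \mathrm{se}(\Gamma_j)^2)$ and
$\gamma^*_j \sim N(\gamma_j, \mathrm{se}(\gamma_j)^2)$, recomputing
RSS each time (vectorized over simulations, so the default 1,000
draws cost milliseconds). Empirical p-values carry a $+1/(n_{\rm
sim}+1)$ continuity correction and are therefore never zero; a
per-variant p-value needs $n_{\rm sim} \ge 400$ to resolve below the
$0.05/20$ Bonferroni level at $J=20$. When outliers are found, the
distortion component compares the shift between the all-variant and
outlier-free IVW estimates against shifts from removing random
non-outlier subsets of the same size.

**Leave-one-out** re-estimates IVW (auto mode) omitting each variant
in turn. The result is flagged *robust* when every reduced-set
estimate keeps the sign of the full estimate and every reduced-set
95% CI overlaps the full CI. Published analyses rarely define
"robust" operationally; this criterion is this package's
reproducible operationalization.

The per-pair pipeline removes the union of radial and residual-test
outliers once, then re-estimates; removed ids are logged in the
provenance table.

# Instrument selection and harmonization

Two named profiles bundle the selection thresholds: `loose`
(p < 1e-5, clump r² < 0.01, 10,000-kb window) for exploratory
microbiome exposures where genome-wide significant variants are
scarce, and `strict` (p < 5e-6, r² < 0.001, 10,000-kb) for
validation. The p-value filter is strictly `<` while the F filter is
inclusive `≥ 10` — both inequalities are deliberate and tested at the
boundary. Clumping is greedy: the smallest p-value indexes each
clump (ties broken by chromosome then position for determinism), and
LD is the squared Pearson correlation of 0/1/2 genotype codes from
the reference panel — the standard composite estimate when phase is
unknown. Monomorphic panel variants carry no LD information and are
treated as uncorrelated.

Harmonization aligns outcome effects to the exposure's effect allele
through sign flips and strand complements; incompatible allele pairs
and instruments missing from the outcome are dropped (no proxy
search). Palindromic pairs (A/T, C/G) cannot be strand-resolved from
alleles, so orientation is inferred from allele frequencies when both
are available and the pair's minor-allele frequency is
unambiguous; pairs with MAF > 0.42 are dropped after harmonization.
The 0.42 rule is restricted to palindromic pairs by default — the
standard rationale, since only they are strand-ambiguous — with
`palindromic_only = FALSE` available to apply it to every variant. A
palindrome whose frequency is missing is dropped under its own reason
code, since the rule cannot be checked.

The annotation catalog is a local file standing in for online variant
annotation services: trait associations for the confounder screen
(default terms "cancer", "tumor", "tumour" matched case-insensitively
as substrings, association threshold 5e-8), eQTL/regulatory flags for
the cis-pQTL filter, and reference allele frequencies for
supplementing missing EAFs. The catalog schema includes an optional
`EAF_ALLELE` column naming the allele its frequency refers to; without
it the frequency is assumed to be on the matched effect allele, and a
frequency stored for the other allele is complemented.

The pipeline applies the F ≥ 10 screen at selection time, before
harmonization, and reports per-variant F in the outputs.

# The synthetic-GWAS generator

`simulate_pair()` implements the standard two-sample generative model:
$\gamma_j \sim N(0, \sigma_\gamma^2)$ truncated away from zero at
0.01 (avoiding degenerate Wald ratios) for instruments, zero for null
background variants; $\Gamma_j = \beta\gamma_j + \alpha_j$; estimated
effects add noise at the allele-frequency/sample-size standard error
of a variance-1 trait, $\mathrm{se} = 1/\sqrt{2f(1-f)n}$, and
p-values are exact two-sided normal tails of $\hat\beta/\mathrm{se}$.
Randomness is drawn in a fixed order (frequencies, exposure effects,
invalid flags, pleiotropic effects, exposure noise, outcome noise)
under a single integer seed. `noise_scale = 0` gives the noiseless
large-sample limit in which every ratio equals $\beta$ exactly.

Pleiotropy modes: *balanced* draws $\alpha_j \sim N(0,
\sigma_\alpha^2)$ on the invalid subset; *directional* draws
$\mathrm{sign}(\gamma_j)\, N(\sigma_\alpha, \sigma_\alpha^2)$ — that
is, the direct effect is defined on the exposure-increasing allele.
The orientation coupling matters: with a sign-symmetric $\gamma$
distribution, an orientation-free "directional" $\alpha$ would
contribute $\sum_j \gamma_j\alpha_j$ with expectation zero to the IVW
numerator, producing neither IVW bias nor an Egger intercept in
expectation. Defining directionality relative to the
exposure-increasing allele makes the ratio estimates shift coherently,
which is what "directional pleiotropy" means operationally and what
makes the robustness contrasts in the test suite well-posed.

The LD panel generator copies each individual's two haplotype alleles
from a latent block haplotype with probability $r_2^{1/4}$, so any two
block members correlate by $\sqrt{r_2}$ and their squared correlation
hits the block target; blocks sit on separate chromosomes with
variants 1 kb apart, so clumping windows behave predictably.

Defaults emulate the scale of the motivating setting: an exposure GWAS
of 18,340 (a multi-cohort microbiome study), an outcome GWAS of 3,301
(a proteomic study), allele frequencies uniform on (0.05, 0.5),
$\sigma_\gamma = 0.15$, $\sigma_\alpha = 0.1$. The generator emulates
summary statistics only: it does not model sample overlap between the
two GWAS, case-control traits, winner's curse from in-sample
selection, allele-frequency drift between cohorts, population
stratification, or real LD spectra (blocks are exchangeable with a
single within-block r² target). Passing tests therefore demonstrate
the pipeline's statistical behavior under its stated model, not
robustness to those additional features of real data.

# Problem sizes and numerical choices

The property suites use sample sizes of 50,000 per GWAS, chosen so
that the negligible-measurement-error (NOME) assumption behind the
Egger intercept test effectively holds (typical
$|\gamma_j|/\mathrm{se}(\gamma_j) \approx 12$) and so valid-instrument
ratios are tight relative to the contamination the robust estimators
are asked to absorb. The contamination suite plants 30% invalid
instruments with directional $\sigma_\alpha = 0.15$ at true
$\beta = 0.3$, $J = 20$; the calibration suites use 200–2,000
replicates and 500-draw residual-test simulations; end-to-end
coverage runs roughly 200 replicates of a 50-instrument pair over
$\beta \in \{-0.3, 0, 0.3\}$. These sizes are the package's chosen
design points for stable Monte-Carlo assertions at desk scale.

Other numerical conventions: bootstrap and simulation counts are
configurable and seeded; empirical p-values are continuity-corrected;
the weighted-mode bandwidth falls back to returning the common ratio
when the spread is exactly zero; clumping tie-breaks are
deterministic; zero-exposure-effect pairs are excluded from ratio
computations (and a single-pair Wald ratio with $\gamma = 0$ is an
error); all allele characters are uppercased on read and positions are
1-based.

# Multiple testing and power

The FDR family is a genuine design choice. The default,
`per_pair_methods`, adjusts within each exposure–outcome pair across
the estimator p-values — correcting by the number of MR methods, with
the two IVW variants counting once (the primary one enters the
family). The alternative, `per_outcome_exposures`, adjusts primary
IVW p-values across exposures within each outcome, direction and
profile — the wider family a multi-taxon screen suggests. Both are
one flag apart; significance labels always use the primary IVW
adjusted p-value at 0.05.

Power uses the closed form
$\Phi(\sqrt{n r^2}\,|\beta| - z_{1-\alpha/2})$ for the two-sided
$\alpha$-level Wald test, with $n$ the outcome sample size and $r^2$
the instrument-explained exposure variance;
`minimum_detectable_effect()` is its exact inverse, and the worked
design point (n = 3,301, r² = 0.02, 80% power at β = 0.345) is
asserted in the tests.

# Limitations

Beyond the generator simplifications above: first-order weights ignore
exposure-side error (second-order or exact weights are a future
extension); no proxy-SNP search for instruments missing from the
outcome GWAS; biallelic variants only, no liftover, no VCF/PLINK
formats; the residual test's distortion component follows the common
bootstrap scheme and inherits its conservativeness at small $J$; and
the bidirectional scan treats every trait pair independently — no
multivariable MR, no Steiger filtering, no account of correlated
exposures.
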