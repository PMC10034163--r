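test_that("Wald ratio matches the delta-method formula", {
  r <- wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(r$beta, 2)
  expect_equal(r$se, 0.5)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.05)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "zero exposure effect")
})

test_that("IVW reduces to the weighted mean of ratios", {
  # equal weights: plain mean
  h <- make_ratios(c(0.1, 0.3))
  expect_equal(mr_ivw(h, mode = "fixed")$beta, 0.2)

  # identical ratios: Q = 0, fixed and random standard errors agree
  h2 <- make_ratios(rep(0.4, 5))
  fe <- mr_ivw(h2, mode = "fixed")
  re <- mr_ivw(h2, mode = "random")
  expect_equal(fe$beta, 0.4)
  expect_equal(fe$extra$Q, 0)
  expect_equal(fe$se, re$se)

  # random-effects se never undercuts fixed-effects
  h3 <- make_ratios(c(0, 0.5, 1, 2))
  expect_gte(mr_ivw(h3, mode = "random")$se, mr_ivw(h3, mode = "fixed")$se)
})

test_that("IVW fixed-effects equals zero-intercept WLS to 10 digits", {
  set.seed(71)
  for (i in 1:20) {
    J <- sample(5:30, 1)
    g <- rnorm(J, 0, 0.2); g <- sign(g) * pmax(abs(g), 0.02)
    se_o <- abs(rnorm(J, 0, 0.02)) + 0.005
    G <- 0.3 * g + rnorm(J, 0, se_o)
    h <- make_harmonized(g, rep(0.01, J), G, se_o)
    est <- mr_ivw(h, mode = "fixed")
    wls <- lm(G ~ 0 + g, weights = 1 / se_o^2)
    expect_equal(est$beta, unname(coef(wls)), tolerance = 1e-10)
    expect_equal(est$se, sqrt(1 / sum(g^2 / se_o^2)), tolerance = 1e-10)
  }
})

test_that("the auto rule switches IVW variants as documented", {
  # J > 4 -> random effects regardless of heterogeneity
  h5 <- make_ratios(c(0, 1, 2, 3, 4))
  expect_equal(mr_ivw(h5, mode = "auto")$method, "ivw_re")
  # J <= 4 with strong heterogeneity (Q p < 0.10) -> fixed effects
  h_het <- make_ratios(c(0, 5, -5), se_b = rep(0.5, 3))
  expect_lt(mr_ivw(h_het, mode = "fixed")$extra$Q_pval, 0.10)
  expect_equal(mr_ivw(h_het, mode = "auto")$method, "ivw_fe")
  # J <= 4 without heterogeneity -> random effects
  h_hom <- make_ratios(c(0.29, 0.3, 0.31))
  expect_gte(mr_ivw(h_hom, mode = "fixed")$extra$Q_pval, 0.10)
  expect_equal(mr_ivw(h_hom, mode = "auto")$method, "ivw_re")
})

test_that("MR-Egger recovers slope and intercept on noiseless data", {
  g <- c(0.1, -0.2, 0.3, 0.15, -0.25)
  # after orientation to positive gamma: Gamma = 0.5 * gamma
  G <- 0.5 * g
  h <- make_harmonized(g, rep(0.01, 5), G, rep(0.02, 5))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extra$intercept, 0, tolerance = 1e-10)

  # constant pleiotropy after orientation becomes the intercept
  G2 <- 0.5 * abs(g) + 0.02
  G2 <- G2 * sign(g)                      # express on original orientation
  h2 <- make_harmonized(g, rep(0.01, 5), G2, rep(0.02, 5))
  e2 <- mr_egger(h2)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$extra$intercept, 0.02, tolerance = 1e-10)
})

test_that("MR-Egger equals the closed-form 2x2 WLS solution", {
  set.seed(72)
  for (i in 1:20) {
    J <- sample(5:25, 1)
    g <- rnorm(J, 0, 0.2); g <- sign(g) * pmax(abs(g), 0.02)
    se_o <- abs(rnorm(J, 0, 0.02)) + 0.005
    G <- 0.3 * g + 0.01 + rnorm(J, 0, se_o)
    h <- make_harmonized(g, rep(0.01, J), G, se_o)
    e <- mr_egger(h)
    # oracle: weighted normal equations on oriented data
    x <- abs(g); y <- G * sign(g); w <- 1 / se_o^2
    sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
    sy <- sum(w * y); sxy <- sum(w * x * y)
    det <- sw * sxx - sx^2
    slope <- (sw * sxy - sx * sy) / det
    intercept <- (sxx * sy - sx * sxy) / det
    expect_equal(e$beta, slope, tolerance = 1e-10)
    expect_equal(e$extra$intercept, intercept, tolerance = 1e-10)
  }
})

test_that("the weighted median interpolates the weighted distribution", {
  # hand oracle: s = {1/6, 1/2, 5/6}; 0.5 hits the middle ratio
  h <- make_ratios(c(0.1, 0.2, 0.9))
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta, 0.2)

  # all ratios identical: the common value, bootstrap se near the
  # analytic se of a median of equal normals
  J <- 15
  h2 <- make_ratios(rep(0.3, J), se_b = rep(0.1, J))
  wm <- mr_weighted_median(h2, n_boot = 4000, seed = 2)
  expect_equal(wm$beta, 0.3)
  analytic <- sqrt(pi / 2) * 0.1 / sqrt(J)   # large-sample se of a median
  expect_lt(abs(wm$se - analytic), 0.35 * analytic)
})

test_that("the weighted median resists contamination that biases IVW", {
  set.seed(73)
  reps <- 40
  est <- replicate(reps, {
    sim <- simulate_pair(sim_config(n_variants = 20, causal_beta = 0.3,
                                    pleiotropy_mode = "directional",
                                    pleiotropy_sd = 0.15,
                                    invalid_fraction = 0.3,
                                    n_exposure = 5e4, n_outcome = 5e4))
    h <- sim_to_harmonized(sim)
    c(wm = mr_weighted_median(h, n_boot = 2)$beta,
      ivw = mr_ivw(h, mode = "fixed")$beta)
  })
  wm_bias <- mean(est["wm", ]) - 0.3
  ivw_bias <- mean(est["ivw", ]) - 0.3
  boot_se <- sd(est["wm", ]) / sqrt(reps)
  expect_lt(abs(wm_bias), 3 * boot_se + 0.05)
  expect_gt(abs(ivw_bias), abs(wm_bias))
})

test_that("the weighted mode finds the majority cluster", {
  h <- make_ratios(rep(0.4, 4))
  expect_equal(mr_weighted_mode(h, n_boot = 10, seed = 3)$beta, 0.4)

  h2 <- make_ratios(c(0.3, 0.3, 0.3, 0.9))
  m <- mr_weighted_mode(h2, n_boot = 10, seed = 4)
  expect_lt(abs(m$beta - 0.3), 0.05)
  # oracle: direct evaluation of the weighted KDE on the same grid
  b <- c(0.3, 0.3, 0.3, 0.9)
  hband <- 0.9 * min(sd(b), IQR(b) / 1.34) * 4^(-1 / 5)
  grid <- seq(min(b) - 3 * hband, max(b) + 3 * hband, length.out = 512)
  dens <- vapply(grid, function(x) sum(dnorm((x - b) / hband)) / hband,
                 numeric(1))
  expect_equal(m$beta, grid[which.max(dens)], tolerance = 1e-12)

  # grid refinement moves the mode by less than a tenth of a bandwidth
  m2 <- mr_weighted_mode(h2, n_boot = 10, seed = 4, grid_n = 1024)
  expect_lt(abs(m2$beta - m$beta), hband / 10)
})

test_that("estimators are invariant to pair order and joint sign flips", {
  sim <- simulate_pair(sim_config(n_variants = 15, causal_beta = 0.25,
                                  seed = 74))
  h <- sim_to_harmonized(sim)
  perm <- sample(nrow(h))
  h_perm <- h[perm, ]
  attributes(h_perm)[c("exposure_id", "outcome_id", "direction")] <-
    attributes(h)[c("exposure_id", "outcome_id", "direction")]
  h_flip <- h
  h_flip$beta_exposure <- -h_flip$beta_exposure
  h_flip$beta_outcome <- -h_flip$beta_outcome
  for (pair in list(list(h, h_perm), list(h, h_flip))) {
    expect_equal(mr_ivw(pair[[1]], "fixed")$beta,
                 mr_ivw(pair[[2]], "fixed")$beta, tolerance = 1e-12)
    expect_equal(mr_egger(pair[[1]])$beta, mr_egger(pair[[2]])$beta,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_median(pair[[1]], n_boot = 2)$beta,
                 mr_weighted_median(pair[[2]], n_boot = 2)$beta,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_mode(pair[[1]], n_boot = 2)$beta,
                 mr_weighted_mode(pair[[2]], n_boot = 2)$beta,
                 tolerance = 1e-12)
  }
})

test_that("without pleiotropy all estimators agree with the truth", {
  sim <- simulate_pair(sim_config(n_variants = 40, causal_beta = 0.3,
                                  n_exposure = 5e4, n_outcome = 5e4,
                                  seed = 75))
  res <- mr_estimate_all(sim_to_harmonized(sim), n_boot = 300, seed = 76)
  expect_true(all(abs(res$beta - 0.3) < 3 * res$se))
  expect_equal(sum(res$primary), 1)
  expect_equal(res$method[res$primary], "ivw_re")   # J > 4
})

test_that("tidy and glance return one well-formed row", {
  h <- make_ratios(c(0.1, 0.2, 0.3, 0.4, 0.5))
  r <- mr_ivw(h)
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_true(td$ci_low <= td$beta && td$beta <= td$ci_high)
  g <- seq(0.1, 0.5, length.out = 5)
  h2 <- make_harmonized(g, rep(0.01, 5), 0.3 * g, rep(0.02, 5))
  gl <- glance(mr_egger(h2))
  expect_false(is.na(gl$egger_intercept))
  # Egger refuses when every instrument has the same strength
  expect_error(mr_egger(h), "variation in instrument strength")
})
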