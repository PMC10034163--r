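test_that("Cochran's Q matches hand arithmetic and decomposes exactly", {
  # identical ratios: no heterogeneity at all
  q0 <- cochran_q(make_ratios(rep(0.7, 4)))
  expect_equal(q0$Q, 0)
  expect_equal(q0$pval, 1)

  # two unit-weight ratios 0 and 2: Q = 2 on 1 df
  q2 <- cochran_q(make_ratios(c(0, 2)))
  expect_equal(q2$Q, 2)
  expect_equal(q2$df, 1)
  expect_equal(q2$pval, pchisq(2, 1, lower.tail = FALSE))

  # per-variant contributions always sum to Q
  sim <- simulate_pair(sim_config(n_variants = 25, causal_beta = 0.2,
                                  pleiotropy_mode = "balanced",
                                  pleiotropy_sd = 0.05,
                                  invalid_fraction = 0.2, seed = 81))
  q <- cochran_q(sim_to_harmonized(sim))
  expect_equal(sum(q$per_variant_q), q$Q, tolerance = 1e-12)
})

test_that("under homogeneity Q has its chi-square mean", {
  # oracle: E[Q] = J - 1 under the null
  set.seed(82)
  J <- 50
  qs <- replicate(500, {
    b <- rnorm(J, 0.3, 0.1)
    cochran_q(make_ratios(b, se_b = rep(0.1, J)))$Q
  })
  expect_lt(abs(mean(qs) - (J - 1)) / (J - 1), 0.05)
})

test_that("the radial slope is the fixed-effects IVW estimate", {
  sim <- simulate_pair(sim_config(n_variants = 20, causal_beta = 0.15,
                                  seed = 83))
  h <- sim_to_harmonized(sim)
  expect_equal(radial_scan(h)$beta, mr_ivw(h, mode = "fixed")$beta,
               tolerance = 1e-10)
})

test_that("radial scan flags exactly the planted outlier", {
  # homogeneous noiseless set: nothing flagged
  g <- seq(0.1, 0.5, length.out = 8)
  h0 <- make_harmonized(g, rep(0.01, 8), 0.3 * g, rep(0.02, 8))
  expect_length(radial_scan(h0)$outlier_ids, 0)

  # plant one ratio 10 residual-SD away
  set.seed(84)
  J <- 20
  b <- rnorm(J, 0.3, 0.05)
  b[7] <- 0.3 + 10 * 0.05
  h1 <- make_ratios(b, se_b = rep(0.05, J))
  rs <- radial_scan(h1)
  expect_equal(rs$outlier_ids, "rs0007")
  # oracle: direct Q_j computation at the Bonferroni cut
  beta <- sum((1 / 0.05^2) * b) / sum(rep(1 / 0.05^2, J))
  qj <- (b - beta)^2 / 0.05^2
  expect_equal(unname(rs$per_variant_q), qj, tolerance = 1e-12)
  expect_setequal(rs$outlier_ids,
                  sprintf("rs%04d", which(pchisq(qj, 1, lower.tail = FALSE) <
                                            0.05 / J)))
})

test_that("the pleiotropy residual test is calm on consistent data", {
  g <- seq(0.1, 0.5, length.out = 10)
  h <- make_harmonized(g, rep(1e-4, 10), 0.3 * g, rep(0.02, 10))
  p <- mr_presso(h, n_sim = 300, seed = 85)
  expect_gt(p$global_pval, 0.5)
  expect_length(p$outlier_ids, 0)
  expect_equal(p$beta_raw, p$beta_corrected)
})

test_that("the residual test detects a planted gross outlier deterministically", {
  set.seed(86)
  J <- 20
  g <- rnorm(J, 0, 0.2); g <- sign(g) * pmax(abs(g), 0.05)
  se_o <- rep(0.02, J)
  G <- 0.3 * g + rnorm(J, 0, se_o)
  G[5] <- 0.3 * g[5] + 15 * se_o[5]
  h <- make_harmonized(g, rep(0.01, J), G, se_o)
  p1 <- mr_presso(h, n_sim = 500, seed = 87)
  expect_lt(p1$global_pval, 0.05)
  expect_true("rs0005" %in% p1$outlier_ids)
  # corrected estimate drops the outlier, distortion quantified
  expect_lt(abs(p1$beta_corrected - 0.3), abs(p1$beta_raw - 0.3))
  expect_false(is.na(p1$distortion_pval))
  # same seed, same input -> identical result
  p2 <- mr_presso(h, n_sim = 500, seed = 87)
  expect_identical(p1, p2)
  # radial and the residual test agree on the planted outlier
  expect_true("rs0005" %in% radial_scan(h)$outlier_ids)
})

test_that("residual-test refusal below 4 pairs names the requirement", {
  h <- make_ratios(c(0.1, 0.2, 0.3))
  expect_error(mr_presso(h), "at least 4")
})

test_that("leave-one-out recomputes per-instrument and flags instability", {
  # three instruments give exactly three rows
  h3 <- make_ratios(c(0.25, 0.3, 0.35))
  loo3 <- leave_one_out(h3)
  expect_equal(nrow(loo3), 3)

  # homogeneous noiseless data: every estimate equals the full one
  g <- seq(0.1, 0.5, length.out = 6)
  h <- make_harmonized(g, rep(0.01, 6), 0.3 * g, rep(0.02, 6))
  loo <- leave_one_out(h)
  expect_equal(loo$beta, rep(attr(loo, "full")$beta, 6), tolerance = 1e-12)
  expect_true(attr(loo, "robust"))

  # one dominant outlier: flag false, omitting it moves the estimate
  b <- c(rep(0.3, 6), 4)
  hout <- make_ratios(b, se_b = rep(0.05, 7))
  looo <- leave_one_out(hout, ivw_mode = "fixed")
  expect_false(attr(looo, "robust"))
  full <- attr(looo, "full")
  moved <- abs(looo$beta[looo$omitted == "rs0007"] - full$beta)
  expect_gt(moved, 1.96 * full$se)
})

test_that("outlier removal marks rows and is reflected in re-estimation", {
  h <- make_ratios(c(0.3, 0.31, 0.29, 5))
  h2 <- remove_outliers(h, "rs0004")
  expect_equal(h2$action[4], "dropped_outlier")
  expect_equal(nrow(retained_pairs(h2)), 3)
  expect_lt(abs(mr_ivw(h2, "fixed")$beta - 0.3), 0.02)
})
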