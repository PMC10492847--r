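# Causal-effect estimators.

test_that("Wald ratio and its two SE orders behave as defined", {
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$ratio, 0)
  w <- wald_ratio(0.1, 0.01, 0.1, 0.02)
  expect_equal(w$ratio, 1)
  expect_equal(w$se, 0.2)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "nonzero")

  # second-order SE dominates the first-order SE
  withr::with_seed(42, {
    be <- runif(1000, 0.01, 0.5) * sample(c(-1, 1), 1000, TRUE)
    se_e <- runif(1000, 0.001, 0.1)
    bo <- rnorm(1000, 0, 0.1)
    se_o <- runif(1000, 0.001, 0.1)
    w1 <- wald_ratio(be, se_e, bo, se_o, "first")
    w2 <- wald_ratio(be, se_e, bo, se_o, "second")
    expect_true(all(w2$se >= w1$se))
  })
})

test_that("IVW reproduces the hand-computed toy estimate and degenerate case", {
  h <- toy_harmonized()
  e <- mr_ivw(h)
  expect_equal(e$beta, 7 / 60)
  expect_equal(e$se, 1 / sqrt(600))
  expect_equal(e$n_snp, 3L)

  # identical ratios: theta = common ratio, Q = 0, random = fixed
  hc <- harmonized_set(
    data.frame(rsid = c("a", "b", "c"), beta_exp = c(0.1, 0.2, 0.4),
               se_exp = 0.01, beta_out = c(0.05, 0.10, 0.20), se_out = 0.01,
               stringsAsFactors = FALSE), "X", "Y")
  ef <- mr_ivw(hc, "fixed")
  er <- mr_ivw(hc, "random")
  expect_equal(ef$beta, 0.5)
  expect_equal(ef$extra$Q, 0, tolerance = 1e-20)
  expect_equal(er$beta, ef$beta)
  expect_equal(er$se, ef$se)  # Q/(k-1) < 1 bounded at 1

  expect_error(mr_ivw(harmonized_set(toy_harmonized()$pairs[1, ], "X", "Y")),
               "at least 2")
})

test_that("IVW equals weighted least squares through the origin (oracle)", {
  for (seed in 1:25) {
    h <- random_harmonized(sample(4:40, 1), seed = seed)
    expect_equal(mr_ivw(h)$beta, wls_origin_slope(h), tolerance = 1e-10)
  }
})

test_that("random-effects IVW keeps the point estimate and inflates the SE", {
  h <- random_harmonized(15, seed = 99)
  h$pairs$beta_out[1] <- h$pairs$beta_out[1] + 0.3  # force heterogeneity
  ef <- mr_ivw(h, "fixed"); er <- mr_ivw(h, "random")
  expect_equal(er$beta, ef$beta)
  expect_equal(er$se, ef$se * sqrt(ef$extra$Q / (er$n_snp - 1)))
  expect_gt(er$se, ef$se)
})

test_that("Egger matches the weighted normal equations and exact-line case", {
  # points exactly on beta_out = 0.5 * beta_exp
  hl <- harmonized_set(
    data.frame(rsid = sprintf("rs%d", 1:4), beta_exp = c(0.1, 0.2, 0.3, 0.4),
               se_exp = 0.01, beta_out = c(0.05, 0.10, 0.15, 0.20),
               se_out = c(0.01, 0.02, 0.01, 0.03), stringsAsFactors = FALSE),
    "X", "Y")
  eg <- mr_egger(hl)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-12)

  for (seed in 1:25) {
    h <- random_harmonized(sample(4:40, 1), seed = seed + 100)
    eg <- mr_egger(h)
    orc <- wls_egger_oracle(h)
    expect_equal(eg$slope$beta, orc$slope, tolerance = 1e-10)
    expect_equal(eg$intercept$estimate, orc$intercept, tolerance = 1e-10)
    # SEs: unscaled oracle SEs times the bounded overdispersion factor
    infl <- max(1, orc$sigma)
    expect_equal(eg$intercept$se, orc$se_unscaled[1] * infl, tolerance = 1e-10)
    expect_equal(eg$slope$se, orc$se_unscaled[2] * infl, tolerance = 1e-10)
  }
  expect_error(mr_egger(harmonized_set(toy_harmonized()$pairs[1:2, ],
                                       "X", "Y")), "at least 3")
})

test_that("weighted median interpolates the 0.5 crossing and resists outliers", {
  h <- harmonized_set(
    data.frame(rsid = c("a", "b", "c"), beta_exp = 0.1, se_exp = 0.01,
               beta_out = c(0.01, 0.02, 0.03), se_out = 0.01,
               stringsAsFactors = FALSE), "X", "Y")
  e <- mr_weighted_median(h, "simple", n_boot = 50, seed = 1)
  expect_equal(e$beta, 0.2)  # ratios {0.1, 0.2, 0.3}, equal weights

  # one wild outlier among 9 consistent ratios stays outside the estimate
  h9 <- random_harmonized(9, seed = 7, theta = 0.1)
  cols <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out")
  h2 <- harmonized_set(
    rbind(h9$pairs[cols],
          data.frame(rsid = "rs_out", beta_exp = 0.1, se_exp = 0.01,
                     beta_out = 0.5, se_out = 0.01)), "X", "Y")
  e2 <- mr_weighted_median(h2, n_boot = 100, seed = 2)
  ratios <- h9$pairs$beta_out / h9$pairs$beta_exp
  expect_gt(e2$beta, min(ratios)); expect_lt(e2$beta, max(ratios))
})

test_that("weighted median is invariant to duplicating a SNP at half weight", {
  r <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  w <- c(2, 1, 3, 1, 2)
  theta <- bimr:::.weighted_median_point(r, w)
  r2 <- c(r, r[3]); w2 <- w; w2[3] <- w[3] / 2; w2 <- c(w2, w[3] / 2)
  expect_equal(bimr:::.weighted_median_point(r2, w2), theta)
})

test_that("mode estimators find the majority cluster and handle degeneracy", {
  # all ratios identical -> the common ratio
  hc <- harmonized_set(
    data.frame(rsid = c("a", "b", "c"), beta_exp = c(0.1, 0.2, 0.4),
               se_exp = 0.01, beta_out = c(0.025, 0.05, 0.1), se_out = 0.01,
               stringsAsFactors = FALSE), "X", "Y")
  e <- mr_mode(hc, n_boot = 50, seed = 3)
  expect_equal(e$beta, 0.25)

  # 7 ratios near 0.1, 3 near 0.9 -> mode near 0.1
  withr::with_seed(8, {
    bx <- runif(10, 0.1, 0.3)
    target <- c(rep(0.1, 7), rep(0.9, 3))
    h <- harmonized_set(
      data.frame(rsid = sprintf("rs%d", 1:10), beta_exp = bx, se_exp = 0.01,
                 beta_out = bx * target + rnorm(10, 0, 0.002), se_out = 0.01,
                 stringsAsFactors = FALSE), "X", "Y")
  })
  es <- mr_mode(h, weighted = FALSE, n_boot = 50, seed = 4)
  expect_lt(abs(es$beta - 0.1), 0.05)

  # grid-search oracle: independent dense maximisation of the same density
  p <- h$pairs
  r <- p$beta_out / p$beta_exp
  w <- rep(1 / 10, 10)
  hband <- 0.9 * min(sd(r), mad(r)) * 10^(-1 / 5)
  grid <- seq(min(r) - hband, max(r) + hband, length.out = 40001)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, r, hband)), 1)
  expect_equal(es$beta, grid[which.max(dens)], tolerance = 1e-3)
})

test_that("odds-ratio conversion matches direct evaluation and is monotone", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$pvalue, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)  # symmetric CI

  o2 <- to_odds_ratio(0.1215, 0.0398)
  expect_equal(o2$or, 1.1292, tolerance = 2e-4)
  expect_equal(o2$ci_low, 1.0444, tolerance = 2e-4)
  expect_equal(o2$ci_high, 1.2209, tolerance = 2e-4)

  zr <- seq(0.1, 5, length.out = 30)
  ps <- vapply(zr, function(z) to_odds_ratio(z * 0.05, 0.05)$pvalue, 1)
  expect_true(all(diff(ps) < 0))
  expect_error(to_odds_ratio(0.1, 0), "se must be")
})

test_that("estimators are equivariant under joint sign flips of subsets", {
  h <- random_harmonized(12, seed = 31)
  flip <- c(2, 5, 7, 11)
  h2 <- h
  h2$pairs$beta_exp[flip] <- -h2$pairs$beta_exp[flip]
  h2$pairs$beta_out[flip] <- -h2$pairs$beta_out[flip]
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mr_mode(h2, n_boot = 10, seed = 1)$beta,
               mr_mode(h, n_boot = 10, seed = 1)$beta, tolerance = 1e-12)
})

test_that("mr_all returns the five methods (or the single-SNP fallback)", {
  h <- random_harmonized(10, seed = 13)
  res <- mr_all(h, n_boot = 50)
  expect_equal(res$method,
               c("IVW (fixed)", "MR-Egger", "Weighted median", "Simple mode",
                 "Weighted mode"))
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_equal(res$or, exp(res$beta))
  expect_false(is.null(attr(res, "egger_intercept")))

  h1 <- harmonized_set(h$pairs[1, ], "X", "Y")
  res1 <- mr_all(h1)
  expect_equal(res1$method, "Wald ratio")
  expect_equal(res1$beta, h$pairs$beta_out[1] / h$pairs$beta_exp[1])
})
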