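# Sensitivity analyses: Cochran Q / I2 heterogeneity, Egger-intercept
# pleiotropy test, leave-one-out influence, MR-PRESSO.

#' Cochran Q heterogeneity test
#'
#' `Q = sum(w_j (r_j - theta_IVW)^2)` over the per-SNP Wald ratios with IVW
#' weights `w_j = 1 / se(r_j)^2`, referred to a chi-square distribution
#' with k - 1 df. `I2 = max(0, (Q - df) / Q) * 100` summarises the share of
#' variation across instruments attributable to heterogeneity.
#'
#' @param x a [harmonized_set] with >= 2 pairs.
#' @param se_order Wald-ratio SE order for the weights.
#' @return list of class `heterogeneity_result` with `Q`, `df`, `pvalue`,
#'   `i2`.
#' @export
cochran_q <- function(x, se_order = "first") {
  .check_set(x, 2L, "cochran_q")
  p <- x$pairs
  wr <- wald_ratio(p$beta_exp, p$se_exp, p$beta_out, p$se_out, order = se_order)
  w <- 1 / wr$se^2
  theta <- sum(w * wr$ratio) / sum(w)
  Q <- sum(w * (wr$ratio - theta)^2)
  df <- nrow(p) - 1L
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(Q = Q, df = df,
                 pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
                 i2 = i2),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran Q = %.4f (df = %d), p = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$pvalue, x$i2))
  invisible(x)
}

#' Directional-pleiotropy (Egger intercept) test
#'
#' @param x a [harmonized_set] with >= 3 pairs.
#' @return list of class `pleiotropy_result` with `intercept`, `se`,
#'   `pvalue` from [mr_egger()].
#' @export
pleiotropy_test <- function(x) {
  eg <- mr_egger(x)
  structure(eg$intercept, class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Egger intercept = %.4f (se %.4f), p = %.4f\n",
              x$estimate, x$se, x$pvalue))
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the causal effect with each instrument removed in turn
#' (fixed-effect IVW, matching the headline analysis), plus the all-SNP
#' row. Rows whose 95% CI no longer supports the full-set sign conclusion
#' are flagged as influential.
#'
#' @param x a [harmonized_set] with >= 3 pairs.
#' @param se_order Wald-ratio SE order.
#' @return data frame of class `leave_one_out` with columns `omitted_rsid`
#'   (`"All"` for the full set), `n_snp`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `influential`.
#' @export
leave_one_out <- function(x, se_order = "first") {
  .check_set(x, 3L, "leave_one_out")
  p <- x$pairs
  k <- nrow(p)
  one <- function(idx, label) {
    sub <- harmonized_set(p[idx, , drop = FALSE], x$exposure_label,
                          x$outcome_label)
    e <- mr_ivw(sub, model = "fixed", se_order = se_order)
    data.frame(omitted_rsid = label, n_snp = e$n_snp, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(k), function(j) one(setdiff(seq_len(k), j), p$rsid[j]))
  full <- one(seq_len(k), "All")
  out <- rbind(do.call(rbind, rows), full)
  # influential: omitting the SNP overturns the full-set significance call
  full_sig <- full$pvalue < 0.05
  row_sig <- out$pvalue < 0.05 & sign(out$beta) == sign(full$beta)
  out$influential <- if (full_sig) !row_sig else row_sig
  out$influential[out$omitted_rsid == "All"] <- FALSE
  rownames(out) <- NULL
  structure(out, class = c("leave_one_out", "data.frame"))
}

#' MR-PRESSO: global pleiotropy, outlier and distortion tests
#'
#' Residual-sum-of-squares framework for detecting horizontal pleiotropy.
#' The observed statistic is
#' `RSS_obs = sum_j w_j (beta_out_j - theta_(-j) * beta_exp_j)^2`, where
#' `theta_(-j)` is the fixed-effect IVW estimate computed without SNP j and
#' `w_j = 1 / se_out_j^2` (optionally augmented with the exposure-variance
#' term via `weight_exposure`). The global test compares `RSS_obs` with
#' `n_sim` parametric-bootstrap replicates in which
#' `beta_exp* ~ N(beta_exp, se_exp)` and
#' `beta_out* ~ N(theta_(-j) beta_exp, se_out)`, with the leave-one-out
#' expectations recomputed inside every replicate;
#' `global_p = (1 + #(RSS_sim >= RSS_obs)) / (1 + n_sim)`. The outlier test
#' compares each SNP's observed weighted squared residual with its own
#' simulated distribution, Bonferroni-adjusting by k; per-SNP p-values are
#' always reported, but outliers are called only when the global test
#' rejects at `outlier_sig` (the published construction runs the outlier
#' search conditional on a significant global test). The distortion test,
#' run only when outliers are found, compares the outlier-free IVW estimate
#' with estimates after removing equally many random SNPs.
#'
#' @param x a [harmonized_set] with >= 4 pairs.
#' @param n_sim parametric-bootstrap replicates (default 1000).
#' @param seed RNG seed (default 20230909).
#' @param outlier_sig significance level for Bonferroni-adjusted per-SNP
#'   p-values (default 0.05).
#' @param weight_exposure if `TRUE`, residual weights use
#'   `1 / (se_out^2 + theta_(-j)^2 se_exp^2)` instead of outcome variance
#'   only.
#' @return list of class `presso_result` with `rss_obs`, `global_pvalue`,
#'   `outlier_pvalues` (named, Bonferroni-adjusted), `outliers`,
#'   `distortion_pvalue` (`NA` when no outliers), `corrected_estimate`
#'   (an `mr_estimate`, `NULL` when no outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(x, n_sim = 1000, seed = 20230909, outlier_sig = 0.05,
                      weight_exposure = FALSE) {
  .check_set(x, 4L, "mr_presso")
  p <- x$pairs
  k <- nrow(p)
  loo_theta <- function(be, bo, se_out) {
    wiv <- be^2 / se_out^2
    r <- bo / be
    (sum(wiv * r) - wiv * r) / (sum(wiv) - wiv)
  }
  th_mj <- loo_theta(p$beta_exp, p$beta_out, p$se_out)
  w <- if (weight_exposure) {
    1 / (p$se_out^2 + th_mj^2 * p$se_exp^2)
  } else {
    1 / p$se_out^2
  }
  res_obs <- w * (p$beta_out - th_mj * p$beta_exp)^2
  rss_obs <- sum(res_obs)

  sim <- withr::with_seed(seed, {
    BE <- matrix(stats::rnorm(k * n_sim, p$beta_exp, p$se_exp), nrow = k)
    BO <- matrix(stats::rnorm(k * n_sim, th_mj * p$beta_exp, p$se_out), nrow = k)
    BE[BE == 0] <- .Machine$double.eps
    WIV <- BE^2 / p$se_out^2
    R <- BO / BE
    SWR <- colSums(WIV * R); SW <- colSums(WIV)
    TH <- (rep(SWR, each = k) - WIV * R) / (rep(SW, each = k) - WIV)
    W_SIM <- if (weight_exposure) 1 / (p$se_out^2 + TH^2 * p$se_exp^2) else w
    RES <- W_SIM * (BO - TH * BE)^2
    list(rss = colSums(RES), res = RES)
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  outlier_p_raw <- rowMeans(sim$res >= res_obs)
  outlier_p <- stats::setNames(pmin(1, outlier_p_raw * k), p$rsid)
  # per published construction, outliers are called only when the global
  # test itself detects pleiotropy
  outliers <- if (global_p < outlier_sig) p$rsid[outlier_p < outlier_sig] else
    character(0)

  distortion_p <- NA_real_
  corrected <- NULL
  if (length(outliers) && length(outliers) <= k - 2L) {
    keep <- !(p$rsid %in% outliers)
    sub <- harmonized_set(p[keep, , drop = FALSE], x$exposure_label,
                          x$outcome_label)
    corrected <- mr_ivw(sub, model = "fixed")
    full <- mr_ivw(x, model = "fixed")
    d_obs <- corrected$beta - full$beta
    n_out <- length(outliers)
    d_sim <- withr::with_seed(seed + 1, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(k, n_out)
        sub_b <- harmonized_set(p[-drop_idx, , drop = FALSE],
                                x$exposure_label, x$outcome_label)
        mr_ivw(sub_b, model = "fixed")$beta - full$beta
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_sim)
  }

  structure(list(rss_obs = rss_obs, global_pvalue = global_p,
                 outlier_pvalues = outlier_p, outliers = outliers,
                 distortion_pvalue = distortion_p,
                 corrected_estimate = corrected,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSSobs = %.4f, global p = %.4f (%d sims)\n",
              x$rss_obs, x$global_pvalue, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.4f\n", x$distortion_pvalue))
  } else {
    cat("  outliers: None\n")
  }
  invisible(x)
}
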