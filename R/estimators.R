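# Causal-effect estimators on harmonized summary statistics: Wald ratio,
# IVW, MR-Egger, weighted median, simple/weighted mode.
#
# Conventions (standard in the two-sample MR literature): IVW and weighted
# median use a normal reference for p-values; MR-Egger uses a t reference
# with k - 2 df; the mode estimators use t with k - 1 df. 95% CIs are
# beta +/- 1.959964 * se on the log-odds scale throughout.

Z95 <- 1.959964

#' Per-SNP Wald ratio
#'
#' `ratio = beta_out / beta_exp`. The first-order standard error
#' `se_out / |beta_exp|` ignores uncertainty in the SNP-exposure effect; the
#' second-order (delta-method) version adds it:
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE (vectorised).
#' @param beta_out,se_out SNP-outcome effect and SE (vectorised).
#' @param order `"first"` (default) or `"second"` order SE.
#' @return list with components `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       order = c("first", "second")) {
  order <- match.arg(order)
  if (any(beta_exp == 0)) {
    stop("wald_ratio: beta_exp must be nonzero", call. = FALSE)
  }
  ratio <- beta_out / beta_exp
  se <- if (order == "first") {
    se_out / abs(beta_exp)
  } else {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  list(ratio = ratio, se = se)
}

#' Log-odds estimate to odds-ratio scale
#'
#' @param beta log-odds causal estimate.
#' @param se standard error (> 0).
#' @param df degrees of freedom for the p-value reference distribution;
#'   `Inf` (default) gives the normal reference. The 95% CI always uses the
#'   normal quantile 1.959964.
#' @return list with `or`, `ci_low`, `ci_high`, `pvalue`.
#' @export
to_odds_ratio <- function(beta, se, df = Inf) {
  if (any(se <= 0)) stop("to_odds_ratio: se must be > 0", call. = FALSE)
  pvalue <- 2 * stats::pt(abs(beta) / se, df = df, lower.tail = FALSE)
  list(or = exp(beta),
       ci_low = exp(beta - Z95 * se),
       ci_high = exp(beta + Z95 * se),
       pvalue = pvalue)
}

.mr_estimate <- function(method, beta, se, n_snp, df = Inf, extra = NULL) {
  o <- to_odds_ratio(beta, se, df = df)
  structure(list(method = method, n_snp = n_snp,
                 beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pvalue = o$pvalue,
                 or = o$or, or_ci_low = o$ci_low, or_ci_high = o$ci_high,
                 extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): OR %.4f (95%% CI %.4f-%.4f), p = %.4g\n",
              x$method, x$n_snp, x$or, x$or_ci_low, x$or_ci_high, x$pvalue))
  invisible(x)
}

.check_set <- function(x, min_snp, caller) {
  stopifnot(inherits(x, "harmonized_set"))
  if (n_snps(x) < min_snp) {
    stop(sprintf("%s: requires at least %d instruments, got %d",
                 caller, min_snp, n_snps(x)), call. = FALSE)
  }
  invisible(x)
}

#' Single-instrument Wald estimate
#'
#' The causal estimate when only one instrument survives selection; IVW
#' with a single SNP reduces to this.
#'
#' @param x a [harmonized_set] with exactly >= 1 pair (the first is used if
#'   more are present).
#' @param se_order Wald-ratio SE order, `"first"` or `"second"`.
#' @return An `mr_estimate`.
#' @export
mr_wald <- function(x, se_order = "first") {
  .check_set(x, 1L, "mr_wald")
  p <- x$pairs[1L, ]
  w <- wald_ratio(p$beta_exp, p$se_exp, p$beta_out, p$se_out, order = se_order)
  .mr_estimate("Wald ratio", w$ratio, w$se, 1L)
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted average of the per-SNP Wald ratios,
#' `theta = sum(w r) / sum(w)` with `w = 1 / se(r)^2`. Under the fixed-effect
#' model `se(theta) = (sum w)^{-1/2}`; the multiplicative random-effects
#' model scales this by `max(1, sqrt(Q / (k - 1)))`, leaving the point
#' estimate unchanged. With first-order ratio SEs the estimator is
#' identical to weighted least squares of `beta_out` on `beta_exp` through
#' the origin with weights `1 / se_out^2`.
#'
#' @param x a [harmonized_set] with >= 2 pairs.
#' @param model `"fixed"` (default) or `"random"`.
#' @param se_order Wald-ratio SE order (default `"first"`).
#' @return An `mr_estimate`; `$extra` carries `Q` and the model used.
#' @export
mr_ivw <- function(x, model = c("fixed", "random"), se_order = "first") {
  model <- match.arg(model)
  .check_set(x, 2L, "mr_ivw")
  p <- x$pairs
  wr <- wald_ratio(p$beta_exp, p$se_exp, p$beta_out, p$se_out, order = se_order)
  w <- 1 / wr$se^2
  theta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  k <- nrow(p)
  Q <- sum(w * (wr$ratio - theta)^2)
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / (k - 1))) else se_fixed
  .mr_estimate(sprintf("IVW (%s)", model), theta, se, k,
               extra = list(Q = Q, model = model))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept and weights `1 / se_out^2`, after
#' orienting every pair so the exposure effect is nonnegative. The slope
#' estimates the causal effect under the InSIDE assumption; a nonzero
#' intercept indicates directional horizontal pleiotropy. Coefficient SEs
#' carry a multiplicative overdispersion factor bounded below at 1, and
#' p-values use a t reference with k - 2 df.
#'
#' @param x a [harmonized_set] with >= 3 pairs.
#' @return list of class `mr_egger` with components `slope` (an
#'   `mr_estimate`) and `intercept` (list with `estimate`, `se`, `pvalue`).
#' @export
mr_egger <- function(x) {
  .check_set(x, 3L, "mr_egger")
  p <- x$pairs
  k <- nrow(p)
  sgn <- ifelse(p$beta_exp < 0, -1, 1)
  bx <- sgn * p$beta_exp
  by <- sgn * p$beta_out
  w <- 1 / p$se_out^2
  if (stats::var(bx) == 0) {
    stop("mr_egger: zero variance in exposure effects (degenerate regressor)",
         call. = FALSE)
  }
  # closed-form weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (k - 2)
  infl <- max(1, sqrt(sigma2))
  se_slope <- infl * sqrt(sw / denom)
  se_int <- infl * sqrt(swxx / denom)
  p_int <- 2 * stats::pt(abs(intercept) / se_int, df = k - 2, lower.tail = FALSE)
  structure(list(
    slope = .mr_estimate("MR-Egger", slope, se_slope, k, df = k - 2,
                         extra = list(overdispersion = infl)),
    intercept = list(estimate = intercept, se = se_int, pvalue = p_int)
  ), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (se %.4f), p = %.4g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  S <- cumsum(w) - w / 2
  if (S[1L] >= 0.5) return(r[1L])
  below <- max(which(S < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1L] - r[below]) * (0.5 - S[below]) /
    (S[below + 1L] - S[below])
}

.boot_se <- function(x, n_boot, seed, point_fun, se_order = "first") {
  p <- x$pairs
  k <- nrow(p)
  withr::with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, p$beta_exp, p$se_exp)
      by <- stats::rnorm(k, p$beta_out, p$se_out)
      bx[bx == 0] <- .Machine$double.eps
      point_fun(by / bx, abs(bx) / p$se_out)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted / simple median estimator
#'
#' The causal estimate at which the weighted cumulative distribution of the
#' sorted per-SNP Wald ratios crosses 1/2 (linearly interpolated between
#' bracketing ratios). Consistent when instruments carrying at least half
#' of the weight are valid. The SE comes from a seeded parametric
#' bootstrap: SNP effects are redrawn from `N(beta, se)` and the median
#' recomputed.
#'
#' @param x a [harmonized_set] with >= 3 pairs.
#' @param weights `"ivw"` (default; proportional to the inverse ratio
#'   variance) or `"simple"` (uniform).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (default 20230909).
#' @param se_order Wald-ratio SE order for the weights.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(x, weights = c("ivw", "simple"),
                               n_boot = 1000, seed = 20230909,
                               se_order = "first") {
  weights <- match.arg(weights)
  .check_set(x, 3L, "mr_weighted_median")
  p <- x$pairs
  wr <- wald_ratio(p$beta_exp, p$se_exp, p$beta_out, p$se_out, order = se_order)
  w <- if (weights == "ivw") 1 / wr$se^2 else rep(1, nrow(p))
  theta <- .weighted_median_point(wr$ratio, w)
  point_fun <- if (weights == "ivw") {
    function(r, sqrt_w) .weighted_median_point(r, sqrt_w^2)
  } else {
    function(r, sqrt_w) .weighted_median_point(r, rep(1, length(r)))
  }
  se <- .boot_se(x, n_boot, seed, point_fun, se_order)
  method <- if (weights == "ivw") "Weighted median" else "Simple median"
  .mr_estimate(method, theta, se, nrow(p))
}

.mode_point <- function(r, w, phi, n_grid = 10000L) {
  k <- length(r)
  if (length(unique(r)) == 1L) return(r[1L])
  s_candidates <- c(stats::sd(r), stats::mad(r))
  s_candidates <- s_candidates[s_candidates > 0]
  h <- phi * 0.9 * min(s_candidates) * k^(-1 / 5)
  if (h == 0 || !is.finite(h)) return(r[which.max(w)])
  grid <- seq(min(r) - h, max(r) + h, length.out = n_grid)
  wn <- w / sum(w)
  dens <- colSums(wn * exp(-0.5 * (outer(r, grid, "-") / h)^2))
  grid[which.max(dens)]
}

#' Mode-based estimator (simple and weighted)
#'
#' The mode of a normal-kernel density of the per-SNP Wald ratios,
#' maximised over a fine grid (10,000 points for the point estimate; 512
#' for bootstrap replicates, where grid error is far below the bootstrap
#' SE). Bandwidth is `phi * 0.9 * min(sd, MAD) * k^(-1/5)` with the
#' MAD on the consistent (1.4826-scaled) scale. Consistent when the largest
#' cluster of instruments is valid. Weighted mode weights the kernel by the
#' inverse ratio variance; simple mode weights uniformly. SE by seeded
#' parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param weighted logical; weighted (default) or simple mode.
#' @param phi bandwidth inflation factor (default 1).
#' @return An `mr_estimate` (p-value on a t reference with k - 1 df).
#' @export
mr_mode <- function(x, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = 20230909, se_order = "first") {
  .check_set(x, 3L, "mr_mode")
  p <- x$pairs
  k <- nrow(p)
  wr <- wald_ratio(p$beta_exp, p$se_exp, p$beta_out, p$se_out, order = se_order)
  w <- if (weighted) 1 / wr$se^2 else rep(1, k)
  theta <- .mode_point(wr$ratio, w, phi)
  point_fun <- if (weighted) {
    function(r, sqrt_w) .mode_point(r, sqrt_w^2, phi, n_grid = 512L)
  } else {
    function(r, sqrt_w) .mode_point(r, rep(1, length(r)), phi, n_grid = 512L)
  }
  se <- .boot_se(x, n_boot, seed, point_fun, se_order)
  method <- if (weighted) "Weighted mode" else "Simple mode"
  .mr_estimate(method, theta, se, k, df = k - 1)
}

#' Run the five standard MR estimators
#'
#' IVW (fixed or random effects chosen by the caller), MR-Egger, weighted
#' median, simple mode and weighted mode on one harmonized set, returned as
#' a tidy results table. With exactly one valid pair the single-SNP Wald
#' fallback is returned alone.
#'
#' @param x a [harmonized_set].
#' @param ivw_model `"fixed"` (default) or `"random"`.
#' @param n_boot,seed,phi bootstrap count, RNG seed, mode bandwidth factor.
#' @param se_order Wald-ratio SE order.
#' @return data frame of class `mr_result_set`, one row per method, with
#'   columns `exposure`, `outcome`, `method`, `n_snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `or`, `or_ci_low`, `or_ci_high`.
#'   Attribute `"egger_intercept"` carries the pleiotropy intercept test.
#' @export
mr_all <- function(x, ivw_model = "fixed", n_boot = 1000, seed = 20230909,
                   phi = 1, se_order = "first") {
  .check_set(x, 1L, "mr_all")
  k <- n_snps(x)
  ests <- list()
  egger_int <- NULL
  if (k == 1L) {
    ests <- list(mr_wald(x, se_order))
  } else {
    ests <- list(mr_ivw(x, model = ivw_model, se_order = se_order))
    if (k >= 3L) {
      eg <- mr_egger(x)
      egger_int <- eg$intercept
      ests <- c(ests, list(
        eg$slope,
        mr_weighted_median(x, "ivw", n_boot = n_boot, seed = seed,
                           se_order = se_order),
        mr_mode(x, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed,
                se_order = se_order),
        mr_mode(x, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed,
                se_order = se_order)))
    }
  }
  out <- do.call(rbind, lapply(ests, function(e) {
    data.frame(exposure = x$exposure_label, outcome = x$outcome_label,
               method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               or = e$or, or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, egger_intercept = egger_int,
            class = c("mr_result_set", "data.frame"))
}
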