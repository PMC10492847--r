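# Synthetic GWAS summary-statistics generator with known ground truth.
#
# Emulates, at the summary level, the statistical structure a two-sample MR
# analysis assumes: per-SNP exposure effects strong enough to pass the
# significance filter, SEs scaled by sample size and allele frequency via
# se(beta) ~ 1 / sqrt(2 N MAF (1 - MAF)) on a unit-variance trait scale,
# optional pleiotropic (invalid) instruments, LD blocks of correlated
# satellites, palindromic variants with near-0.5 frequencies, background
# null SNPs, and a planted confounder-trait catalogue.

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulation configuration
#'
#' Parameters of a simulated two-sample MR study. Defaults mirror the shape
#' of a well-powered exposure GWAS feeding a large outcome GWAS.
#'
#' @param k number of independent instrument SNPs (>= 1).
#' @param theta true causal effect (log-odds of outcome per unit exposure).
#' @param n_exp,n_out exposure and outcome sample sizes (effective sizes;
#'   case/control imbalance is not modelled separately).
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param gamma_sd SD of true SNP-exposure effects (unit-SD trait scale).
#' @param prop_invalid fraction of instruments with horizontal pleiotropy.
#' @param mu_alpha,sd_alpha mean and SD of pleiotropic effects; nonzero
#'   `mu_alpha` gives directional pleiotropy.
#' @param n_null_snps background SNPs with no exposure effect.
#' @param ld_block_spec list of `list(size =, r2 =)` blocks; block b hangs
#'   `size - 1` correlated satellite SNPs off instrument b.
#' @param palindrome_fraction fraction of instruments assigned A/T or C/G
#'   alleles with effect-allele frequency drawn in (0.45, 0.55).
#' @param confounder_spec optional data frame `(rsid, trait, pvalue)` of
#'   planted confounder-trait associations (rsids follow the deterministic
#'   naming scheme, see [simulate_study()]).
#' @param p_sig significance threshold instruments are guaranteed to pass
#'   (default `5e-8`).
#' @param seed default RNG seed for [simulate_study()].
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(k = 44, theta = 0, n_exp = 86640,
                              n_out = 212334, maf_range = c(0.05, 0.5),
                              gamma_sd = 0.08, prop_invalid = 0,
                              mu_alpha = 0, sd_alpha = 0,
                              n_null_snps = 200, ld_block_spec = list(),
                              palindrome_fraction = 0,
                              confounder_spec = NULL, p_sig = 5e-8,
                              seed = 20230909) {
  stopifnot(k >= 1, n_exp > k + 1, n_out > 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            prop_invalid >= 0, prop_invalid <= 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            gamma_sd > 0, sd_alpha >= 0, p_sig > 0, p_sig < 1,
            length(ld_block_spec) <= k)
  structure(list(k = k, theta = theta, n_exp = n_exp, n_out = n_out,
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 prop_invalid = prop_invalid, mu_alpha = mu_alpha,
                 sd_alpha = sd_alpha, n_null_snps = n_null_snps,
                 ld_block_spec = ld_block_spec,
                 palindrome_fraction = palindrome_fraction,
                 confounder_spec = confounder_spec, p_sig = p_sig,
                 seed = seed),
            class = "sim_config")
}

.analytic_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Draw observed beta = truth + noise, resampling (optionally the truth too)
# until the observed Wald p-value passes p_sig. Bounded at max_rounds.
.sample_significant <- function(k, truth_mean, truth_sd, se, p_sig,
                                resample_truth, max_rounds = 1000L) {
  truth <- if (resample_truth) stats::rnorm(k, truth_mean, truth_sd) else
    rep_len(truth_mean, k)
  obs <- truth + stats::rnorm(k, 0, se)
  z_crit <- stats::qnorm(p_sig / 2, lower.tail = FALSE)
  for (round in seq_len(max_rounds)) {
    fail <- which(abs(obs / se) <= z_crit)
    if (!length(fail)) return(list(truth = truth, obs = obs))
    if (resample_truth) {
      truth[fail] <- stats::rnorm(length(fail), truth_mean, truth_sd)
    }
    obs[fail] <- truth[fail] + stats::rnorm(length(fail), 0, se[fail])
  }
  stop("simulate_study: significance unreachable for some instruments; ",
       "increase gamma_sd or n_exp (feasibility error)", call. = FALSE)
}

#' Simulate a two-sample MR study with known truth
#'
#' Generates exposure and outcome [sumstats] tables, an [ld_reference], a
#' [trait_catalog] and a ground-truth table, fully reproducibly given the
#' seed. Instrument j carries a true exposure effect `gamma_j ~
#' N(0, gamma_sd)`; the pair (effect, sampling noise) is redrawn until the
#' observed exposure association passes `p_sig`, so the relevance assumption
#' holds by construction and the significance filter keeps exactly the
#' planted instruments. Invalid instruments add a pleiotropic effect
#' `alpha_j ~ N(mu_alpha, sd_alpha)` to the outcome; the true outcome effect
#' is `theta * gamma_j + alpha_j`. LD-block satellites replicate their index
#' instrument's signal and are entered in the LD reference with the block's
#' within-r2 (so clumping removes exactly `size - 1` per block). Instruments
#' sit >= 25 Mb apart (outside any clumping window); satellites sit within
#' 1 Mb of their index. Outcome rows have their allele orientation randomly
#' swapped to exercise harmonization.
#'
#' Deterministic rsid scheme: instrument j is `rs<100000 + j>`, satellite i
#' of block b is `rs<200000 + 100 b + i>`, null SNP j is `rs<900000 + j>`.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list of class `simulated_study` with `exposure_table`,
#'   `outcome_table`, `ld`, `catalog`, `truth` (data frame: `rsid`, `role`,
#'   `gamma`, `alpha`, `invalid`, `block`, `palindromic`) and `config`.
#' @export
simulate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cf) {
  k <- cf$k
  rsid_inst <- sprintf("rs%d", 100000L + seq_len(k))
  chrom <- as.character((seq_len(k) - 1L) %% 22L + 1L)
  pos <- 1000000L + ((seq_len(k) - 1L) %/% 22L) * 25000000L

  # palindromes go on the last instruments, LD blocks hang off the first,
  # so the two planted features cannot collide in small studies
  n_pal <- round(cf$palindrome_fraction * k)
  pal <- c(rep(FALSE, k - n_pal), rep(TRUE, n_pal))

  eaf <- numeric(k)
  ea <- character(k); oa <- character(k)
  if (n_pal) {
    eaf[pal] <- stats::runif(n_pal, 0.45, 0.55)
    pp <- sample(c("AT", "CG"), n_pal, replace = TRUE)
    ea[pal] <- substr(pp, 1, 1); oa[pal] <- substr(pp, 2, 2)
  }
  n_np <- k - n_pal
  if (n_np) {
    maf <- stats::runif(n_np, cf$maf_range[1], cf$maf_range[2])
    flip <- stats::runif(n_np) < 0.5
    eaf[!pal] <- ifelse(flip, 1 - maf, maf)
    pr <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS), n_np,
                                           replace = TRUE), , drop = FALSE]
    ea[!pal] <- pr[, 1]; oa[!pal] <- pr[, 2]
  }
  maf_all <- pmin(eaf, 1 - eaf)
  se_exp <- .analytic_se(cf$n_exp, maf_all)
  se_out <- .analytic_se(cf$n_out, maf_all)

  drawn <- .sample_significant(k, 0, cf$gamma_sd, se_exp, cf$p_sig,
                               resample_truth = TRUE)
  # code effect alleles as exposure-increasing (gamma >= 0): the convention
  # under which mu_alpha != 0 is directional pleiotropy detectable by the
  # Egger intercept; flipping truth and observation together preserves the
  # conditional error distribution
  sgn <- ifelse(drawn$truth < 0, -1, 1)
  gamma <- sgn * drawn$truth
  beta_exp_obs <- sgn * drawn$obs

  n_invalid <- round(cf$prop_invalid * k)
  invalid <- c(rep(TRUE, n_invalid), rep(FALSE, k - n_invalid))
  invalid <- sample(invalid)
  alpha <- ifelse(invalid, stats::rnorm(k, cf$mu_alpha, cf$sd_alpha), 0)
  beta_out_true <- cf$theta * gamma + alpha
  beta_out_obs <- beta_out_true + stats::rnorm(k, 0, se_out)

  inst_exp <- data.frame(rsid = rsid_inst, chrom = chrom, pos = pos,
                         effect_allele = ea, other_allele = oa, eaf = eaf,
                         beta = beta_exp_obs, se = se_exp,
                         pvalue = pmax(2 * stats::pnorm(-abs(beta_exp_obs / se_exp)), .Machine$double.xmin),
                         n = cf$n_exp, stringsAsFactors = FALSE)
  role <- rep("instrument", k)
  truth <- data.frame(rsid = rsid_inst, role = role, gamma = gamma,
                      alpha = alpha, invalid = invalid, block = NA_integer_,
                      palindromic = pal, stringsAsFactors = FALSE)
  out_rows <- data.frame(rsid = rsid_inst, chrom = chrom, pos = pos,
                         effect_allele = ea, other_allele = oa, eaf = eaf,
                         beta = beta_out_obs, se = se_out,
                         pvalue = pmax(2 * stats::pnorm(-abs(beta_out_obs / se_out)), .Machine$double.xmin),
                         n = cf$n_out, stringsAsFactors = FALSE)
  ld_pairs <- list()

  # LD-block satellites replicating index-instrument signals
  if (length(cf$ld_block_spec)) {
    for (b in seq_along(cf$ld_block_spec)) {
      blk <- cf$ld_block_spec[[b]]
      size <- blk$size; r2 <- blk$r2
      stopifnot(size >= 2, r2 >= 0, r2 <= 1)
      n_sat <- size - 1L
      sid <- sprintf("rs%d", 200000L + 100L * b + seq_len(n_sat))
      s_maf <- rep(maf_all[b], n_sat)
      s_se_exp <- .analytic_se(cf$n_exp, s_maf)
      s_se_out <- .analytic_se(cf$n_out, s_maf)
      s_drawn <- .sample_significant(n_sat, gamma[b], 0, s_se_exp, cf$p_sig,
                                     resample_truth = FALSE)
      s_bx <- s_drawn$obs
      s_by <- beta_out_true[b] + stats::rnorm(n_sat, 0, s_se_out)
      s_pos <- pos[b] + seq_len(n_sat) * 50000L
      s_pr <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS),
                                               n_sat, replace = TRUE), ,
                                    drop = FALSE]
      inst_exp <- rbind(inst_exp, data.frame(
        rsid = sid, chrom = chrom[b], pos = s_pos,
        effect_allele = s_pr[, 1], other_allele = s_pr[, 2],
        eaf = eaf[b], beta = s_bx, se = s_se_exp,
        pvalue = pmax(2 * stats::pnorm(-abs(s_bx / s_se_exp)), .Machine$double.xmin),
        n = cf$n_exp, stringsAsFactors = FALSE))
      out_rows <- rbind(out_rows, data.frame(
        rsid = sid, chrom = chrom[b], pos = s_pos,
        effect_allele = s_pr[, 1], other_allele = s_pr[, 2],
        eaf = eaf[b], beta = s_by, se = s_se_out,
        pvalue = pmax(2 * stats::pnorm(-abs(s_by / s_se_out)), .Machine$double.xmin),
        n = cf$n_out, stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        rsid = sid, role = "satellite", gamma = gamma[b], alpha = alpha[b],
        invalid = invalid[b], block = b, palindromic = FALSE,
        stringsAsFactors = FALSE))
      members <- c(rsid_inst[b], sid)
      cmb <- utils::combn(members, 2L)
      ld_pairs[[length(ld_pairs) + 1L]] <- data.frame(
        rsid_a = cmb[1, ], rsid_b = cmb[2, ], r2 = r2,
        stringsAsFactors = FALSE)
    }
  }

  # Background null SNPs (no exposure effect)
  if (cf$n_null_snps > 0) {
    nn <- cf$n_null_snps
    nid <- sprintf("rs%d", 900000L + seq_len(nn))
    n_chrom <- as.character(sample.int(22L, nn, replace = TRUE))
    n_pos <- sample.int(250000000L, nn, replace = TRUE)
    n_maf <- stats::runif(nn, cf$maf_range[1], cf$maf_range[2])
    n_se_exp <- .analytic_se(cf$n_exp, n_maf)
    n_se_out <- .analytic_se(cf$n_out, n_maf)
    n_bx <- stats::rnorm(nn, 0, n_se_exp)
    n_by <- stats::rnorm(nn, 0, n_se_out)
    n_pr <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS), nn,
                                             replace = TRUE), , drop = FALSE]
    inst_exp <- rbind(inst_exp, data.frame(
      rsid = nid, chrom = n_chrom, pos = n_pos,
      effect_allele = n_pr[, 1], other_allele = n_pr[, 2],
      eaf = n_maf, beta = n_bx, se = n_se_exp,
      pvalue = pmax(2 * stats::pnorm(-abs(n_bx / n_se_exp)), .Machine$double.xmin),
      n = cf$n_exp, stringsAsFactors = FALSE))
    out_rows <- rbind(out_rows, data.frame(
      rsid = nid, chrom = n_chrom, pos = n_pos,
      effect_allele = n_pr[, 1], other_allele = n_pr[, 2],
      eaf = n_maf, beta = n_by, se = n_se_out,
      pvalue = pmax(2 * stats::pnorm(-abs(n_by / n_se_out)), .Machine$double.xmin),
      n = cf$n_out, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      rsid = nid, role = "null", gamma = 0, alpha = 0, invalid = FALSE,
      block = NA_integer_, palindromic = FALSE, stringsAsFactors = FALSE))
  }

  # Randomly swap outcome allele orientation (harmonization must undo it)
  swap <- stats::runif(nrow(out_rows)) < 0.5
  tmp <- out_rows$effect_allele[swap]
  out_rows$effect_allele[swap] <- out_rows$other_allele[swap]
  out_rows$other_allele[swap] <- tmp
  out_rows$beta[swap] <- -out_rows$beta[swap]
  out_rows$eaf[swap] <- 1 - out_rows$eaf[swap]

  ld <- ld_reference(
    if (length(ld_pairs)) do.call(rbind, ld_pairs) else NULL,
    inst_exp[c("rsid", "chrom", "pos")])
  catalog <- trait_catalog(cf$confounder_spec)

  structure(list(
    exposure_table = sumstats(inst_exp, "sim_exposure", source = "simulated"),
    outcome_table = sumstats(out_rows, "sim_outcome", source = "simulated"),
    ld = ld, catalog = catalog, truth = truth, config = cf),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("Simulated MR study: k = %d instruments ",
                     "(theta = %.4g), %d exposure rows, %d outcome rows\n"),
              x$config$k, x$config$theta, nrow(x$exposure_table),
              nrow(x$outcome_table)))
  invisible(x)
}

#' Study-shaped simulation scenarios
#'
#' Configurations mirroring the two directions of the IBD-rosacea case
#' study: forward (IBD as exposure) with 44 instruments at genome-wide
#' significance 5e-8, exposure N 86,640, outcome N 212,334 and a true
#' effect of log(1.1291); reverse (rosacea as exposure) with 12 instruments
#' at the relaxed 5e-6 threshold, exposure N 212,334, outcome N 86,640 and
#' no true effect, with small SNP-exposure effects (weak-instrument
#' regime).
#'
#' @param direction `"forward"` or `"reverse"`.
#' @param ... overrides passed on to [simulation_config()].
#' @return A [simulation_config()].
#' @export
make_case_study_scenario <- function(direction = c("forward", "reverse"),
                                       ...) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    defaults <- list(k = 44, theta = log(1.1291), n_exp = 86640,
                     n_out = 212334, gamma_sd = 0.08, p_sig = 5e-8)
  } else {
    defaults <- list(k = 12, theta = 0, n_exp = 212334, n_out = 86640,
                     gamma_sd = 0.02, p_sig = 5e-6)
  }
  overrides <- list(...)
  do.call(simulation_config, utils::modifyList(defaults, overrides))
}
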