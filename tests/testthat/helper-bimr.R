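# Shared fixtures, built in code.

# Three-pair toy set with hand-computable IVW: ratios (0.2, 0.1, 0.1),
# first-order weights (100, 400, 100) -> theta 7/60, se 1/sqrt(600).
toy_harmonized <- function() {
  harmonized_set(
    data.frame(rsid = c("rs1", "rs2", "rs3"),
               beta_exp = c(0.1, 0.2, 0.1), se_exp = 0.01,
               beta_out = c(0.02, 0.02, 0.01), se_out = 0.01,
               stringsAsFactors = FALSE),
    "X", "Y")
}

random_harmonized <- function(k, seed, theta = 0.1) {
  withr::with_seed(seed, {
    beta_exp <- rnorm(k, 0, 0.1)
    beta_exp[abs(beta_exp) < 0.02] <- 0.02
    se_exp <- runif(k, 0.005, 0.02)
    se_out <- runif(k, 0.005, 0.02)
    beta_out <- theta * beta_exp + rnorm(k, 0, se_out)
    harmonized_set(
      data.frame(rsid = sprintf("rs%d", seq_len(k)),
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out,
                 stringsAsFactors = FALSE),
      "X", "Y")
  })
}

# Minimal well-formed summary-statistics data frame.
snp_df <- function(rsid = c("rs1", "rs2", "rs3"),
                   chrom = "1",
                   pos = c(1e6, 2e6, 3e6),
                   effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta = c(0.1, -0.2, 0.05),
                   se = 0.01, pvalue = c(1e-10, 1e-9, 1e-8),
                   n = 1000) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}

# Independent weighted-least-squares oracles via stats::lm.
wls_origin_slope <- function(h) {
  p <- h$pairs
  unname(coef(lm(beta_out ~ 0 + beta_exp, data = p,
                 weights = 1 / p$se_out^2)))
}

wls_egger_oracle <- function(h) {
  p <- h$pairs
  sgn <- ifelse(p$beta_exp < 0, -1, 1)
  d <- data.frame(bx = sgn * p$beta_exp, by = sgn * p$beta_out)
  fit <- lm(by ~ bx, data = d, weights = 1 / p$se_out^2)
  sm <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_unscaled = unname(sm$coefficients[, "Std. Error"]) / sm$sigma,
       sigma = sm$sigma)
}

# Bidirectional fixture: three exposure studies plus one reverse study on a
# shared rsid universe (rsids re-prefixed per study so panels concatenate).
# Effects are null throughout so the shared outcome table carries no signal
# that could double as a reverse-causation instrument.
make_bidirectional_fixture <- function(seed) {
  rename <- function(s, prefix) {
    fix <- function(v) sub("^rs", paste0("rs", prefix), v)
    s$exposure_table$rsid <- fix(s$exposure_table$rsid)
    s$outcome_table$rsid <- fix(s$outcome_table$rsid)
    s$ld$positions$rsid <- fix(s$ld$positions$rsid)
    s
  }
  fwd <- lapply(1:3, function(i) {
    rename(simulate_study(simulation_config(k = 5, theta = 0, n_null_snps = 5,
                                            seed = seed + i)), i)
  })
  rev <- rename(simulate_study(simulation_config(k = 4, theta = 0,
                                                 n_null_snps = 5,
                                                 p_sig = 5e-6,
                                                 seed = seed + 9)), 9)
  labels <- c("IBD", "UC", "CD")
  exposures <- list()
  for (i in 1:3) {
    exposures[[labels[i]]] <- sumstats(
      rbind(as.data.frame(fwd[[i]]$exposure_table),
            as.data.frame(rev$outcome_table)), labels[i])
  }
  outcome <- sumstats(
    do.call(rbind, c(list(as.data.frame(rev$exposure_table)),
                     lapply(fwd, function(s) as.data.frame(s$outcome_table)))),
    "Rosacea")
  all_pos <- unique(do.call(rbind, c(lapply(fwd, function(s) s$ld$positions),
                                     list(rev$ld$positions))))
  list(exposures = exposures, outcome = outcome,
       ld = ld_reference(NULL, all_pos))
}
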