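# Allele harmonization and palindromic-SNP handling.

make_pair_tables <- function(exp_alleles, out_alleles, beta_out = 0.05,
                             eaf_exp = 0.3, eaf_out = 0.3) {
  exposure <- sumstats(snp_df(rsid = "rs1", pos = 1e6,
                              effect_allele = exp_alleles[1],
                              other_allele = exp_alleles[2],
                              eaf = eaf_exp, beta = 0.1, pvalue = 1e-10),
                       "X")
  outcome <- sumstats(snp_df(rsid = "rs1", pos = 1e6,
                             effect_allele = out_alleles[1],
                             other_allele = out_alleles[2],
                             eaf = eaf_out, beta = beta_out, pvalue = 0.5),
                      "Y")
  list(exposure = exposure, outcome = outcome)
}

test_that("palindromic pairs are exactly A/T and C/G", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("g", "c"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_equal(is_palindromic(c("A", "A"), c("T", "C")), c(TRUE, FALSE))
})

test_that("swapped outcome alleles flip the outcome effect and frequency", {
  tt <- make_pair_tables(c("A", "G"), c("G", "A"), beta_out = 0.05,
                         eaf_out = 0.7)
  h <- harmonize(tt$exposure, tt$outcome)
  expect_equal(n_snps(h), 1L)
  expect_equal(h$pairs$beta_out, -0.05)
  expect_equal(h$pairs$eaf_out, 0.3)
  expect_true(h$pairs$flipped)

  # same orientation: untouched
  tt2 <- make_pair_tables(c("A", "G"), c("A", "G"))
  h2 <- harmonize(tt2$exposure, tt2$outcome)
  expect_equal(h2$pairs$beta_out, 0.05)
  expect_false(h2$pairs$flipped)
})

test_that("missing and incompatible outcome records are excluded with reasons", {
  exposure <- sumstats(snp_df(), "X")
  outcome <- sumstats(snp_df(rsid = c("rs1", "rs2"),
                             pos = c(1e6, 2e6),
                             effect_allele = c("A", "C"),
                             other_allele = c("G", "T"),
                             beta = 0.05, pvalue = 0.5), "Y")
  h <- harmonize(exposure, outcome)
  expect_equal(n_snps(h), 1L)  # rs1 matches; rs2 incompatible; rs3 missing
  reasons <- setNames(h$exclusions$reason, h$exclusions$rsid)
  expect_equal(unname(reasons["rs2"]), "incompatible_alleles")
  expect_equal(unname(reasons["rs3"]), "missing_in_outcome")
  expect_equal(n_snps(h) + nrow(h$exclusions), 3L)
})

test_that("palindromic SNPs follow the intermediate-frequency rule", {
  # eaf 0.50 is intermediate -> excluded under drop_intermediate
  tt <- make_pair_tables(c("A", "T"), c("A", "T"), eaf_exp = 0.5,
                         eaf_out = 0.5)
  h <- harmonize(tt$exposure, tt$outcome)
  expect_equal(h$exclusions$reason, "palindromic_intermediate")

  # clearly minor in both studies -> kept, same orientation
  tt2 <- make_pair_tables(c("A", "T"), c("A", "T"), eaf_exp = 0.1,
                          eaf_out = 0.12)
  h2 <- harmonize(tt2$exposure, tt2$outcome)
  expect_equal(n_snps(h2), 1L)
  expect_false(h2$pairs$flipped)

  # minor in one study, major in the other -> orientation flipped
  tt3 <- make_pair_tables(c("A", "T"), c("A", "T"), beta_out = 0.05,
                          eaf_exp = 0.1, eaf_out = 0.9)
  h3 <- harmonize(tt3$exposure, tt3$outcome)
  expect_equal(h3$pairs$beta_out, -0.05)
  expect_equal(h3$pairs$eaf_out, 0.1, tolerance = 1e-12)
  expect_true(h3$pairs$flipped)

  # drop_all mode excludes every palindrome regardless of frequency
  h4 <- harmonize(tt2$exposure, tt2$outcome, mode = "drop_all")
  expect_equal(h4$exclusions$reason, "palindromic_all_mode")

  # missing outcome EAF: orientation unverifiable -> dropped
  out_na <- tt2$outcome
  out_na$eaf <- NA_real_
  attr(out_na, "trait_label") <- "Y"
  h5 <- harmonize(tt2$exposure, out_na)
  expect_equal(h5$exclusions$reason, "palindromic_intermediate")
})

test_that("harmonization is idempotent on aligned data", {
  s <- simulate_study(simulation_config(k = 10, n_null_snps = 0, seed = 21))
  h1 <- harmonize(s$exposure_table, s$outcome_table)
  # rebuild an outcome table already aligned to the exposure orientation
  aligned <- as.data.frame(s$outcome_table)
  idx <- match(h1$pairs$rsid, aligned$rsid)
  aligned$beta[idx] <- h1$pairs$beta_out
  aligned$eaf[idx] <- h1$pairs$eaf_out
  exp_idx <- match(h1$pairs$rsid, s$exposure_table$rsid)
  aligned$effect_allele[idx] <- s$exposure_table$effect_allele[exp_idx]
  aligned$other_allele[idx] <- s$exposure_table$other_allele[exp_idx]
  h2 <- harmonize(s$exposure_table, sumstats(aligned, "sim_outcome"))
  expect_equal(h2$pairs$beta_out, h1$pairs$beta_out)
  expect_false(any(h2$pairs$flipped[!h2$pairs$palindromic]))
})

test_that("joint allele-orientation flips leave effect products invariant", {
  s <- simulate_study(simulation_config(k = 12, n_null_snps = 0, seed = 22))
  h1 <- harmonize(s$exposure_table, s$outcome_table)

  flip_table <- function(tab, rows) {
    d <- as.data.frame(tab)
    tmp <- d$effect_allele[rows]
    d$effect_allele[rows] <- d$other_allele[rows]
    d$other_allele[rows] <- tmp
    d$beta[rows] <- -d$beta[rows]
    d$eaf[rows] <- 1 - d$eaf[rows]
    sumstats(d, trait_label(tab))
  }
  rows_e <- seq(1, nrow(s$exposure_table), by = 2)
  exp_f <- flip_table(s$exposure_table, rows_e)
  out_f <- flip_table(s$outcome_table, match(exp_f$rsid[rows_e],
                                             s$outcome_table$rsid))
  h2 <- harmonize(exp_f, out_f)
  common <- intersect(h1$pairs$rsid, h2$pairs$rsid)
  p1 <- h1$pairs[match(common, h1$pairs$rsid), ]
  p2 <- h2$pairs[match(common, h2$pairs$rsid), ]
  expect_equal(p1$beta_exp * p1$beta_out, p2$beta_exp * p2$beta_out,
               tolerance = 1e-12)
})

test_that("harmonized sets round-trip through the TSV export", {
  h <- random_harmonized(20, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- read_harmonized(path, "X", "Y")
  expect_equal(back$pairs$beta_exp, h$pairs$beta_exp, tolerance = 1e-12)
  expect_equal(back$pairs$beta_out, h$pairs$beta_out, tolerance = 1e-12)
  expect_identical(back$pairs$rsid, h$pairs$rsid)
})
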