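# Instrument selection and strength metrics.

test_that("significance filter keeps exactly the sub-threshold records", {
  tab <- sumstats(snp_df(pvalue = c(1e-9, 1e-7, 5e-8)), "X")
  kept <- select_significant(tab, 5e-8)
  expect_equal(kept$rsid, "rs1")  # strict inequality: 5e-8 itself is out
  log <- attr(kept, "step_log")
  expect_equal(log$n_in, 3L)
  expect_equal(log$n_out + nrow(log$dropped), log$n_in)

  all_kept <- select_significant(tab, 1)
  expect_equal(nrow(all_kept), 3L)
  expect_equal(all_kept$pvalue, sort(tab$pvalue))  # ascending-p order
})

test_that("significance filter agrees with a brute-force scan on 1000 SNPs", {
  s <- simulate_study(simulation_config(k = 5, n_null_snps = 995, seed = 11))
  tab <- s$exposure_table
  kept <- select_significant(tab, 5e-8)
  expect_setequal(kept$rsid, tab$rsid[tab$pvalue < 5e-8])
})

test_that("greedy clumping matches the hand-traced example", {
  # 3 SNPs within one window; r2(1,2) = 0.5 prunes SNP 2, r2(1,3) = 0.0005
  # is below the 0.001 threshold so SNP 3 survives
  tab <- sumstats(snp_df(pvalue = c(1e-10, 1e-9, 1e-8),
                         pos = c(1e6, 2e6, 3e6)), "X")
  ld <- ld_reference(
    data.frame(rsid_a = c("rs1", "rs1"), rsid_b = c("rs2", "rs3"),
               r2 = c(0.5, 0.0005)),
    tab[c("rsid", "chrom", "pos")])
  out <- ld_clump(tab, ld)
  expect_setequal(out$rsid, c("rs1", "rs3"))
  dropped <- attr(out, "step_log")$dropped
  expect_equal(dropped$rsid, "rs2")
  expect_equal(dropped$detail, "clumped_by=rs1")
})

test_that("clumping respects the distance window and the no-LD identity", {
  # 20,001 kb apart: outside the 10,000 kb window, so high r2 is irrelevant
  tab <- sumstats(snp_df(rsid = c("rs1", "rs2"), pos = c(1e6, 1e6 + 20001e3),
                         pvalue = c(1e-10, 1e-9), beta = 0.1), "X")
  ld <- ld_reference(data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.9),
                     tab[c("rsid", "chrom", "pos")])
  expect_equal(nrow(ld_clump(tab, ld)), 2L)

  # all pairwise r2 = 0 -> identity
  tab2 <- sumstats(snp_df(), "X")
  ld0 <- ld_reference(NULL, tab2[c("rsid", "chrom", "pos")])
  expect_setequal(ld_clump(tab2, ld0)$rsid, tab2$rsid)
})

test_that("clumping is order-invariant and output is LD-independent", {
  s <- simulate_study(simulation_config(
    k = 8, n_null_snps = 0, seed = 3,
    ld_block_spec = list(list(size = 3, r2 = 0.4), list(size = 2, r2 = 0.9))))
  tab <- s$exposure_table
  out1 <- ld_clump(tab, s$ld)
  shuffled <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  out2 <- ld_clump(shuffled, s$ld)
  expect_identical(out1$rsid, out2$rsid)

  # exhaustive post-check: no kept pair within window with r2 > threshold
  pos <- ld_positions(s$ld, out1$rsid)
  for (i in seq_len(nrow(out1) - 1)) {
    for (j in seq(i + 1, nrow(out1))) {
      close_by <- pos$chrom[i] == pos$chrom[j] &&
        abs(pos$pos[i] - pos$pos[j]) <= 1e7
      if (close_by) expect_lte(ld_r2(s$ld, out1$rsid[i], out1$rsid[j]), 0.001)
    }
  }
})

test_that("confounder screen applies the direct and proxy rules", {
  tab <- sumstats(snp_df(), "X")

  # empty catalogue -> identity
  out <- screen_confounders(tab, trait_catalog(), "smoking")
  expect_equal(nrow(out), 3L)

  # direct hit on a listed trait below threshold -> removed
  cat1 <- trait_catalog(data.frame(rsid = "rs1", trait = "smoking",
                                   pvalue = 1e-9))
  out1 <- screen_confounders(tab, cat1, "smoking")
  expect_false("rs1" %in% out1$rsid)
  expect_equal(attr(out1, "step_log")$dropped$detail, "smoking")

  # hit on an unlisted trait, or above threshold -> kept
  expect_equal(nrow(screen_confounders(tab, cat1, "obesity")), 3L)
  cat_weak <- trait_catalog(data.frame(rsid = "rs1", trait = "smoking",
                                       pvalue = 1e-6))
  expect_equal(nrow(screen_confounders(tab, cat_weak, "smoking")), 3L)

  # proxy rule-table: removed only when proxy r2 exceeds the threshold
  for (case in list(list(r2 = 0.85, kept = FALSE), list(r2 = 0.75, kept = TRUE))) {
    cat_p <- trait_catalog(
      data.frame(rsid = "rsP", trait = "smoking", pvalue = 1e-10),
      proxies = data.frame(rsid = "rs2", proxy_rsid = "rsP", r2 = case$r2))
    res <- screen_confounders(tab, cat_p, "smoking")
    expect_equal("rs2" %in% res$rsid, case$kept)
  }
})

test_that("variance_explained folds MAF and scales by trait SD", {
  expect_equal(variance_explained(0.5, 0.1), 0.005)
  expect_equal(variance_explained(0.3, 0), 0)
  expect_equal(variance_explained(0.9, 0.2), variance_explained(0.1, 0.2))
  expect_equal(variance_explained(0.5, 0.1, trait_sd = 2), 0.005 / 4)
  expect_error(variance_explained(0.5, 0.1, trait_sd = 0), "trait_sd")
})

test_that("F statistic follows the (N-k-1)/k formula with strict strength cut", {
  expect_equal(f_statistic(0.005, 1001, 1), 999 * (0.005 / 0.995))
  expect_equal(f_statistic(0, 1000, 5), 0)
  expect_error(f_statistic(0.1, 4, 3), "n > k \\+ 1")
  expect_false(is_strong_instrument(10))   # boundary is strict
  expect_true(is_strong_instrument(10 + 1e-9))

  # monotone in R2 and in N at fixed k
  r2s <- seq(0.001, 0.3, length.out = 20)
  expect_true(all(diff(vapply(r2s, f_statistic, 1, n = 5000, k = 10)) > 0))
  ns <- seq(100, 10000, length.out = 20)
  expect_true(all(diff(vapply(ns, function(n) f_statistic(0.05, n, 10), 1)) > 0))
})

test_that("build_instrument_set composes the filters with full provenance", {
  spec <- data.frame(rsid = "rs100002", trait = "smoking", pvalue = 1e-12)
  s <- simulate_study(simulation_config(k = 6, n_null_snps = 50, seed = 9,
                                        confounder_spec = spec))
  iset <- build_instrument_set(s$exposure_table, s$ld, s$catalog,
                               n_exposure = s$config$n_exp,
                               confounder_traits = "smoking")
  # pass-through up to the screen: significance output = planted instruments
  expect_equal(iset$k, 5L)
  expect_false("rs100002" %in% iset$instruments$rsid)
  screen_log <- iset$provenance[[3]]
  expect_equal(screen_log$dropped$rsid, "rs100002")

  for (st in iset$provenance) {
    expect_equal(st$n_in, st$n_out + nrow(st$dropped))
  }
  expect_equal(iset$total_r2, sum(iset$per_snp_r2))
  expect_equal(iset$f_statistic,
               f_statistic(iset$total_r2, s$config$n_exp, iset$k))

  # without a catalogue the set equals the significance+clump output
  iset2 <- build_instrument_set(s$exposure_table, s$ld,
                                n_exposure = s$config$n_exp)
  expect_equal(iset2$k, 6L)
})
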