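# bimr — bidirectional two-sample Mendelian randomization

`bimr` implements the complete summary-statistics Mendelian randomization
(MR) workflow used to ask whether two traits are causally linked — and in
which direction — from GWAS summary statistics alone. It was built around a
bidirectional case study of inflammatory bowel disease (IBD, with its
subtypes ulcerative colitis and Crohn's disease) and rosacea, and ships a
ground-truth simulator so every stage can be validated against planted
truth.

## What it does

**Instrument selection.** SNPs associated with the exposure at a
significance threshold (5×10⁻⁸ genome-wide; 5×10⁻⁶ when instruments are
scarce) are pruned to approximate independence by greedy LD clumping
(r² ≤ 0.001 within ±10,000 kb) and screened against confounder traits
(removing any instrument, or proxy at r² > 0.80, associated with a listed
confounder at p < 5×10⁻⁸). Instrument strength is summarised by
R² = 2·MAF·(1−MAF)·(β/SD)² per SNP and
F = [(N−k−1)/k]·[R²/(1−R²)], with F > 10 the conventional adequacy bar.

**Harmonization.** Exposure and outcome effects are aligned on a common
effect allele; swapped alleles are sign-flipped, incompatible records
dropped, and palindromic SNPs (A/T, C/G) excluded when either study's
allele frequency is intermediate (0.42–0.58 by default) since their strand
cannot be resolved.

**Estimation.** Five estimators of the causal log-odds θ from the per-SNP
Wald ratios rⱼ = β_out,ⱼ / β_exp,ⱼ:

- **IVW**: θ̂ = Σwⱼrⱼ / Σwⱼ with wⱼ = 1/se(rⱼ)², fixed-effect
  se = (Σwⱼ)^(−1/2) or multiplicative random-effects inflation
  max(1, √(Q/(k−1)));
- **MR-Egger**: weighted regression of β_out on β_exp with a free
  intercept — the intercept tests directional pleiotropy;
- **weighted median**: the 50% crossing of the weighted ordered ratios,
  consistent while valid instruments carry ≥ half the weight;
- **simple and weighted mode**: the kernel-density mode of the ratios.

Results are reported as OR = exp(θ̂) with 95% CIs.

**Sensitivity.** Cochran Q and I² heterogeneity, the Egger-intercept test,
leave-one-out influence, and MR-PRESSO (RSS-based global pleiotropy test by
parametric bootstrap, per-SNP outlier test, distortion test).

**Simulation.** `simulate_study()` generates paired exposure/outcome
summary statistics with known causal effect, pleiotropic instruments, LD
blocks, palindromic variants, background null SNPs and a planted
confounder catalogue — the basis of the package's statistical validation.

## Worked example

A study shaped like the IBD→rosacea direction of the case study (44
instruments, exposure N = 86,640, outcome N = 212,334, true
θ = log 1.1291):

```r
library(bimr)
cfg    <- make_case_study_scenario("forward", n_null_snps = 100)
study  <- simulate_study(cfg, seed = 2026)
report <- run_mr(study$exposure_table, study$outcome_table, study$ld,
                 config = mr_config(n_boot = 500, presso_n_sim = 500))
print(report)
```

```
MR report (forward): sim_exposure -> sim_outcome [causal]
Instrument set for sim_exposure: k = 44, total R2 = 0.1164, F = 259.4 (strong)
  significance       144 -> 44 (100 dropped)
  ld_clump           44 -> 44 (0 dropped)
Harmonized set sim_exposure -> sim_outcome: 44 SNP pairs, 0 excluded
           method n_snp       or or_ci_low or_ci_high       pvalue
1     IVW (fixed)    44 1.124253  1.110327   1.138355 9.823228e-76
2        MR-Egger    44 1.118865  1.081923   1.157069 6.287077e-08
3 Weighted median    44 1.126992  1.105303   1.149107 1.764409e-33
4     Simple mode    44 1.115222  1.076128   1.155735 3.782322e-07
5   Weighted mode    44 1.124592  1.091357   1.158840 1.389831e-09
Cochran Q = 32.0916 (df = 43), p = 0.8888, I2 = 0.0%
Egger intercept = 0.0005 (se 0.0016), p = 0.7641
MR-PRESSO: RSSobs = 33.9901, global p = 0.8942 (500 sims)
  outliers: None
```

Reading the output: 144 input SNPs reduce to the 44 planted instruments
(the 100 background null SNPs fail genome-wide significance); no LD or
palindrome losses in this draw. All five estimators agree on an OR near
the simulated truth of 1.1291, heterogeneity and pleiotropy diagnostics
are null (as planted), and the pipeline's verdict at α = 0.05 is
"causal". `export_plot_data(report, "out/")` writes scatter, forest,
funnel and leave-one-out tables for plotting;
`run_bidirectional()` runs both directions for several exposures at once
and assembles the sensitivity summary table.

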