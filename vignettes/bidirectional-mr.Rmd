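---
title: "Methods: bidirectional two-sample MR in bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR in bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The model

Two-sample Mendelian randomization treats genetic variants as natural
instruments for an exposure. For SNP $j$, let $\gamma_j$ be its effect on
the exposure and $\Gamma_j$ its effect on the outcome, both estimated in
*different* GWAS samples with standard errors $\sigma_{x,j}$,
$\sigma_{y,j}$. Under the three instrumental-variable assumptions —
(1) relevance: $\gamma_j \neq 0$; (2) independence: the variant is not
associated with exposure–outcome confounders; (3) exclusion restriction:
the variant affects the outcome only through the exposure — each Wald
ratio $r_j = \hat\Gamma_j / \hat\gamma_j$ estimates the same causal effect
$\theta$ (a log odds ratio when the outcome is binary). The package's job
is to enforce (1) by a significance filter, approximate (2) by a
confounder-trait screen, and probe (3) by pleiotropy-robust estimators and
sensitivity tests, in both directions of a trait pair.

## Instrument selection

- **Significance filter**: keep SNPs with exposure $p$ below the
  direction's threshold (defaults $5\times10^{-8}$ forward,
  $5\times10^{-6}$ reverse, where a relaxed threshold is the accepted
  trade-off when an exposure yields too few genome-wide hits). The
  comparison is strict (`p < thr`).
- **LD clumping**: greedy pass over SNPs by ascending $p$, dropping any
  SNP within $\pm 10{,}000$ kb of an already-kept SNP on the same
  chromosome with $r^2 > 0.001$. Ties in $p$ are broken by chromosome,
  position, then rsid, so the result is deterministic and invariant to
  input row order. SNPs absent from the LD reference are kept as isolated
  (with a log entry): an external reference panel cannot be assumed to
  cover every variant, and dropping them silently would bias selection.
- **Confounder screen**: a SNP is removed if it — or a proxy with
  $r^2 > 0.80$ — is associated with a listed confounder trait at
  $p < 5\times10^{-8}$. The catalogue is a local table standing in for a
  phenome-wide lookup service; live queries are out of scope.

Strength metrics use $R^2_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)
(\beta_j/\mathrm{SD})^2$ and $F = \frac{N-k-1}{k}\cdot\frac{R^2}{1-R^2}$
with $R^2 = \sum_j R^2_j$ (summing is justified because clumped
instruments are approximately independent). The trait SD defaults to 1
(betas on the standardized or log-odds scale) and is configurable, since
summary data rarely state it. $F > 10$ (strict) is labelled "strong".
A caveat worth knowing: for a *rare binary* trait analysed on the
log-odds scale, the unit-SD $R^2$ formula can overstate precision
dramatically relative to the effective sample size, so published $F$
values for such traits may be far below what the formula reproduces from
$k$, $N$ and a rounded $R^2$; `bimr` always reports the formula value and
leaves the interpretation to the analyst.

## Harmonization

Records are matched by rsid. Same-orientation allele pairs pass through;
swapped pairs have $\hat\Gamma$ sign-flipped and EAF complemented;
incompatible allele sets are excluded. Palindromic SNPs (A/T, C/G) are the
delicate case because a strand flip is indistinguishable from an allele
swap: under the default `drop_intermediate` policy they are excluded
whenever either study's EAF lies in the open window (0.42, 0.58) — or when
the outcome EAF is missing — and otherwise oriented so the same allele is
minor in both studies. A `drop_all` policy is also provided; published
pipelines differ on this point and the case study's counts are consistent
with either. The window bounds are configurable; (0.42, 0.58) is the
convention of widely used MR tooling.

## Estimators and reporting conventions

With first-order ratio SEs $se(r_j) = \sigma_{y,j}/|\hat\gamma_j|$
(default; a second-order delta-method version is available by flag) and
weights $w_j = 1/se(r_j)^2$:

- **IVW**: $\hat\theta = \sum w_j r_j / \sum w_j$, algebraically equal to
  weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through the
  origin with weights $1/\sigma_y^2$. Fixed-effect
  $se = (\sum w_j)^{-1/2}$; the multiplicative random-effects model
  scales it by $\max(1, \sqrt{Q/(k-1)})$ and never changes the point
  estimate. The pipeline uses fixed effects when Cochran $Q$'s $p \ge
  0.05$ and random effects otherwise, storing both.
- **MR-Egger**: weighted regression with free intercept after orienting
  all pairs to $\hat\gamma_j \ge 0$; implemented by closed-form weighted
  normal equations. Coefficient SEs carry a multiplicative overdispersion
  factor bounded below at 1, so p-values stay conservative under
  underdispersion. The intercept estimates the average directional
  pleiotropy.
- **Weighted median**: the value where the weighted empirical CDF of the
  sorted ratios ($S_j = \sum_{i\le j} w_i - w_j/2$, normalized) crosses
  $1/2$, linearly interpolated between bracketing ratios.
- **Mode estimators**: the maximiser of a normal-kernel density of the
  ratios with bandwidth $h = \phi\, \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{MAD})\,k^{-1/5}$ (MAD on the consistent 1.4826 scale); weights
  uniform (simple) or $w_j$ (weighted). The point estimate uses a
  10,000-point grid spanning $[\min r - h, \max r + h]$; bootstrap
  replicates use a 512-point grid, where grid error is far below the
  bootstrap SE. If all ratios coincide the common ratio is returned.

P-value reference distributions follow the field's software conventions:
normal for IVW and the weighted median, $t_{k-2}$ for MR-Egger (slope and
intercept), $t_{k-1}$ for the modes; 95% CIs are always
$\hat\theta \pm 1.959964\,se$ on the log scale, exponentiated for OR
reporting. These conventions are not arbitrary here: the package's
consistency checks verify that the published case-study CIs are exactly
reproducible from the published ORs and p-values under them (and not
under a single shared reference).

Weighted-median and mode SEs come from a parametric bootstrap (redraw
$\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{x,j})$,
$\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{y,j})$, re-estimate; default
1000 replicates). Every stochastic routine takes an explicit seed
(default 20230909) and restores the caller's RNG state, so pipelines are
reproducible end to end; byte-identical report files under identical
config are a tested invariant.

## Sensitivity analyses

- **Cochran $Q$** with IVW weights, $\chi^2_{k-1}$ reference;
  $I^2 = \max(0, (Q - df)/Q)\cdot 100$.
- **Leave-one-out**: fixed-effect IVW re-estimated without each SNP
  (matching the headline analysis), plus the all-SNP row; rows that
  overturn the full-set significance call are flagged.
- **MR-PRESSO**: observed statistic $RSS = \sum_j w_j(\hat\Gamma_j -
  \hat\theta_{(-j)}\hat\gamma_j)^2$ with leave-one-out IVW expectations
  and outcome-variance weights (an exposure-variance-augmented weighting
  is available by flag). The global p compares $RSS$ against parametric
  simulations with the leave-one-out expectations recomputed inside every
  replicate, as $(1 + \#\{RSS^{sim} \ge RSS\})/(1 + n_{sim})$. Per-SNP
  outlier p-values (own simulated residual distribution, Bonferroni
  $\times k$) are always reported, but outliers are *called* only when
  the global test rejects — the published construction runs the outlier
  search conditional on global significance, and unconditional calling
  produces spurious outliers on homogeneous data whenever the empirical
  per-SNP p hits zero at modest $n_{sim}$. The distortion test (random
  same-size removals) runs only when outliers exist, so an empty outlier
  list yields an absent distortion p by design.

## The synthetic-data generator

`simulate_study()` emulates the summary-level structure the analysis
assumes: per-SNP MAF from a configurable range, SEs
$1/\sqrt{2N\,\mathrm{MAF}(1-\mathrm{MAF})}$ on the unit-variance scale
(consistent with the $R^2$ formula above), true instrument effects
$\gamma_j \sim N(0, \sigma_\gamma)$ with effect alleles coded
exposure-increasing, pleiotropic effects $\alpha_j \sim N(\mu_\alpha,
\sigma_\alpha)$ on a configurable fraction of instruments, outcome truth
$\theta\gamma_j + \alpha_j$, LD blocks of correlated satellites,
palindromic variants at near-0.5 EAF, background null SNPs, planted
confounder-catalogue rows, and outcome tables with randomly swapped
allele orientation so harmonization is always exercised.

Two deliberate design points:

- **Selection on observed significance.** The pair (true effect, noise)
  is redrawn until the *observed* exposure association passes the
  threshold. This makes stage counts exact — the significance filter
  keeps precisely the planted instruments, which the pipeline accounting
  tests rely on — at the cost of a mild winner's curse: measured IVW
  interval coverage on the study-shaped causal scenario is ~93% rather
  than 95%, the same attenuation real MR studies incur by selecting
  instruments in the exposure sample itself.
- **Directional pleiotropy scale.** Where a robustness scenario needs
  "substantial" directional pleiotropy, the generator anchors it to the
  mediated effect: $\alpha \sim N(0.012, 0.012)$ log-odds, i.e. a
  pleiotropic pathway as strong on average as the causal pathway
  ($\theta\cdot E[\gamma] \approx 0.012$) with comparable heterogeneity.
  Under much stronger one-sided contamination the weighted median's
  quantile-shift bias saturates near 2–2.5 bootstrap SEs regardless of
  magnitude — a regime in which no median-type estimator "recovers" the
  truth — so the moderate regime is the meaningful one for the breakdown
  property.

What the generator does **not** model: genotype-level data (LD is induced
at the summary level), a realistic allele-frequency spectrum or
annotation, case/control imbalance (N is an effective sample size), or
between-study sample overlap. Passing tests therefore validate the
statistical machinery under the stated assumptions, not robustness to
real-data pathologies such as population stratification or overlapping
samples.

`make_case_study_scenario()` pins the two directions of the case study:
forward $k = 44$, $N_{exp} = 86{,}640$, $N_{out} = 212{,}334$,
$\theta = \log 1.1291$ at $5\times10^{-8}$; reverse $k = 12$,
$\theta = 0$, small $\gamma$ at $5\times10^{-6}$. One honest discrepancy:
the case study reports reverse-direction $F = 4.63$ with
$R^2 = 0.03\%$, which is mutually inconsistent with its own $F$ formula
and with any instrument set selected at $p < 5\times10^{-6}$ on the
unit-SD scale (the threshold alone forces per-SNP $z^2 \gtrsim 21$). The
reverse scenario therefore mirrors the sizes, threshold and null effect,
and lets $F$ come out as the formula dictates; the likely origin of the
printed value is the rare-binary-outcome scale mismatch discussed under
instrument strength.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate: oracle equality of
IVW/Egger with closed-form weighted least squares on 100 random sets
(tolerance $10^{-10}$ relative); 95% CI coverage and null type-I error of
IVW over 500 study-shaped replicates each; MR-PRESSO global-test size
over 200 replicates of 200 simulations; detection of a planted
$10\,\sigma_y$ outlier in 100 replicates; weighted-median bias under 40%
directional pleiotropy over 25 replicates with 200-replicate bootstraps;
and exact stage accounting on studies with planted nulls, LD blocks,
palindromes and confounders. These sizes keep the full validation in the
low tens of seconds while leaving Monte-Carlo error well inside every
acceptance band.

## Interface choices and limitations

The package is an R library: the exported functions, the simulator and
`scripts/acceptance.R` are the interface, and plot-*data* exporters
(`export_plot_data()`) replace figure rendering so any plotting tool can
consume the outputs. Config files are JSON (`read_analysis_config()`).
No proxy-SNP substitution is attempted for instruments missing in the
outcome study; no Steiger filtering, multivariable MR, or
genotype-level analysis is provided. The fixed-vs-random IVW switch keyed
on $Q$'s p-value at 0.05 generalises the single stated instance in the
case study; both estimates are always stored so the switch never hides
information.
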