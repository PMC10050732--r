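# mrsuite

Two-sample Mendelian randomization (MR) for GWAS summary statistics, with
first-class support for **correlated instruments**, built around the
question of whether genetically proxied morning plasma cortisol affects
periodontitis risk.

## The problem

Observational associations between circulating cortisol and periodontal
disease are vulnerable to confounding and reverse causation. MR sidesteps
both by using genetic variants as instruments: variants in the *SERPINA1* /
*SERPINA6* locus shift long-term plasma cortisol, are fixed at conception,
and can therefore proxy the exposure in an instrumental-variable analysis.
Because the variants come from one locus they are in linkage
disequilibrium (LD), and pooling them correctly requires the
correlated-instrument form of the inverse-variance-weighted (IVW)
estimator.

`mrsuite` implements the complete workflow for an epidemiologist working
from summary statistics:

* **gwas_io** — read/write/validate tab-delimited GWAS summary statistics
  and LD matrices; harmonize exposure and outcome to common effect alleles
  (swapped, strand-complement and palindromic cases, with full provenance).
* **instruments** — P-value selection with greedy LD clumping
  (keep the smallest-P variant of each clump at a squared-LD threshold),
  first-stage F statistics, variance explained (plain and LD-adjusted).
* **estimators** — per-SNP Wald ratios `β_Y / β_X`; fixed-effect IVW for
  correlated instruments via generalized least squares with covariance
  `Ω_ij = σ_Yi σ_Yj ρ_ij`; classic independent-instrument IVW (fixed or
  multiplicative random effects); MR-Egger regression and its intercept
  test for directional pleiotropy; Cochran's Q / I²; leave-one-out; and a
  profile-score (RAPS) estimator that accounts for exposure-side sampling
  error.
* **power** — closed-form a priori power and minimum detectable odds ratio
  for binary outcomes, `power = Φ(|ln OR|/SE − z_{1−α/2}) + Φ(−|ln OR|/SE −
  z_{1−α/2})` with `SE = 1/√(N·r²)` by default.
* **synthetic_data** — a seeded generator of two disjoint cohorts
  (Gaussian-copula haplotypes with block-AR(1) LD, a genetically driven
  standardized exposure, a liability-threshold binary outcome, optional
  pleiotropy), fitted per SNP into the same summary-statistic format, so
  every estimator is testable without external data.
* **cli_pipeline** — `run_mr_pipeline()` orchestrates
  select → harmonize → estimate → diagnose → power and writes
  tab-delimited result tables.

All causal estimates are reported as the odds ratio of the outcome per
1-SD increment of the exposure, with 95% normal-theory CIs.

## Worked example

The three cortisol instruments from the CORNET GWAS ship with the package:

```r
library(mrsuite)
instr <- cortisol_instruments()
f_statistic(instr$beta, instr$se)
#> [1] 30.25000 47.15111 45.56250
round(variance_explained(instr$eaf, instr$beta), 4)
#> [1] 0.0027 0.0036 0.0033
```

The weakest instrument has F ≈ 30.3 — comfortably past the F > 10
weak-instrument rule of thumb — and each variant explains ~0.3% of
cortisol variance.

A full synthetic end-to-end run:

```r
cfg <- simulation_config(seed = 7)          # 3 correlated SNPs, n = 5,000 per cohort
st  <- simulate_study(cfg)                  # exposure + outcome GWAS + true LD
h   <- harmonize(st$exposure, st$outcome, st$ld)
mr_ivw_correlated(h)
#> ivw_correlated (3 SNPs): beta = 0.1313 (SE 0.1772), OR = 1.140 [0.806, 1.614], P = 0.459
mr_heterogeneity(h)
#> Cochran's Q = 0.592 (df 2), P = 0.744, I^2 = 0.0%
```

The config's causal effect defaults to zero, and the IVW CI duly covers
the null; Q shows no heterogeneity across the three Wald ratios.

Power at the periodontitis GWAS scale (17,353 cases / 28,210 controls):

```r
mr_power_binary(1.30, n_cases = 17353, n_controls = 28210, r2 = 0.005)
#> [1] 0.9772521
min_detectable_or(17353, 28210, r2 = 0.016, target_power = 0.8)
#> [1] 1.109336
```

With instruments explaining 0.5% of cortisol variance there is ~98% power
to detect OR 1.30 per SD; the liberal 1.6% instrument set can detect
OR ≈ 1.11 at 80% power.

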