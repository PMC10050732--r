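---
title: "Methods: two-sample MR with correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsuite)
```

`mrsuite` estimates the causal effect of a continuous exposure (here:
morning plasma cortisol, in SD units) on a binary outcome (periodontitis)
from two non-overlapping GWAS. This vignette documents the statistical
model, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The two-sample MR model

For instrument $j$, let $\hat\beta_{Xj} \pm \sigma_{Xj}$ be its per-allele
association with the exposure and $\hat\beta_{Yj} \pm \sigma_{Yj}$ its
per-allele log-odds association with the outcome, estimated in separate
samples. If the instrument is valid (relevance, exchangeability, exclusion
restriction), each Wald ratio $\hat\theta_j = \hat\beta_{Yj} /
\hat\beta_{Xj}$ estimates the causal log-odds per 1-SD exposure.

**Correlated-instrument IVW.** When instruments come from one locus they
are in LD with signed correlation matrix $\rho$. We pool on the beta scale
by generalized least squares through the origin with covariance
$\Omega_{ij} = \sigma_{Yi}\sigma_{Yj}\rho_{ij}$:

$$\hat\theta = (\beta_X^\top \Omega^{-1} \beta_X)^{-1}
               \beta_X^\top \Omega^{-1} \beta_Y,
  \qquad
  \mathrm{SE}(\hat\theta) = (\beta_X^\top \Omega^{-1} \beta_X)^{-1/2}.$$

This is algebraically identical to pooling the Wald ratios with their
LD-induced correlation, but avoids ratio-space instability when some
$\hat\beta_{Xj}$ is small. With identity LD it reduces exactly to classic
fixed-effect IVW (a tested invariant, to 1e-10), and with one instrument
to the Wald ratio with the first-order delta SE $\sigma_Y/|\beta_X|$ (the
second-order SE, adding $\beta_Y^2\sigma_X^2/\beta_X^4$, is available by
flag; the first-order default keeps the GLS equivalence).

**Diagnostics.** Cochran's $Q = \sum_j (\hat\beta_{Yj} -
\hat\theta\hat\beta_{Xj})^2/\sigma_{Yj}^2$ with $K-1$ df and $I^2 =
\max(0, (Q - \mathrm{df})/Q)$ quantify heterogeneity; MR-Egger regresses
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ *with* an intercept (weights
$1/\sigma_{Yj}^2$, instruments oriented so $\hat\beta_{Xj} > 0$) — a
nonzero intercept indicates directional pleiotropy; leave-one-out
re-estimates the pooled effect omitting each SNP. The Egger SEs use the
weighted-regression sigma as estimated, and its slope/intercept P-values
are two-sided *t* with $K-2$ df — with a normal reference the intercept
test's true size at, say, $K = 20$ would be $P(|t_{18}| > 1.96) \approx
6.6\%$ rather than 5%. All other P-values are two-sided normal
(chi-square for $Q$), 95% CIs, no multiplicity adjustment — matching how
such analyses are conventionally reported.

**RAPS.** The profile-score estimator maximizes
$-\tfrac12\sum_j (\hat\beta_{Yj} - \theta\hat\beta_{Xj})^2 /
(\sigma_{Yj}^2 + \theta^2\sigma_{Xj}^2 + \tau^2)$, which accounts for
exposure-side sampling error (with $\tau^2 = 0$ by default; with
overdispersion, the full Gaussian likelihood including its log-variance
terms is maximized jointly over $(\theta, \tau^2 \ge 0)$, otherwise
$\tau^2$ would run away). Optimization is Brent / L-BFGS-B from the IVW
start within a wide bracket; the SE is the inverse observed information at
the optimum (numerical Hessian). The simple quadratic loss is used, not
Tukey/Huber robust losses, and LD is ignored — RAPS is intended for the
clumped (r² < 0.2) polygenic instrument set.

## Instrument selection and strength

Candidates passing the P-value threshold are clumped greedily: sort by
ascending P (ties broken by lexicographic rsID so the output is invariant
to row order), keep the top, discard everything with squared LD ≥ the
threshold against it, repeat. No genomic-window constraint is applied —
the LD matrix alone decides. Strength is summarized by $F_j =
(\hat\beta_{Xj}/\sigma_{Xj})^2$ and variance explained $2p_j(1-p_j)
\hat\beta_{Xj}^2$ (unit-variance exposure). For a correlated set the plain
sum of per-SNP terms overstates the total $r^2$, so the report also gives
the quadratic form $\beta_X^\top D R^- D\, \beta_X$ with $D =
\mathrm{diag}\sqrt{2p(1-p)}$ and $R^-$ a pseudo-inverse; neither variant
is privileged because published totals rarely state their LD handling.

## Harmonization rules

Outcome records are aligned to the exposure's effect allele: identical
pairs pass through; swapped (and strand-complement-swapped) pairs get
$\beta \to -\beta$, $p \to 1-p$; palindromic SNPs (A/T, C/G) cannot be
strand-resolved from letters, so those with EAF within a window of 0.5
in either study are dropped and the rest aligned by frequency. The window
defaults to 0.08 — a conventional conservative choice, exposed as an
argument since there is no community consensus — and every input SNP
receives a provenance flag. LD matrices carry *signed* r (the GLS needs
signs; only clumping squares them), are validated for symmetry/unit
diagonal, and indefinite estimates (possible from small panels) are
ridge-repaired by $\delta I$, $\delta = |\lambda_{\min}| + 10^{-8}$, with
a warning.

## Power

For a binary outcome the anticipated SE of the pooled log-OR is taken as
$1/\sqrt{N r^2}$ (total outcome GWAS size $N$, instrument $r^2$), giving
$\mathrm{power} = \Phi(|b|/\mathrm{SE} - z_{1-\alpha/2}) +
\Phi(-|b|/\mathrm{SE} - z_{1-\alpha/2})$ for $b = \ln \mathrm{OR}$. An
alternative `"binomial"` model divides the effective size by
$\varphi(1-\varphi)$ (case fraction $\varphi$), and is never more
optimistic since $\varphi(1-\varphi) \le 1/4$. The standardized model is
the default because it is the variant under which the motivating
analysis's stated operating points (≥80% power for OR 1.30 at
$r^2 = 0.005$ and OR 1.19 at $r^2 = 0.016$, N = 45,563) hold; published
MR power formulas differ in exactly this term, so both are exposed.
Exposure-GWAS uncertainty is deliberately ignored (first-order), as is
conventional for a priori MR power. The minimum detectable OR inverts the
formula by bisection on the log scale to 1e-6. When `run_mr_pipeline()`
computes power it plugs in the LD-adjusted total $r^2$ if a non-identity
LD matrix was supplied (the plain sum would flatter a correlated set),
and the plain sum otherwise.

## The synthetic-data generator

The generator emulates the *structure* of a two-sample MR study, not any
particular human cohort:

* **Genotypes.** Per haplotype, a latent normal vector with block-AR(1)
  correlation is thresholded at each SNP's MAF quantile; the dosage is
  the sum of two independent haplotypes. This Gaussian copula gives
  direct, analytic control of the dosage LD the estimators consume — the
  package computes the implied dosage correlation exactly via a 1-D
  integral reduction of the bivariate normal CDF — at the price of not
  reproducing realistic human LD maps, allele-frequency spectra, or
  recombination structure.
* **Phenotypes.** Exposure $X = G\gamma + cU + e$ with the residual
  variance set so $\mathrm{var}(X) = 1$ exactly (clean per-SD semantics);
  the outcome cohort's liability $L = \theta X' + G\alpha + cU + e'$
  (its own latent exposure $X'$, shared confounder $U$), also scaled to
  unit variance, dichotomized at $\Phi^{-1}(1-\mathrm{prevalence})$.
  A probit/liability outcome was chosen over a logistic link because it
  controls prevalence exactly and keeps $\theta$ interpretable; the
  consequence is that a logistic GWAS on such data estimates an
  *attenuated* log-odds — for small per-allele effects, approximately the
  liability effect times $\phi(t)/(\varphi(1-\varphi))$. Recovery tests
  therefore target the large-sample fitted value (or use a null
  $\theta$, where the scales agree), not the liability coefficient.
* **GWAS fits.** Per SNP: closed-form simple OLS (continuous) or
  maximum-likelihood logistic regression (binary), emitting the same
  summary-statistic format the readers consume. Monomorphic SNPs and
  separated logistic fits are dropped with warnings.
* **Randomness.** One documented stream: a config resolves per-SNP MAFs
  and instrument effects once (a fixed "study design"); each
  `simulate_study()` call seeds R's RNG a single time and draws cohorts
  and pleiotropic effects $\alpha \sim N(\mu_\alpha, \sigma_\alpha^2)$
  afresh — $\alpha$ is per-replicate randomness so that rejection rates
  across replicates are rates under the generating process. Identical
  seeds give byte-identical output files.

**Default study conditions.** The default config mirrors the motivating
setting qualitatively at desk scale: one block of 3 correlated
instruments (latent AR(1) ρ = 0.5) from a single locus, per-allele
effects γ = 0.1 on the standardized exposure, MAFs in (0.2, 0.5],
cohorts of 5,000, a shared confounder loading of 0.3, causal effect 0
(the motivating analysis's own finding), and outcome prevalence 0.38
(the case fraction of a 17,353-case / 28,210-control GWAS). These sizes
give expected per-instrument F ≈ 40–60, comfortably above the weakest
real instrument (F ≈ 30), while keeping a 1,000-replicate coverage run in
tens of seconds. The Egger calibration scenario uses 20 independent
instruments with effects spread over 0.14–0.35 (expected F ≈ 21–125, so
the weakest mirrors a liberal clumped set's minimum of ~17, and the
between-SNP effect spread dominates the exposure-side SE — the regime in
which the intercept test is nominally calibrated; a narrow effect spread
would add regression-dilution bias to the intercept), cohorts of 2,000,
balanced pleiotropy σ_α = 0.02, and a directional alternative μ_α = 0.05,
whose implied mean direct effect on the log-odds scale (≈1.6·μ_α ≈ 0.08)
is large relative to the intercept SE at these sizes, so the directional
scenario is decisively detectable.

What passing these simulations does *not* show: robustness to realistic
LD, to MAF-dependent effect sizes, to sample overlap between the two
GWAS (deliberately absent — overlap biases two-sample MR and the
motivating design avoided it), to binary-exposure settings, or to
pleiotropy correlated with instrument strength (InSIDE violations).

## Numerical notes and limitations

* GLS solves go through the Cholesky factor of Ω; a singular Ω (after
  PSD repair) raises an error carrying the condition number.
* `write_summary_stats()` serializes numerics at 17 significant digits so
  write∘read is the exact identity.
* Wald P-values from very strong associations are floored at the smallest
  positive double to stay within (0, 1].
* The minimum detectable OR is returned on the definitional side of the
  root: power at the returned OR is ≥ target, at OR − 1e-4 it is below.
* Not implemented (out of scope by design): GSMR/HEIDI, CAUSE,
  weighted-median/mode estimators, Steiger filtering, proxy-SNP lookup,
  reference-panel download, and the observational (cohort-regression) arm
  of the motivating study.
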