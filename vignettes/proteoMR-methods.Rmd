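---
title: "Two-sample MR of protein biomarkers: models, parameters and design choices"
author: "proteoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR of protein biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoMR)
```

## The problem

Circulating inflammatory proteins are routinely found elevated in patients
with inflammatory disease, but association says nothing about direction:
a protein may drive disease, or be expressed in response to it. proteoMR
implements a two-sample Mendelian randomization (MR) pipeline that uses
cis-acting protein quantitative trait loci (cis-pQTLs) as instrumental
variables to estimate the causal log-odds effect of a protein's circulating
level on case-control disease status. "Two-sample" means the SNP-protein
effects ($b_{zx}$, estimated in a small deeply-phenotyped exposure cohort)
and the SNP-disease effects ($b_{zy}$, estimated in a large biobank-style
outcome cohort) come from disjoint sets of individuals, which directs both
weak-instrument and winner's-curse bias toward the null rather than toward
spurious effects.

A valid instrument must (i) associate with the protein, (ii) not associate
with confounders of the protein-disease relation, and (iii) affect disease
only through the protein. (ii) and (iii) cannot be verified per SNP;
restricting instruments to the cis region and screening for heterogeneity
between per-SNP causal estimates (the HEIDI outlier procedure) are the
operational defenses.

## Pipeline stages

1. **Association scans** (`rankInverseNormal`, `linearScan`,
   `logisticScan`, `qcFilterVariants`, `hweTest`, `varianceExplained`).
   Protein levels are rank-inverse-normal transformed within measurement
   groups, $\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties, so
   exposure effects are per SD of a standard-normal phenotype. The exposure
   scan is OLS (synthetic individuals are unrelated, so no kinship mixed
   model is needed); the outcome scan is per-SNP maximum-likelihood
   logistic regression; both adjust for sex, age and principal-component
   covariates. Variant QC applies MAF/HWE/missingness/info thresholds in a
   fixed order, logging the first failing rule per variant.
2. **Instrument selection** (`cisWindow`, `intersectAndHarmonize`,
   `greedyPrune`, `selectInstruments`). Candidates are SNPs inside the
   protein-coding gene's end points plus a 2-Mb flank (1-based, inclusive
   boundaries), present and allele-harmonizable in both cohorts, with
   exposure $p < 10^{-6}$. The greedy loop then repeatedly takes the
   smallest-p candidate and discards everything with $r^2 > 0.6$ against
   it **in either cohort's LD**, so the final set is pairwise below the
   threshold in both. Proteins with fewer than four surviving instruments
   are rejected; sets of exactly four are analyzed with the HEIDI screen
   disabled (it needs at least five SNPs).
3. **Causal estimation** (`waldRatio`, `glsCausalEstimate`,
   `heidiOutlier`, `gsmrEstimate`). Per SNP, the Wald ratio
   $\hat\beta_i = b_{zy,i}/b_{zx,i}$ carries the first-order delta-method
   variance $v_i = (se_{zy,i}^2 + \hat\beta_i^2 se_{zx,i}^2)/b_{zx,i}^2$.
   Ratios are combined by generalized least squares under
   $V_{ij} = r_{ij}\sqrt{v_i v_j}$, where $r$ is the signed LD estimated in
   the outcome cohort: $\hat b = (1'V^{-1}\hat\beta)/(1'V^{-1}1)$,
   $se = (1'V^{-1}1)^{-1/2}$, tested against $\chi^2_1$ (fixed-effect
   convention). HEIDI first removes, in one pass at $\alpha = 0.01$, every
   SNP whose ratio deviates from the top-exposure-SNP reference ratio by
   more than chance given
   $\mathrm{var}(d_i) = v_i + v_{ref} - 2 r_{i,ref}\sqrt{v_i v_{ref}}$.
4. **Sensitivity estimators** (`ivwCorrelated`, `eggerCorrelated`,
   `weightedMedian`). IVW and MR-Egger are GLS regressions of $b_{zy}$ on
   $b_{zx}$ (through the origin, and with a free pleiotropy intercept,
   respectively) under the outcome-side covariance
   $\Omega_{ij} = r_{ij} se_{zy,i} se_{zy,j}$, with random-effect residual
   inflation floored at one. The weighted median interpolates the
   inverse-variance-weighted median of the ratios and takes its SE from a
   parametric bootstrap. These run on the full instrument set: outliers
   are only ever removed in the main (GSMR) analysis.
5. **Grid reporting** (`runGrid`, `bhAdjust`, `categorizeCell`,
   `writeReport`). Every protein-disease cell is estimated; the GSMR raw
   p-values are Benjamini-Hochberg adjusted with $m$ equal to the total
   number of attempted cells (failed cells stay in the denominator —
   conservative, and faithful to an all-cells grid); cells are binned into
   the heat-map categories (protective/harmful direction, four raw-p
   shades below 0.05, star for FDR < 0.05) and written as TSV + YAML.

## What the synthetic cohorts emulate

Individual-level biobank data of the kind this pipeline targets are
access-restricted, so the package ships a generator
(`simulationConfig`, `generatePairedStudy`, `scanStudy`) whose defaults are
the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `nExposure` | 872 | exposure-cohort size |
| `nOutcome`, `nCases` | 20,000 / 2,000 | outcome cohort; cases in expectation |
| `nSnpsPerBlock`, `blockRho` | 5+5, 0.3 | AR(1) LD blocks |
| `eafRange` | (0.15, 0.85) | effect-allele frequencies |
| `nCausal`, `h2Target` | 10, 0.30 | causal cis SNPs; protein variance explained |
| `trueB` | ln 0.84 | causal log-odds per protein SD |
| `pleioFraction`, `pleioEffectMean`, `pleioEffectSd` | 0, 0, 0.05 | direct SNP-disease effects |

The exposure-cohort size and the joint variance explained sit inside the
ranges reported for deeply phenotyped protein panels (single instruments
explaining up to ~40% and instrument sets 12-60% of a protein's variance);
an outcome cohort of 20,000 with a 10% case fraction is a deliberately
scaled-down biobank (real case series run from ~1,000 to ~59,000 against
~360,000 controls) that keeps hundreds of replicates affordable while
leaving the outcome scan comfortably asymptotic. The causal odds ratio
0.84/SD matches the magnitude of a typical protective effect this kind of
screen detects.

Genotypes come from a Gaussian copula: per individual two latent MVN
vectors with the target correlation are thresholded at each SNP's allele
frequency quantile and summed, giving Binomial(2, EAF) marginals,
Hardy-Weinberg by construction, and dosage correlations close to (slightly
attenuating) the latent $r$. The protein is
$\sum_j u_j g_j + \text{covariates} + \varepsilon$ with per-SNP effect
magnitudes drawn as roughly equal $h^2$ shares with mild jitter and random
signs, rescaled so the realized genetic variance is `h2Target`; noise
variance is $1 - h^2 - \mathrm{Var(covariates)}$ so the protein has unit
variance and `trueB` is exactly the log-odds per protein SD. Disease
status is Bernoulli from a logistic model (not a liability threshold —
matching the logistic model the outcome scan actually fits) whose
intercept is tuned by root-finding so the expected case count equals
`nCases`, and whose linear predictor adds `trueB` times the protein-scale
genetic value, direct effects for pleiotropic SNPs, and covariate effects.
Covariates are one binary (sex), one continuous (age) and $k \ge 2$
standardized PC-like variables with small effects on both traits, so both
scans genuinely exercise covariate adjustment.

Two deliberate emulation choices: instrument selection runs in the same
exposure cohort used for effect estimation, reproducing the winner's-curse
regime of the real design (which biases toward the null — no split-sample
debiasing is added); and pleiotropic SNPs are drawn among the causal SNPs
*excluding* the largest-effect sentinel, emulating a cis architecture
whose lead variant acts through the protein — the HEIDI reference is the
top exposure SNP, and a pleiotropic reference would invert the logic of
outlier removal (a known failure mode of the method, not of this
implementation).

What the generator does **not** model: realistic human LD maps,
relatedness, imputation error, sex chromosomes, plate/batch structure
beyond the INT grouping hook, or case-control ascertainment. Passing
recovery tests on these cohorts therefore demonstrates the estimators'
statistical correctness under the stated model, not robustness to every
artefact of real biobank data.

## Numerical choices

- All GLS solves use Cholesky factorization, never explicit inversion; a
  condition number above $10^{12}$ raises an error recommending a stricter
  $r^2$ threshold (no silent regularization).
- Ratio-based estimators (GSMR, HEIDI) first orient every SNP so its
  exposure effect is positive, negating $b_{zy}$ and the LD signs. The
  covariance $r_{ij}\sqrt{v_i v_j}$ is only sign-correct in this coding;
  orientation makes all estimators invariant to allele-coding flips
  (verified to $10^{-12}$ in the tests).
- The delta-method ratio variance is first order. At the default exposure
  size (n = 872, per-instrument F ≈ 25) it is mildly conservative: the
  heterogeneity statistic $Q$ runs below its nominal $\chi^2_{L-1}$ mean,
  and the causal test's empirical size sits around 3% at nominal 5%
  (conservative, never anticonservative). The $Q$ calibration property is
  therefore checked at n = 3,000, where the approximation's premise
  (strong instruments, as enforced by the $p<10^{-6}$ selection rule)
  holds.
- Greedy-pruning ties on exposure p break by smaller position, then
  lexicographic SNP id, making selection deterministic; removal triggers
  on $r^2$ strictly greater than the threshold.
- Palindromic (A/T, C/G) SNPs are excluded at harmonization by default
  (configurable): with cohorts genotyped on different platforms their
  strand cannot be verified. Harmonizing a table against itself is
  sign-identical (involution check).
- The weighted-median bootstrap resamples effects independently, ignoring
  LD between instruments (flagged limitation; the estimator is a
  sensitivity check, not the main analysis). Its seed is recorded in the
  returned object.
- BH adjustment delegates to `stats::p.adjust` with the external test
  count `m`; an independent $O(m^2)$ implementation of the step-up
  definition cross-checks it in the tests.
- `hweTest` uses the 1-df chi-square rather than an exact test: the
  thresholds in use ($10^{-20}$, $5\times10^{-8}$) are deep-tail, where
  the chi-square is the conventional choice.
- `varianceExplained` reports incremental $R^2$ over the covariate-only
  model (per SNP alone, and jointly), equivalent to sequential ANOVA with
  covariates first.

## Simulation scales used in validation

The test suite and the acceptance script rerun the whole pipeline at the
default study conditions: 200 paired-cohort replicates for parameter
recovery (mean GSMR estimate, 95% CI coverage) and 200 under a null effect
for the size of the $\chi^2_1$ test. Pleiotropy-machinery checks (HEIDI
detection and bias reduction, Egger intercept power, weighted-median
robustness) run at summary-statistics level — effects drawn around truth
at the stated SEs and LD — because they probe the estimators, not the
cohort generator, and this keeps hundreds of replicates cheap. Pleiotropy
magnitudes were fixed by power analysis before running anything: direct
log-odds effects N(0.2, 0.02) on 3 of 10 instruments displace the
affected Wald ratios by 4-6 SDs (per-SNP HEIDI flag power ≈ 0.95 at
$\alpha=0.01$); the Egger check uses mean direct effect 0.05 across 20
well-spread instruments ($b_{zx}$ from 0.1 to 0.9, $se_{zy} = 0.02$),
where the intercept's analytic z is ≈ 4.7.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 7)
study <- generatePairedStudy(cfg)
scans <- scanStudy(study)
gsmrEstimate(scans$input)
```

## Known limitations

- Single-pass HEIDI with the top exposure SNP as reference: a pleiotropic
  lead SNP defeats the screen (the pass count is configurable, but no
  multi-reference scheme is implemented).
- Exposure-side uncertainty enters IVW/Egger only through the regression
  design, not the covariance (the cited sensitivity-method convention).
- No trans-pQTL instruments, proxy-SNP lookup, multivariable or
  bidirectional MR.
- The grid's FDR denominator is recomputed per run from the attempted
  cells; analyses at different selection thresholds get their own
  denominators.
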