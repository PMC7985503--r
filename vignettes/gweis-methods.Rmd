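---
title: "Interaction scans with robust inference: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction scans with robust inference: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gweisr)
```

# The model

For each SNP and exposure, `run_gweis()` fits

$$Y_i = \beta_0 + G_i\beta_G + E_i\beta_E + G_iE_i\beta_{GxE} +
C_i'\beta_C + C_i'G_i\beta_{CxG} + C_i'E_i\beta_{CxE} + \epsilon_i$$

by ordinary least squares and tests $\beta_{GxE}$ two-sidedly against a
$t$ reference with $n - p$ degrees of freedom, where $p = 4 + 3k$ for $k$
covariates. Dosages count the recorded effect allele (0/1/2; male X
genotypes 0/2, single copies counted twice); exposures — including ordinal
questionnaire codes and endorsement counts — enter as continuous
covariates. The assumptions are those of the linear model *minus*
homoscedasticity: residuals may have any per-observation variance, because
inference uses the Huber-White sandwich covariance

$$\widehat{\mathrm{Var}}(\hat\beta) =
(X'X)^{-1} X' \mathrm{diag}(e_i^2)\, X (X'X)^{-1},$$

with raw squared residuals (HC0, the default) or the $n/(n-p)$ rescaling
(HC1). Interaction tests are unusually sensitive to heteroscedasticity:
when the residual variance depends on $E$, it co-varies with $(GE)^2$, and
the classical single-$\sigma^2$ standard error of $\hat\beta_{GxE}$ is
systematically too small, inflating the scan genome-wide. The acceptance
suite demonstrates this directly: under a null with residual variance
$\exp(0.5E)$, the model-based test rejects well above its nominal 5% while
the HC0 test stays inside the binomial envelope.

The second protection is structural. Covariate main effects do not shield
the interaction term from a covariate that *moderates* the SNP effect
while correlating with the exposure; such an effect loads onto
$G \times E$ unless the $C\times G$ and $C\times E$ blocks are in the
design. They are included by default
(`design_spec(covariate_interactions = TRUE)`), and a dedicated test shows
that omitting them under a generative $C\times G$ effect inflates the null
rejection rate while the full design stays nominal.

`run_gwas()` is the companion main-effect scan ($Y \sim 1 + G + C$) with
model-based errors by default, matching standard GWAS software; its
results feed the main-effect PRS.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `hc` | `"HC0"` | sandwich variant; HC0 is the plain squared-residual estimator, HC1 the small-sample rescaling |
| `covariate_interactions` | `TRUE` | include $C\times G$, $C\times E$ blocks |
| QC `maf_min` / `miss_max` / `info_min` | 0.01 / 0.05 / 0.9 | post-imputation variant filters; absent info scores pass trivially (logged) |
| clump `r2_threshold` / `window_kb` | 0.2 / 250 | greedy clumping for score construction; 0.8 is the looser "independent signal" reporting convention |
| PRS `grid` | .001, .05, .1, …, .9, 1 | p-value thresholds for score SNP sets |
| `bonferroni_threshold()` layers | — | per-analysis $\alpha/m$; cross-environment further $/25$; score evaluation $0.05/25/2$ |

The $t$ rather than normal reference costs nothing at biobank $n$ and is
correct at the hundreds-of-samples scale of simulation fixtures. Listwise
deletion is per SNP, not global: each SNP uses every sample complete for
that SNP, exposure, phenotype and covariates, so complete-case $n$ (and
slightly, allele frequencies) may differ across SNPs and exposures — the
behaviour of per-variant regression scans generally.

Allele-coding convention: some scan software counts the minor allele,
some the first bim allele. Interaction *p*-values are invariant to the
flip (the coefficient changes sign), so `read_plink()` defaults to
counting bim A1 and always records the counted allele in the output
(`A1` column); explicitness beats mimicry of any one convention.

# The synthetic cohort generator

`simulate_cohort()` exists so that calibration claims about the scan are
testable: every acceptance property is computed on data whose generative
truth is known.

* **Genotypes** (`simulate_genotypes()`): two haplotypes per sample; each
  haplotype allele is a latent standard normal thresholded at the
  allele-frequency quantile. Within an LD block the latents share a
  factor with weight $\sqrt\rho$, which yields tunable pairwise $r^2$
  without coalescent machinery; across blocks haplotypes are independent.
  Unlinked dosages are exactly Binomial(2, maf), hence in Hardy-Weinberg
  equilibrium. Allele frequencies are uniform on 0.01–0.5 by default, the
  post-QC spectrum. Missingness, when configured, is injected completely
  at random.
* **Exposures** (`env_spec()` / `simulate_environment()`): a latent
  Gaussian combining independent noise, an optional genetic component
  over a causal SNP set (variance share `h2` — environments measured in
  observational cohorts are rarely free of genetic influence, and a
  heritable exposure turns apparent GxE partly into GxG), and an optional
  measured-confounder component (`confounder_share`, used to build the
  confounding scenarios). Ordinal and count types are equal-frequency
  quantile bins of the latent, coded from 0 — mirroring graded
  questionnaire responses analysed as continuous. Coefficients are not
  invariant to the 0- vs 1-based coding choice but the interaction test
  is, being invariant to affine shifts of $E$ when the full design is
  used.
* **Phenotype** (`simulate_phenotype()`): built exactly from the model
  above with configured coefficients; noise is
  $\mathcal N(0, \sigma^2 e^{\theta E_i})$. The multiplicative-in-$E$
  variance is the standard inflation-inducing form and reduces to
  homoscedasticity at $\theta = 0$. The default output is the continuous
  linear outcome; `phenotype = "likert12"` rank-bins it into 13
  equal-frequency integer levels 0–12, reproducing a 12-item sum-score
  scale. Equal-frequency binning is the least-assumption choice for a
  scale with no published generative model; it is a display transform,
  and the calibration studies use the linear outcome that the fitted
  model actually describes.
* **Covariates**: an age analogue ($\mathcal N(57, 8^2)$, a typical adult
  cohort), a Bernoulli(½) sex indicator, standard-normal PC-like columns,
  and one-hot assessment-centre indicators (first centre as reference).
* **Split**: `split_holdout()` reserves a disjoint prediction sample;
  score weights carry the training ids, and `evaluate_prs()` refuses any
  hold-out overlap (leakage guard by construction).

What the generator does **not** emulate: realistic human LD maps and
recombination, imputation uncertainty (hard calls only), relatedness,
population structure beyond independent PC-like covariates, and
informative missingness. Passing calibration tests on this bench
therefore shows the *statistical machinery* is correct under the stated
model; it does not certify behaviour under, say, cryptic relatedness.

# Polygenic score evaluation

Score SNP sets are clumped index SNPs at each grid threshold; weights are
GWAS main-effect betas (`PRS`, `iPRS_G`) or interaction betas from the
scan (`iPRS_GxE`, `iPRS_G_plus_GxE`). The main-effect PRS used as a
covariate in interaction-score evaluation comes from the GWAS, not from
the interaction scan's main-effect columns: a SNP set pruned on
interaction p-values under-represents main-effect variance, which would
flatter the iPRS. Missing dosages in scoring are imputed as
$2\times$ the training-set effect-allele frequency (the standard scoring
default). The exposure enters the evaluation model untransformed,
matching the scan convention.

Predictive ability is $\Delta R^2_{adj}$, full minus covariate-only
model, using $1-(1-R^2)(n-1)/(n-p-1)$; the adjustment makes the null
increment mean-zero (it can be negative) rather than mechanically
positive. Significance is the 1-df nested-model F-test, judged at
$0.05/25/2$ in the cross-environment design. The best threshold is the
$\Delta R^2_{adj}$ argmax, ties to the smallest threshold.

# Numerical choices and degenerate inputs

* Least squares via QR; rank deficiency (monomorphic SNP, constant
  exposure after listwise deletion, collinear covariates, fewer complete
  cases than columns) raises a typed condition; genome-wide scans catch
  it and skip the SNP with a logged reason rather than aborting.
* The sandwich is computed as $R^{-1}R^{-T}$ from the QR factor times the
  $X'\mathrm{diag}(e^2)X$ meat, then symmetrised; tests verify agreement
  with the dense triple product to 1e-10 and with an established
  reference implementation.
* Clumping ties on equal p-values break by (chromosome, position), then
  SNP id, so results are independent of input row order. The window is
  ±`window_kb` around the index SNP. LD $r^2$ is squared Pearson
  correlation of dosages over pairwise-complete samples; a constant
  column yields `NA` and cannot clump. The looser $r^2<0.8$ reporting
  convention uses the same window for consistency.
* An exactly zero coefficient tests as $t = 0$, $p = 1$, even when the
  residual SE is also zero.
* Missing values are `NA` throughout — never a numeric sentinel; PLINK's
  2-bit missing code maps to `NA` on read and back on write.
* Summary-statistics files store full double precision (p-values in
  scientific notation below 1e-4) so write–read round-trips are exact.
* One master seed drives fixed per-stage streams (genotypes,
  environments, phenotype, hold-out split), so any stage is
  independently reproducible and a config reruns byte-identically.
* "None of the above" co-endorsed with substantive options is rejected as
  inconsistent rather than silently ignored: silent repair would hide a
  data problem inside a sum score.

# Problem sizes used by the test suite

Calibration properties are exercised at sizes chosen to make their Monte
Carlo error small relative to the tested effect: the heteroscedasticity
study at $n = 5{,}000$ samples × 2,000 SNPs ($\theta = 0.5$); confounder
control over 400 replicates at $n = 2{,}000$; estimator unbiasedness over
200 replicates at $n = 50{,}000$; null-uniformity (Kolmogorov–Smirnov) on
2,000 SNPs at $n = 1{,}000$; score-evaluation null calibration over 40
replicates (1,000 train / 500 hold-out) and interaction-variance recovery
at 20,000 train / 10,000 hold-out with a planted effect whose partial
interaction variance, $\beta_{GxE}^2 \cdot 2f(1-f)$ at $f = 0.3$, is set
near 2% of phenotype variance. The full suite runs in about a minute on
one core.

# Known limitations

Hard-call genotypes only (no dosage/BGEN input); no mixed-model or
relatedness correction; single-environment models (no joint
multi-exposure or 2-df joint SNP+interaction tests); no shrinkage-based
score construction. These are deliberate scope boundaries, not oversights:
the package implements the per-SNP robust interaction scan and its score
pipeline, and stops there.
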