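# spatGBLUP

Genomic prediction for plant-breeding field trials with parametric spatial
kernels.

Field heterogeneity — soil gradients, moisture, tillage artifacts — makes
neighbouring plots more alike than distant ones and contaminates the
estimation of breeding values, especially in modern trials where most test
genotypes occupy a single plot and only check genotypes are replicated.
`spatGBLUP` fits the genomic and spatial components *simultaneously* in
one linear mixed model,

    y = mu + Z g + s + r,    g ~ N(0, K sigma2_g),
                             s ~ N(0, S sigma2_s),
                             r ~ N(0, I sigma2_r),

where `K` is the additive (VanRaden Method 1) relationship matrix built
from SNP dosages and `S` is a parametric spatial correlation kernel over
inter-plot distances in meters: Power `theta^D` (the distance-based
generalization of AR(1)), Gaussian `exp(-D^2/phi^2)`, or Spherical
(compactly supported). Kernels can be isotropic or Range/Column
directional, and random Range/Column effects can be added for extraneous
(operational) variation. Variance components are estimated by REML with
Fisher scoring; the best spatial structure is chosen by 10-fold
cross-validation over genotypes, repeated 5 times, using prediction RMSE,
with a variance-component likelihood-ratio test (thresholds 2.706 / 4.605
at alpha = 0.1 for 1 / 2 added components) and Cullis generalized
heritability reported alongside. A simulation framework generates field
trials with controlled genotypic/spatial/residual variance partitions to
study when spatial modelling improves the accuracy of estimated genotypic
effects.

Intended users: quantitative geneticists and breeding-program analysts
running genomic selection on gridded field trials.

## Worked example

Simulate a trial on the built-in 829-genotype layout (884 plots, 11
replicated checks, plot dimension 2 x 1 m) with a strong smooth field
trend, then compare the base GBLUP model against the matched spatial
model on recovery of the true genotypic effects:

```r
library(spatGBLUP)

cfg <- sim_config(genotypic_ratio = 0.3, fra_sp = 0.9,
                  family = "gaussian", param = 60.5,
                  scenario = "checks_only", seed = 11)
sim <- simulate_trial(cfg)
tab <- evaluate_models(sim, candidates = list(
  base     = NULL,
  gaussian = list(family = "gaussian", direction = "isotropic",
                  param = 60.5)))
tab[, c("model", "rmse_g", "cor_g", "s2_g", "s2_s", "s2_r")]
#>      model    rmse_g    cor_g      s2_g     s2_s      s2_r
#> 1     base 0.6470427 0.767039 0.8171074       NA 0.8350949
#> 2 gaussian 0.4542754 0.899818 0.8192702 3.056604 0.3629272
```

The spatial model recovers the true genotypic effects with accuracy 0.90
versus 0.77 for the base model — a relative accuracy gain
`(0.900 - 0.767) / (1 - 0.767)` of about 57% for this draw — and its
variance components sit near the generating values (sigma2_g = 1,
sigma2_r = 0.233; at phi = 60.5 the realized field trend is nearly
confounded with the intercept, so sigma2_s is estimated with large
seed-to-seed spread).

Fitting a single model directly, and testing the spatial component:

```r
fit_base <- gsreml(sim$trial, "y")
ker      <- sim$kernel
fit_sp   <- gsreml(sim$trial, "y", spatial = ker)
lrt(fit_sp, fit_base, extra_df = 1)
#> Variance-component LRT: chi2 = 300.9750 (df = 1), threshold 2.706 at alpha = 0.1 -> significant
#>   mixture p-value (0.5 chi2(0) : 0.5 chi2(1)): 1.01e-67
```

For real data the entry point is `analyze_trial()`: it reads a per-plot
trial table (`read_trial()`) and marker kinship (`read_markers()` +
`vanraden_kinship()`), drops missing values, matches genotypes, screens
outliers (|residual| > 2.5 SD under the base model), searches kernel
family x direction x parameter by repeated CV, optionally extends the
winner with Range/Column effects, and writes genotype BLUPs, plot-level
spatial BLUPs, the CV table and a selection summary as CSV/text.

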