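---
title: "Spatial kernels in genomic prediction: models, tuning and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial kernels in genomic prediction: models, tuning and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatGBLUP)
```

## The problem

Breeding trials evaluate hundreds of genotypes on field plots laid out on a
grid of Ranges (North--South) and Columns (East--West). Soil and
topographic gradients make neighbouring plots more alike than distant ones;
this *spatial* variation masks genotypic differences and distorts breeding
value estimates, particularly when most test genotypes are unreplicated and
only a handful of check genotypes recur across the field. Genomic selection
(GBLUP) shares information across related genotypes through a marker-based
relationship matrix, but its residuals still carry the field trend.
`spatGBLUP` fits the genomic and spatial components *simultaneously* in one
mixed model and asks, by cross-validation, whether the spatial component
actually improves prediction.

## Models

The base model for a trait vector $y$ over $n$ plots is

$$ y = \mu\,1 + Z g + r, \qquad g \sim N(0, K\sigma^2_g), \quad
   r \sim N(0, I\sigma^2_r), $$

with $Z$ the plot-to-genotype incidence matrix and $K$ the additive
(VanRaden Method 1) relationship matrix. The spatial model adds a
plot-level random field $s \sim N(0, S\sigma^2_s)$ whose correlation
matrix $S$ is a parametric function of inter-plot distance:

* **Power** $\theta^{D}$, $0 < \theta < 1$ — the generalization of AR(1)
  to unequally spaced plots (and exactly AR(1) with $\rho = \theta$ on a
  unit-spaced transect);
* **Gaussian** $\exp(-D^2/\phi^2)$ — slow initial decay, then a rapid
  drop; adjacent plots are forced to be very similar;
* **Spherical** $1 - 1.5(D/\phi) + 0.5(D/\phi)^3$ for $D \le \phi$, and
  exactly $0$ beyond — compact support.

Distances are in meters and respect the physical plot dimension
(length $\times$ width): the Range component of a distance is
$|\Delta\text{range}| \times \text{width}$, the Column component
$|\Delta\text{col}| \times \text{length}$, and the isotropic distance is
their hypotenuse. Directional (Range-only or Column-only) distances model
anisotropic trends. A third model layer adds i.i.d. random Range and/or
Column effects for *extraneous* variation — discontinuities from field
operations (tillage, ridging) that a smooth kernel cannot follow.

The Gaussian formula deliberately uses $\exp(-D^2/\phi^2)$, with no factor
2 in the denominator; $\phi$ values are therefore directly comparable
across the package's grids and its simulator.

## REML solver

Variance components are estimated by restricted maximum likelihood with
the intercept profiled out. The criterion is
$-\tfrac12[(n-1)\log 2\pi + \log|V| + \log(1'V^{-1}1) + y'Py]$ with
$V = \sigma^2_g ZKZ' + \sigma^2_s S + \dots + \sigma^2_r I$. Updates are
Fisher scoring (expected information) with step-halving whenever a step
would decrease the criterion. Numerical policies, all of which matter in
routine use:

* **Non-negativity.** Proposals below $10^{-9}\,\mathrm{var}(y)$ are
  projected to that floor; a component held at the floor for three
  consecutive iterations is declared a *boundary* solution and reported as
  exactly 0 with a flag. Boundary spatial or residual variances are
  expected behaviour when the true component is near zero, not failures.
* **Convergence** when the criterion changes by less than $10^{-6}$
  (at most 100 iterations); non-convergence is reported, never hidden, and
  cross-validation discards such fold-fits and counts them.
* **PSD repair.** Directional kernels repeat rows across plots that share
  a Range or Column and can be numerically indefinite; if the smallest
  eigenvalue of a kernel is below $-10^{-8}$, jitter
  $\delta = |\lambda_{\min}| + 10^{-8}$ is added and the matrix rescaled
  to unit diagonal.
* **Degenerate input.** A constant response returns the obvious fit (mean,
  all components 0) rather than iterating on a singular surface.
* Expected-information traces are computed from elementwise products of
  $P V_i$, so one iteration costs a Cholesky factorization, one inversion
  and one matrix product per non-residual component.

BLUPs come from the mixed-model equations. Genotypic BLUPs are produced
for *every* genotype in $K$ — genotypes without phenotypes are predicted
through the kinship — and spatial BLUPs for every plot covered by the
kernel, so a held-out plot's spatial effect is its kriging prediction
given the training plots. The prediction-error variance-covariance matrix
of the genotypic BLUPs feeds the Cullis generalized heritability
$h^2 = 1 - \bar V_\Delta / (2\sigma^2_g)$, computed over all genotype
pairs (feasible to a few thousand genotypes).

## Model selection

Candidate kernels (family $\times$ direction $\times$ standardizing
parameter) are compared against the base model under one shared
cross-validation plan: genotypes are partitioned into 10 folds, 5
independent repeats (defaults), and all plots of a genotype follow it into
its fold, so training and test sets never share a genotype. The selection
criterion is the mean prediction RMSE on held-out plots; prediction
accuracy (pCOR) is reported but never drives selection. Exact pRMSE ties
go to the higher pCOR, then to the base model, then to the smaller
standardizing parameter. The standardizing parameter is selected on the
same CV surface as the family and direction — there is no nested CV, which
makes the reported predictability of the *winning* candidate mildly
optimistic; the package therefore also reports a full-data
likelihood-ratio test of the best spatial candidate against the base
model. The LRT uses the plain upper-10% chi-square critical values (2.706
for one added component, 4.605 for two); because the null puts the
variance component on the boundary, the statistic actually follows the
mixture $\tfrac12\chi^2_0 : \tfrac12\chi^2_{df}$, whose p-value is
reported alongside. The plain thresholds are the more conservative
convention and drive the significance flag. Degenerate candidates (a
Range effect in a single-Range field) are skipped with a warning; fold
fits that fail are trapped and counted, and a model with more than half
its folds failed is rejected outright.

Whether the parameter should be refit within each fold is a genuinely
open design point; refitting per fold would make each candidate a
different *procedure* rather than a named kernel, so the package keeps
the parameter fixed per candidate, matching how the candidates are
tabulated and reported.

Default parameter grids: $\theta \in \{0.1, \dots, 0.9\}$ for Power; for
Gaussian and Spherical, 10 values log-spaced between the smallest nonzero
and the largest inter-plot distance, so the grid adapts to the field
extent. Users can (and for large searches should) supply their own grids.

## What the simulator emulates

`default_layout()` is a synthetic stand-in for a large single-field trial:
829 genotypes of which 11 are replicated checks, on a 26 $\times$ 34 grid
(884 plots; 818 unreplicated test genotypes, 6 plots per check spread
evenly in serpentine order), plot dimension 2 $\times$ 1 m so that
adjacent Ranges are closer (1 m) than adjacent Columns (2 m). The exact
coordinates of the field that motivated this design are not published;
any user layout is accepted wherever a layout is taken.

`simulate_trial()` draws genotypic effects i.i.d. $N(0,1)$ — deliberately
*without* a relationship matrix, so genomic information cannot compensate
for spatial noise — and partitions the error variance by two dials: the
genotypic ratio $h$ sets the total error variance $(1-h)/h$, and `fra_sp`
splits it between a spatially correlated field (drawn from the configured
kernel on the isotropic distance matrix) and i.i.d. residual. Both dials
default to the central value 0.5 and are studied over
$\{0.3, 0.5, 0.7, 0.9\}$; generating kernels default to Power
$\theta \in \{0.2, 0.5, 0.8\}$ and Gaussian
$\phi \in \{0.5, 10.5, 30.5, 60.5\}$, endpoints chosen to span
near-identity through field-wide correlation. Three replication scenarios
(checks only, half the test genotypes duplicated, all duplicated) append
extra plots in fresh Ranges. Simulated fits are scored by the recovery of
the *true* genotypic effects (RMSE and correlation), the quantity a
breeder ultimately cares about, with 20 replicates per grid cell by
default.

What the simulator does **not** emulate: marker genotypes and linkage
disequilibrium (the simulated $g$ are exchangeable), genotype-by-
environment interaction, non-Gaussian traits, missing plots, and real
fields' irregular boundaries. Passing simulation-based checks therefore
says the machinery is correct and the spatial kernel is worth fitting when
smooth field trends exist; it does not by itself certify gains on any
particular real field.

## Calibration of the selection step

Selection by "lowest CV pRMSE over a grid of candidates" is an *argmin
over correlated noisy estimates*, and its null behaviour (how often a
spatial candidate displaces the base model when no spatial effect exists)
depends on the field size and the number of candidates. On small fields
(around 100--300 plots) a realized i.i.d. noise field can carry chance
local correlation that cross-validation legitimately detects *within that
dataset*, so a spatial candidate wins a nontrivial share of null searches
even though the likelihood-ratio test stays correctly calibrated (about
its nominal level against the 2.706 threshold). This is a property of the
selection criterion itself, shrinking with field size as chance
correlation fades; the package keeps the LRT alongside the CV winner
precisely so that users can distinguish "predictively useful in this
field" from "statistically demonstrable spatial variance". The package's
own calibration checks measure both rates on simulated null fields; test
problem sizes (a few hundred plots, reduced candidate grids) are chosen to
keep the checks at desk scale.

## Analysis pipeline defaults

`analyze_trial()` chains the preprocessing exactly as a breeder would run
it per trait: drop missing values, match genotypes to the kinship (the
count of unmatched plots is reported), fit the base model, then remove
outlier plots whose base-model residual exceeds 2.5 sample standard
deviations — a single screening pass with strict inequality, applied
before any spatial structure is entertained, because isolated gross
errors masquerade as local spatial dependency. Matching precedes outlier
screening so the screened fit uses exactly the data that later models see.
All file outputs are delimited text plus a manifest echoing the seed and
settings, sufficient to reproduce a run exactly.
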