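---
title: "Environment types and adaptation zones for multi-environment trials"
author: "metzones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment types and adaptation zones for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metzones)
```

## The problem

Breeding programs test candidate genotypes in networks of field trials
spanning many locations and years.  Genotype-by-environment interaction
(G×E) — changes in genotypic differences and rankings across environments —
complicates selection: when G×E is large, a single "best" variety for the
whole target population of environments (TPE) may not exist.  Part of G×E
is *predictable*: it repeats across years for a given location because it is
driven by stable geographic factors (soil, photoperiod, endemic disease
pressure).  If locations can be grouped into **adaptation zones** such that
most genotype-by-location interaction acts *between* zones, selecting within
zones increases genetic gain.

`metzones` implements a two-step procedure for finding such zones:

1. classify trials (location–year combinations) into **environment types
   (ETs)** with a multi-layer self-organizing map (SOM) trained on
   within-trial standardized genotype performance (and, optionally,
   secondary traits, binary stress scores and crop-model environmental
   indices);
2. group geographic clusters of trials into **adaptation zones** by
   hierarchical (Ward) clustering on chi-square distances between their
   ET frequency profiles across years.

The derived zones are then *evaluated* with weighted-REML mixed models:
how much genotype-by-location variance the zones capture, how much
prediction accuracy they add in leave-one-year-out cross-validation, and
whether selecting within zones beats selecting across the undivided TPE
(the CR/DR ratio).

## Stage 0: per-trial adjusted means

Each trial is analysed with the row–column spatial model

$$y_{irc} = \mu + R_r + C_c + G_i + \varepsilon_{irc},$$

with fixed genotype effects $G_i$, random row and column effects
($\sigma^2_r$, $\sigma^2_c$), and a residual with separable AR1×AR1
correlation $\rho_{row}^{|\Delta r|}\rho_{col}^{|\Delta c|}$
(`fit_trial_model()`).  The generalized-least-squares genotype estimates
(BLUEs) and their standard errors are carried forward; every downstream
weighted analysis uses $w = 1/\mathrm{SE}^2$.

Numerical choices: variance parameters are optimized on log/atanh scales so
the restricted likelihood is smooth near boundaries; convergence is a
relative change below 1e-8 with at most 200 gradient iterations (after a
Nelder–Mead warm-up); variances below 1e-10 are reported as 0 and flagged.
Missing plots are dropped and the AR1 correlations are computed from the
observed coordinates by distance-powered correlation.  A separate
measurement-error ("nugget") variance is off by default — the single
spatially correlated residual is the leaner model and the two are hard to
separate on small layouts — and can be switched on with `nugget = TRUE`.

## Stage 1: multi-layer SOM

### Data preparation

Trait tables (trials × genotypes) are completed by **additive imputation**
(`impute_additive()`): least-squares genotype + environment fits fill the
missing cells, observed cells are untouched, and the operation is
idempotent.  Each row (trial) is then standardized to mean 0, sd 1
(`scale_rows()`, sample sd).  Scaling focuses the classification on
genotypic contrasts *within* trials rather than on environmental main
effects.  The order matters — imputation uses the raw additive structure,
so the pipeline always imputes first; imputed values feed only the SOM,
while mixed models use the original data with weights.

### Layers, distances, weights

Data enter the SOM as a `layer_stack()`: named object × variable matrices
over a common trial index, each with a metric and a nonnegative weight.
Two arrangements are supported:

* **one layer per trait** (`build_trait_layers()`): each layer is trials ×
  genotypes; the default weights follow the convention of weighting the
  target trait highest (yield 3, oil 2, flowering 1, binary incidence 1);
* **one layer per genotype** (`build_genotype_layers()`): each layer is
  trials × traits, treating each genotype as a bio-assay of environment
  quality.  Genotype layers are weighted by their contribution to G×E —
  the genotype interaction sums of squares of an AMMI-2
  (`genotype_weights_from_ammi()`), i.e. the squared biplot vector lengths
  under genotype scaling.  A binary incidence layer gets the mean genotype
  weight.

Quantitative layers use the sum-of-squares distance; the binary incidence
layer is one-hot encoded (high, low) and uses the Tanimoto distance
$1 - x'p/(x'x + p'p - x'p)$, so a continuous prototype can represent a
unit's incidence mixture.  The combined distance is
$\sum_l w_l d_l / m_l$, where $m_l$ is the layer's variable count: dividing
by the width makes a user weight of 3 on a 22-column trait layer comparable
with a weight of 1 on a 2-column binary layer.  The combination is
invariant to layer order and to common rescaling of all weights.

### Training

`train_som()` fits a rectangular grid (default 5×5 — large enough to
resolve structure without empty units on networks of ~200 trials) of
multi-layer prototypes.  Batch mode is the default: each epoch assigns all
objects to their closest prototype and replaces each prototype by the mean
of objects assigned within the current neighbourhood radius; the radius
shrinks linearly to 0 over `rlen` epochs, so training ends with exact
k-means (Lloyd) updates under the combined distance, and the quantization
error is then non-increasing.  Batch mode is order-independent, hence
reproducible given the seed, which controls only the initial sample of
objects used as prototypes.  Online mode (per-presentation updates with a
learning rate declining linearly from 0.05 to 0.01) is available for
completeness.  The bubble neighbourhood (uniform within the radius, initial
radius the 2/3 quantile of inter-unit distances) is the default; ties in
the winner search break to the lowest unit index for determinism.
Hexagonal and toroidal topologies are reserved keywords, not implemented.

### From units to environment types

`cluster_prototypes()` clusters the trained prototypes hierarchically under
the same weighted combined distance and cuts at `k_et` clusters (default
6); trials inherit their winning unit's ET.  Ward linkage is the default
for consistency with the zoning step; it is exposed as an argument.

## Stage 2: adaptation zones

Trials are first grouped geographically (`geo_cluster()`): a SOM on two
single-variable layers (latitude, longitude, equal weights), with the grid
dimensioned as the most-square factorization of the requested cluster
count; occupied units are the geographic clusters.  ET counts per cluster,
pooled across years, form the frequency table (`et_frequency()`).
Chi-square distances between cluster profiles,

$$d^2(a, b) = \sum_j (p_{aj} - p_{bj})^2 / m_j,$$

with $m_j$ the overall ET mass (the correspondence-analysis convention;
plain profile differences are available via `weighting = "none"`), feed
Ward clustering cut at `k_zones` (default 4) in `cluster_zones()`.  With
equal masses the distance reduces to a scaled Euclidean distance on
profiles.  `hclust`'s `ward.D2` is used since the input is a distance, not
a squared distance.

Zone assignments from different runs are compared with per-zone **balanced
accuracy** (`balanced_accuracy()`): for reference zone $a$, with $A$ trials
in both, $B$ in the reference only, $C$ in the alternative only and $D$ in
neither, the score is $(A/(A+C) + D/(B+D))/2$.  Because zone labels are
arbitrary, labels are first aligned by the one-to-one matching that
maximizes total overlap (exhaustive over permutations, feasible for the
handful of zones used here).

## Evaluating zones with weighted REML

`reml_fit()` implements restricted maximum likelihood for crossed
random-effect structures with the **two-stage residual convention**: the
residual covariance is fixed at $\mathrm{diag}(1/w)$ with scale 1, the
first-stage standard errors carrying the within-trial error.  The model
wrappers are:

* `fit_model2()` — G, G×L, G×Y, G×L×Y (the two-way decomposition whose
  component shares `percent_gxe()` reports);
* `fit_model4()` — G + G×E benchmark;
* `fit_model5()` — genotype-by-zone effects with an *unstructured* zone ×
  zone covariance $\Sigma_z$ (borrowing information between zones) plus
  residual G×E;
* `fit_model6()` — G, G×Z, G×L(Z), G×Y, G×Z×Y, G×L(Z)×Y, the ingredients
  of the selection-response comparison; `gz_share()` reports
  GZ/(GZ + GL(Z)), truncated at two decimals as such shares are
  conventionally printed.

Variances are maximized by L-BFGS-B with analytic gradients
($-\tfrac12(\mathrm{tr}(PA_k) - y'PA_kPy)$) and a bound at zero; if the
line search stalls near the optimum the fit is polished derivative-free.
$\Sigma_z$ is parameterized by its Cholesky factor (positive semidefinite
by construction) with analytic gradients $(T - Q)L$ in the trace and
quadratic-form matrices, and three seeded restarts guard against local
optima.  Component standard errors come from the inverse Fisher
information $I_{jk} = \tfrac12\mathrm{tr}(PA_jPA_k)$ (not computed for the
unstructured block).  The response is standardized internally so the
optimizer is well conditioned; components are reported on the original
scale.  Boundary estimates are flagged rather than silently truncated,
since published tables show exact zeros with absent standard errors for
such components.

`factorial_regression_scan()` screens environmental covariables one at a
time with a random genotype intercept plus a random genotype slope on the
unit-variance-scaled covariable (residual free, unweighted).  The slope
variance is tested against the no-slope null with a likelihood-ratio test
referred to the 50:50 mixture $\chi^2_0/\chi^2_1$ — the standard reference
for a variance tested on its boundary.  Covariables are ranked by residual
variance; `forward_select()` repeats the scan conditioning on already
selected slopes until nothing passes (default $\alpha = 0.05$).  The
manual, physiology-guided pick among the top candidates used in practice
is replaced by the automatic best-by-residual-variance rule; the scan
table is returned so a user can override.

`loyo_cv()` runs leave-one-year-out cross-validation: models 4 and 5 are
fitted without one year; per held-out trial, the genotype main-effect BLUP
(model 4) and the zone-specific genotype BLUP (model 5) are correlated
with the observed values (Pearson).  Trials with fewer than three observed
genotypes, or constant predictions, get NA.

## Correlated vs. direct response

From the model-6 components,

$$\rho_g = \frac{\sigma^2_g}{\sqrt{\sigma^2_g(\sigma^2_g + \sigma^2_{gz})}},
\qquad \mathrm{CR/DR} = \rho_g\sqrt{H^2_{U}/H^2_{D}},$$

with line-mean heritabilities

$$H^2_{U} = \frac{\sigma^2_g}{\sigma^2_g + \frac{\sigma^2_{gz}}{nz}
  + \frac{\sigma^2_{gl(z)}}{nl\,nz} + \frac{\sigma^2_{gy}}{ny}
  + \frac{\sigma^2_{gzy}}{ny\,nz} + \frac{\sigma^2_{gl(z)y}}{nl\,nz\,ny}},
\qquad
H^2_{D} = \frac{\sigma^2_g + \sigma^2_{gz}}{\sigma^2_g + \sigma^2_{gz}
  + \frac{\sigma^2_{gl(z)}}{nl} + \frac{\sigma^2_{gy}}{ny}
  + \frac{\sigma^2_{gzy}}{ny} + \frac{\sigma^2_{gl(z)y}}{nl\,ny}}.$$

CR/DR below 1 favours subdividing the TPE.  The design constants $nl, ny,
nz$ are medians over genotypes of the numbers of locations per zone, years
and zones in which each genotype was present (`median_counts()`); the
*lower* median is used for even counts since these are integer-valued
design constants.  CR/DR is invariant to a common rescaling of all six
components, $\mathrm{CR/DR} \ge 1$ whenever
$\sigma^2_{gz} = \sigma^2_{gzy} = 0$, and it decreases strictly in
$\sigma^2_{gz}$.

```{r crdr-example}
si <- selection_inputs(var_g = 4, var_gz = 2, var_glz = 2, var_gy = 1,
                       var_gzy = 1, var_glzy = 2, nl = 2, ny = 2, nz = 2)
cr_dr(si)
```

## The synthetic trial network

`simulate_met()` generates networks with exactly the structure the models
assume: trait values decompose as trial intercept + G + G×Z + G×L(Z) +
G×Y + G×Z×Y + G×L(Z)×Y, all i.i.d. normal with configured variances, plus
either a trial-level error of variance `var_plot / n_replicates` (with the
matching weights) or full row–column plot fields with random row/column
effects and AR1×AR1 spatial noise (`simulate_trial_plots()`).  Locations
carry coordinates clustered by zone in a Europe-like latitude/longitude
box, binary incidence is Bernoulli with zone-specific probabilities (a
decreasing gradient by default, mimicking a geographically structured
parasite pressure), secondary traits share correlated genotype main
effects via a user correlation matrix, and an optional
missing-completely-at-random rate masks trial × secondary-trait
combinations, reflecting the unbalanced trait coverage typical of real
networks.  Trial intercepts, fixed effects in the analysis, are drawn from
a wide normal because a simulation needs a distribution for them.  All
randomness derives from one integer seed through R's default
Mersenne–Twister generator.

The defaults mirror a European sunflower-scale network — 22 genotypes,
4 zones × 5 locations × 7 years, yield-like components of a few thousand
(trait units²) proportioned like published zone-nested yield analyses.
What the generator does **not** emulate: diagonal check plots, spatial
trends beyond AR1×AR1, informative missingness, year-to-year covariance
of incidence, or any crop-physiology link between covariables and yield
(period summaries of supplied daily weather are provided by
`simulate_covariables()`, but generating weather is out of scope).
Passing tests on this generator therefore demonstrates correctness of the
estimation and classification machinery under the assumed model, not
robustness to real-data pathologies such as non-normal effects or
systematic layout artefacts.

## Problem sizes and reproducibility

The test-suite and acceptance computations use deliberately compact
designs chosen to keep Monte-Carlo error informative: recovery of
variance components uses 20 genotypes × 15 locations × 5 years (1,500
genotype–trial observations); the classification and cross-validation
scenarios use 15 genotypes over 4 zones with strong genotype-by-zone
variance, where zone recovery and the model-5 accuracy advantage are
clear-cut.  Every simulation, SOM initialization and optimizer restart is
seeded; batch SOM training and the zoning chain are deterministic given
their inputs.

## Known limitations

* The REML engine builds dense n × n covariance matrices; it is
  comfortable to a few thousand observations, not for very large networks.
* Only the model structures above are provided — no general covariance
  DSL, no genomic relationship matrices, no multi-trait selection indices.
* `geo_cluster()` works on raw coordinates with equal layer weights; very
  anisotropic geographies may warrant pre-scaling.
* Automatic layer-weight optimization is deliberately absent: weights are
  scientific choices, exposed as configuration.
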