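---
title: "Methods: spatial immune exclusion scoring and the three-stage prognostic gene screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune exclusion scoring and the three-stage prognostic gene screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`vistamm` implements two linked analyses of myeloma bone marrow:

1. **Spatial arm** — multiplex-immunofluorescence images (channels DAPI,
   CD138, CD8, CD11b, VISTA, plus an optional autofluorescence channel) are
   normalized, segmented into tumor and stroma compartments and into single
   cells, and phenotyped; per-patient compartmentalized densities feed the
   *VISTA-associated T-cell exclusion* score, whose median split is compared
   by Kaplan–Meier, log-rank and Cox analysis.
2. **Screening arm** — a three-stage prognostic screen over immune-related
   gene lists in log2 expression cohorts: list-level ridge-penalized Cox
   with nested cross-validation, per-gene Cox in discovery and validation
   cohorts, and a multivariate second validation with ISS stage and a
   time-dependent autologous-transplant covariate; Holm correction at every
   stage.

A synthetic-data module generates ground-truthed images and simulated
cohorts with the statistical structure both arms assume, so every stage is
testable without clinical data.

# Image pipeline

## Model and parameters

The pipeline is a deterministic function of the image and a
`pipeline_params()` object. The defaults implement the standard analysis:

* foreground where any normalized channel exceeds **0.2**, keeping only
  8-connected components strictly larger than **5000 px²** (293 µm² at the
  0.2421 µm pixel edge; `px2_to_um2()` ties the two scales together);
* tumor where the **10 px** Gaussian-smoothed CD138 channel exceeds **0.2**
  inside the foreground, with the same component-size rule applied to both
  compartments (small islands are reassigned to the other compartment so
  tumor and stroma always partition the foreground);
* nuclei from background-corrected raw DAPI, Otsu-thresholded (an absolute
  threshold can be supplied), split by a watershed on the Euclidean
  distance transform;
* cells as Voronoi regions of the foreground seeded by nucleus regions
  (exact nearest-region Euclidean assignment; equidistant ties go to the
  lowest label, so the map is deterministic and reproduces a brute-force
  per-pixel nearest-seed search exactly);
* phenotyping of cells with area in the closed interval **[500, 5000] px²**
  by mean normalized intensity with strict thresholds **0.5** for CD138 and
  **1.5** for CD8, CD11b and VISTA; compartment membership follows the
  nucleus centroid;
* megakaryocyte exclusion: VISTA-positive regions larger than the upper
  area gate are removed (and counted) before the general gate, so very
  large VISTA-bright cells never enter the density accounting.

## Background correction and normalization

Two design choices deserve a full account because the fixed thresholds
above only mean something relative to them.

**Background.** The default background estimator fits a quadratic surface
by least squares to *signal-free* pixels. Signal-free support is identified
jointly across channels: each channel is scaled by its 99th percentile, the
pixelwise maximum over channels is taken, and pixels in the lowest
`dark_quantile` (default 0.35) of that maximum form the support. The joint
criterion matters: a broad smooth carpet (autofluorescence over an
elliptical tissue section) is indistinguishable from a smooth background
field within its own channel, but tissue-free margins are dark in *every*
channel. Consequently the imaged field must retain roughly a third of its
area free of tissue; fields completely covered by tissue are outside the
estimator's assumptions. When only a single channel is available (nucleus
segmentation corrects raw DAPI on its own) an iterative scheme is used
instead: two passes keep only pixels at or below the current fit (which
rapidly expels blobs pulling the fit upward), then two passes keep
everything within two robust SDs of the negative residuals, recentering the
fit on the noise rather than its lower envelope. On a channel that is
exactly a polynomial field either path reproduces it to machine precision,
which is why a pure-background image normalizes to (numerically) zero. A
morphological top-hat (`background_method = "tophat"`) is available as an
alternative; it cannot achieve the exact-polynomial property and is not the
default.

**Normalization scale.** After subtraction and clipping at zero, each
channel is divided by the `norm_quantile` (default 0.5) quantile of the
corrected pixels above a noise floor (five robust SDs estimated from the
*negative* correction residuals, which signal cannot touch). The intent is
to pin the *dim, nonspecific* signal population near 1: the 0.2 foreground
threshold then sits above noise but below any real signal, and the 1.5
phenotype threshold separates specific bright staining from nonspecific
dim staining. A high quantile (e.g. 0.99) fails this purpose whenever
specifically stained cells exceed 1% of a channel's signal pixels — the
scale then pins *inside* the bright population and maps bright-cell means
to ≈1, making a 1.5 threshold unreachable — so the median of the
above-floor population is used; it is robust while specific cells are
less than half of a channel's signal pixels. Both the quantile and the
floor rule are configurable. Normalization is exactly invariant to
rescaling a raw channel by a positive constant.

## Spatial metrics

Densities divide phenotype counts by compartment area (mm²); the
phenotypes are the four single markers plus the composite VISTA⁺CD11b⁺
(both markers positive, regardless of others). Nearest-neighbor distances
use cell-area centers, within a compartment, excluding self-pairs, averaged
over source cells. Per patient, densities and distances are averaged
*across image regions first*; ratios are computed on the averages (not
averaged ratios), matching the stated order of aggregation. The
preferential-localization ratio of a phenotype is
(tumor density + ε) / (stroma density + ε) with pseudocount ε = 0.1
cells/mm² (configurable, 0 allowed), which keeps ratios finite and
order-preserving when a compartment holds no cells. The exclusion score is

$$\mathrm{score} \;=\;
\frac{d_{\mathrm{VISTA^+CD11b^+,\,tumor}}+\varepsilon}
     {d_{\mathrm{VISTA^+CD11b^+,\,stroma}}+\varepsilon}\;\times\;
\frac{d_{\mathrm{CD8,\,stroma}}+\varepsilon}
     {d_{\mathrm{CD8,\,tumor}}+\varepsilon}$$

— algebraically identical to the ratio-of-ratios reading with the CD8
tumor/stroma ratio in the denominator. At ε = 0 it is exactly invariant to
a common rescaling of all densities, and swapping the compartments of both
phenotypes maps it to its reciprocal. Patients for whom a constituent
density is undefined in every region receive a missing score and are
excluded (with a logged count) from the survival comparison; there is no
defensible imputation for a compartment that was never observed.

# Survival machinery

Cox models are fit by `survival::coxph` behind `fit_cox()` (Efron ties by
default, Breslow selectable), with Wald 95% intervals on the log scale and
a separation guard on the standardized coefficient scale. Zero-variance
covariates are reported as HR 1, p 1 with a warning rather than an error,
so that a degenerate risk score in a null screen stays interpretable. The
time-dependent transplant covariate uses the counting-process expansion:
each transplanted patient contributes a `(0, t*]` row with indicator 0 and
a `(t*, T]` row with indicator 1; with no transplanted patients this
reduces exactly to the standard fit. Kaplan–Meier and the log-rank test
come from `survfit`/`survdiff`; the median split labels values strictly
above the median `high` and everything else (including ties at the median)
`low`, so an even number of distinct values splits in half. Holm
adjustment is `stats::p.adjust(method = "holm")`; Spearman correlation and
the classic pooled-variance Student t-test (Welch via a flag) wrap
`cor.test`/`t.test`.

# The three-stage screen

**Inputs.** Cohorts are log2 expression matrices with survival tables and a
role: discovery, validation, or second validation. Genes absent from the
annotation, or with log2 expression below 8 in at least half of any single
cohort's patients, are excluded. Batch equalization then rescales every
gene within every cohort to a common per-gene mean (pooled over patients)
and variance (pooled within-cohort), so cohort labels stop predicting
expression.

**Stage 1 (lists).** For each of the seven gene lists, every discovery
patient receives an out-of-sample ridge-Cox risk score from a model that
never saw them: a leave-one-out outer loop; inside it, the ridge penalty λ
is chosen from 25 log-spaced points on [10⁻², 10⁴] by 10-fold
event-stratified cross-validation maximizing the cross-validated partial
likelihood (the full-data log-likelihood at the fold-out estimate minus
the training log-likelihood — the penalty-free criterion; the held-out
linear-predictor alternative was considered and rejected as it conflates
calibration with discrimination). Folds are fixed once per run and keyed to
the sorted patient order, so results are invariant to input permutation and
bit-reproducible given a seed. The vector of out-of-sample scores is tested
against overall survival by univariate Cox (Wald) on the standardized
score — this is the list's discovery p-value; a single model trained on all
discovery patients scores the validation patients for the validation
p-value. Both families are Holm-adjusted over the lists; a list passes when
significant in both sets.

A calibration caveat that users should know: the *discovery* p-value is
anti-conservative under the null. Each left-out patient's risk score is
computed from a model trained on everyone else, so it carries a small
systematic anti-correlation with that patient's own outcome
(pre-validation bias), and because every fold trains on every other fold's
outcomes no cross-fitting variant removes the effect — this is the general
difficulty of significance testing on cross-validated quantities. In
package simulations the null discovery p falls below 0.05 far more often
than 5%, independent of cohort size. The *validation* p-value, computed on
patients the model never touched, is exactly calibrated, and a list only
passes stage 1 when significant in both — so the screen's family-wise
error remains controlled by the validation gate (verified by the
null-screen property test). Treat the discovery p as a ranking/screening
device, not as a calibrated tail probability.

The ridge-Cox core maximizes ℓ(β) − λ‖β‖²/2 (Breslow ties; simulated
times are tie-free, and Breslow is the standard choice in penalized
settings) by Newton iterations with step halving. Genes are standardized
within each fitting set, so coefficients and the reported hazard ratios
are per SD. For the leave-one-out loop the implementation carries warm
starts per (fold, λ) across outer iterations and uses scoring steps with
frozen curvature (falling back to full Newton when they stall); this is an
exact-optimum strategy, verified in the tests against naive per-fold
refits.

**Stage 2 (genes).** Genes of passed lists are tested by per-SD univariate
Cox in the pooled discovery set (Holm over genes); survivors are re-tested
in the pooled validation set (Holm over survivors); and those survivors are
tested in an ISS-stage-adjusted multivariate Cox on the validation set
(Holm). The pooled analysis (rather than per-cohort meta-analysis) is the
default since batch equalization has already placed cohorts on one scale.

**Stage 3 (independent validation).** Stage-2 survivors are tested in the
second validation cohort with gene (per SD), ISS stage, and the
time-dependent transplant indicator; Holm over the tested genes. The final
gene list is monotone in the stages by construction.

# Synthetic data: what it emulates, and what it does not

## Images

The generator renders the structure the pipeline assumes, with exact ground
truth. A smooth wavy-boundary tissue ellipse occupies the image center
(about 55% of the field, leaving the tissue-free margin the background
estimator needs); the tumor is a smooth random blob occupying 40% of the
tissue by default, kept at least 45 px from the tissue boundary so that
tumor cells never sit on the tissue edge. Cells sit on a jittered square
grid (48 px spacing, 3 px jitter; the minimal gap exceeds the cell
diameter, so cells never overlap), classified into compartments by the mask
under them; sites not taken by a requested phenotype become CD138⁺ plasma
cells (tumor) or marker-negative fillers, and a gap-closing pass plants
extra filler sites wherever some tissue pixel is farther than ~1.15 grid
spacings from every site — this bounds every Voronoi region inside the
[500, 5000] px² gate, which is what makes exact noiseless recovery a fair
target. Each cell contributes a truncated-Gaussian DAPI nucleus (σ = half
the nucleus radius, truncated at 3σ), a bright uniform disk (amplitude 8 in
design units) on its positive CD8/CD11b/VISTA channels and a dim
nonspecific disk (amplitude 1) on the others; plasma cells carry a CD138
membrane disk with a brighter nucleus-proximal core (so their mean stays
above the 0.5 threshold even when a Voronoi region runs large), and CD138
carries no nonspecific signal; an autofluorescence channel holds a uniform
tissue carpet. One very large VISTA-bright megakaryocyte (radius 45 px,
with a ring of replacement filler sites around its footprint) is planted in
the stroma by default. A quadratic background field (amplitude 0.3) and
additive Gaussian noise (σ = 0.05, 5% of the nonspecific level) are added,
and fixed per-channel gains exercise the normalization's scale invariance.
All amplitudes were chosen from the threshold geometry (disk-to-region area
ratios against the 0.5/1.5 thresholds) before the test suite was run, and
are part of the package's stated study conditions.

Not emulated: optics (no PSF), spectral bleed-through, real marrow
histology, irregular cell shapes or intensity heterogeneity within a
stain. Passing recovery tests therefore demonstrates the pipeline's
correctness on images satisfying its stated assumptions, not robustness to
arbitrary real-world stain quality.

## Cohorts

Event times follow a proportional-hazards model with exponential baseline
(Weibull optional) with log-hazard linear in the standardized log
exclusion score and/or planted standardized gene expression, plus optional
ISS effects; censoring is independent exponential. The transplant process
is an independent exponential clock whose realization switches the hazard
by the transplant log-HR, so the time-dependent Cox model is correctly
specified. Expression is Gaussian around gene-level means on the log2
scale (a configurable fraction of genes is drawn below the log2 = 8 filter
threshold), and cohorts receive global additive/multiplicative batch
shifts. Defaults (baseline hazard 0.02/month, censoring 0.01/month) give
median survival near three years with roughly 70% events, in the range of
the myeloma cohorts the screen is designed for.

# Numerical choices and degenerate inputs

* Connectivity: 8-connected components; the watershed uses EBImage's
  default line connectivity.
* "Larger than 5000 px²" is strict for foreground/compartment components;
  the phenotyping gate [500, 5000] px² is closed.
* Voronoi ties (exactly equidistant nucleus regions) go to the lowest
  label.
* Cells whose nucleus centroid lands on a removed small component join the
  nearest retained compartment (ties to tumor).
* Median-split ties go to `low`.
* λ-selection ties on the cross-validated likelihood go to the larger
  penalty.
* Ridge Newton tolerance 10⁻⁹ on the penalized log-likelihood (10⁻⁷ inside
  cross-validation, where only the argmax matters); blank DAPI, empty gene
  lists, zero-area compartments, constant covariates and all-equal median
  splits are handled explicitly as documented in the function help.

# Problem sizes used in the shipped tests and scripts

The test suite and the acceptance script exercise the full method at the
sizes the analyses are designed for: screening recovery uses discovery /
validation / second-validation cohorts of 1000 / 600 / 700 patients with a
single planted gene (HR 0.75 per SD) among 100 noise genes in a 7-list
layout (three replicates in the tests); null calibration uses 1000
log-rank replicates and 100 stage-1 replicates at n = 60; image recovery
uses 512×512 px regions with ~45–50 cells. The imaging cohort in the
analysis scripts follows the 22-patient design with a median split.

# Known limitations

* The background model is a degree-2 polynomial; vignetting with higher
  spatial order would leak into the corrected signal.
* The joint dark-support rule requires a tissue-free margin
  (≥ `dark_quantile` of the field); whole-field tissue breaks it.
* The generator's cells are circularly symmetric and grid-arranged;
  watershed splitting of heavily overlapping nuclei is exercised only
  lightly.
* Stage-1 power depends on list size: a single prognostic gene diluted in
  a very long list can fail the list-level stage even when its per-gene
  effect is strong.
* The screen assumes proportional hazards throughout; no diagnostics are
  provided.
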