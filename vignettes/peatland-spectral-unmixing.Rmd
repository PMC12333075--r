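---
title: "Methods: spectral unmixing and diversity modelling for peatland vegetation"
author: "peatspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmixing and diversity modelling for peatland vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatspec)
```

## The problem

Boreal peatlands store a large share of global soil organic carbon, and
their surface vegetation — *Sphagnum* mosses, herbaceous and shrubby
vascular plants, and litter — indicates the site's ecohydrology and
nutrient status. Two trophic levels are distinguished: **ombrotrophic**
sites (rain-fed bogs, bryophyte-dominated) and **minerotrophic** sites
(ground- or surface-water-fed fens, vascular-plant-dominated). Close-range
reflectance spectroscopy of 1 m × 1 m vegetation plots offers a route to
mapping species composition and α-diversity at scale, provided two
questions can be answered quantitatively: how well does a plot's
reflectance spectrum determine the fractional cover of individual species,
and how much of the plots' α-diversity is encoded in their spectra?

`peatspec` implements that analysis chain as a reusable, fully tested
pipeline: harmonization of heterogeneous reflectance-factor spectra,
simulation of Sentinel-2 MSI bands, non-negative least-squares (NNLS)
spectral unmixing against a species endmember library, Shannon-Wiener and
Simpson diversity from point-intercept cover data, and partial least
squares (PLS) regression of diversity on spectra. Because the package must
be testable without the deposited spectral libraries, a seeded
synthetic-data generator reproduces the statistical structure of such a
study end to end.

## Spectra and their harmonization

All spectra are reflectance factors (RF) on the 1-nm grid of ASD field
spectrometers, 350–2500 nm. Field plots are measured as HCRF, laboratory
leaves as DHRF, and moss/litter samples as CCRF; after harmonization the
pipeline treats them interchangeably as RF.

Harmonization applies, in a fixed order:

1. **Segmented Savitzky–Golay smoothing** with a second-order polynomial
   and window sizes of 15 nm in 350–1000 nm, 39 nm in 1001–2000 nm, and
   75 nm in 2001–2500 nm. Windows widen with wavelength because detector
   noise grows across the SWIR. On the 1-nm grid, window size in nm equals
   window size in samples. Each segment is filtered independently so the
   different window widths cannot leak across segment boundaries.
2. **Masking** of the atmospheric water-absorption regions 1330–1549,
   1761–2024 and 2311–2500 nm and the noisy 350–399 nm region. The
   retained grid has three contiguous regions — 400–1329, 1550–1760 and
   2025–2310 nm — totalling 1427 samples. Masked wavelengths are removed,
   not flagged; retained values pass through bit-identically.
3. Optional **per-species averaging** of replicate endmember spectra
   (arithmetic mean per wavelength), producing one reference spectrum per
   species.

Two boundary decisions were genuinely open:

* **Segment-edge handling.** We use the standard Savitzky–Golay boundary
  treatment (the full projection-matrix fit over the terminal window),
  which reproduces polynomials up to the filter order *exactly*
  everywhere in the segment — a property the test suite asserts at 1e-9.
  Mirror padding was considered and rejected: the mirror image of a
  quadratic is not a quadratic, so mirror-padded edges would break exact
  polynomial reproduction at segment boundaries.
* **Order of smoothing and masking.** Smoothing runs first, so wavelengths
  that are later masked still inform the smoothed values near mask edges.
  The two orders differ measurably (a regression test constructs a
  spectrum with structure inside a masked band and verifies the outputs
  differ), and smoothing-first is the convention adopted throughout.

## Sentinel-2 band simulation

Hyperspectral spectra are resampled to the ten MSI bands used for
vegetation analysis — B2 (490 nm), B3 (560), B4 (665), B5 (705), B6 (740),
B7 (783), B8 (842), B8a (865), B11 (1610), B12 (2190). B1 and B9 are
excluded for their 60-m resolution; B10 cannot be simulated at all because
its spectral response lies inside the masked water-absorption region (the
package raises a per-band error naming any such band). The band value is
the response-weighted mean of RF over the band support, with the response
**renormalized over the unmasked support**: this preserves constant
spectra even when a band straddles a mask edge, whereas any
non-renormalized convention would bias those bands. Resampling is linear
in the input (asserted at 1e-12), and band values always lie within the
RF range over the band's support.

The tests and the default pipeline use a synthetic Gaussian response table
at the same ten band centres (`gaussian_band_set()`), with bandwidths
chosen to be plausible; an exported sensor response table read with
`read_srf()` is a drop-in replacement.

## Fractional cover and α-diversity

Cover is estimated by point intercept: a 1 m frame marked every 10 cm
carries a 10 × 10 grid, and the species at each of the 100 cell centres is
recorded. Exactly one species is recorded per point, so species covers
partition the plot and sum to 100%. The estimator $\hat f_s = 100\,n_s/n$
is unbiased with binomial sampling error, which the suite verifies over
10,000 simulated grids.

From the covers $f_s$ (relative covers $p_s = f_s / \sum_s f_s$):

* Shannon-Wiener index $H = -\sum_{p_s > 0} p_s \ln p_s$, in nats
  (log base configurable);
* Simpson index $D = 1 - \sum_s p_s^2$ (the complement form, in
  $[0, 1 - 1/\text{richness}]$).

Both are computed through `vegan::diversity()` behind the package's
interface, and the suite checks them against closed forms (uniform
communities, singletons, and a hand-computed five-species profile).

## NNLS spectral unmixing

Endmember species are selected by an abundance rule: a species is excluded
only if it occurs in fewer than 5 plots **and** its cover is below 5% in
every plot where it occurs ("max over occupied plots" is the default
reading of the cover clause; a mean-cover variant is available). Litter
counts as a species. For each trophic level the pipeline uses six
endmembers: five level-specific plants plus litter.

Per plot, the package solves

$$\hat a = \arg\min_{a \ge 0} \lVert E a - y \rVert_2$$

with the plot spectrum $y$ as response and the endmember matrix $E$
(1427 × 6 hyperspectral, 10 × 6 multispectral) as predictors, using an
in-package Lawson–Hanson active-set implementation. There is no intercept
and no sum-to-one constraint in the solver; abundances are normalized
*afterwards* ($\hat a / \sum \hat a$; plots with all-zero coefficients are
flagged and excluded), and a fully constrained variant (`sum_to_one =
TRUE`) is available but not the default. The solver is verified against
the KKT conditions, an exhaustive active-set enumeration oracle, and an
independent library implementation, all at 1e-6.

Evaluation pairs predicted against observed cover in percent. Pairs whose
**observed** cover is zero are dropped from the evaluation set (their
predictions are retained for inspection); dropping predicted zeros instead
is available behind a flag. Accuracy per species is reported as
$R^2 = 1 - SS_{res}/SS_{tot}$ (negative values are legal and indicate a
model worse than the mean), RMSE in percentage points, and bias
(mean of predicted − observed, so positive bias means over-prediction).

## Per-wavelength R² profiles

For descriptive analysis, the RF at each retained wavelength is regressed
on one species' fractional cover across plots (all plots of the level by
default, zeros included; an occupied-plots-only variant is available). The
profile reports the squared Pearson correlation per wavelength — hence
values in $[0, 1]$ — and its maximum with the wavelength where it occurs.
Under the null of independent cover the mean profile value is
$1/(n-1)$, which the suite verifies by permutation.

## PLS diversity models

Diversity is predicted from the harmonized plot spectra (1427 predictors,
tens of plots) with univariate-response PLS fitted by NIPALS on centred,
unit-variance-scaled predictors (scaling toggleable). Full-component PLS
reproduces least squares; one-predictor PLS reproduces simple OLS; and the
NIPALS predictions are cross-checked against an independent SIMPLS
implementation — all at tolerances of 1e-6 to 1e-8 in the suite.

The number of components is chosen by seeded 10-fold cross-validation.
The selection rule was an open choice. Pure PRESS minimization proved
unstable: once the true latent dimension is reached the PRESS curve is
nearly flat, and its argmin wanders among statistically equivalent counts
(in a seeded benchmark with two strong latent components it picked 2 or 3
in barely over half of replicates). The default is therefore the standard
**one-standard-error rule** — the smallest count whose CV error is within
one SE (over folds) of the minimum — which picks the true dimension in
97 of 100 seeded replicates of that benchmark; plain minimization remains
available via `rule = "min"`.

Final evaluation uses a seeded, unstratified 70/30 train/test split:
components are selected by CV on the training set only, and $R^2$, RMSE
and bias are computed on the held-out 30%.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
at the study's conditions:

* **Species templates.** Each species' spectrum is a parametric curve: a
  visible baseline with a Gaussian green peak at 550 nm, a logistic red
  edge to a NIR plateau, a SWIR decline with water-absorption dips at
  1450 and 1940 nm scaled by a moisture parameter, plus small
  species-specific Gaussian "pigment" features at distinct VIS/SWIR
  positions. The defaults encode the field's qualitative contrasts:
  vascular plants have a stronger green peak and steeper red edge than
  mosses; litter rises monotonically through VIS–NIR and keeps a high
  SWIR level. The pigment features exist because smooth three-parameter
  curves alone are far more mutually collinear (pairwise correlations up
  to 0.996, endmember condition number ≈ 1300) than real species
  libraries; with them the condition number is ≈ 160 and species remain
  identifiable, which is the premise of the unmixing analysis. All
  numbers are synthetic — chosen for realism of shape, never presented as
  measured values.
* **Communities.** Covers are Dirichlet draws × 100 per plot; draws below
  0.5% are zeroed (absent species, exercising the zero-removal path) and
  the rest renormalized. Concentrations mirror the relative abundance
  structure of the two levels (litter dominant, a couple of rare species
  per level), with total concentration 3 for the minerotrophic and 4 for
  the more even ombrotrophic level — reproducing the observed ordering of
  diversity between levels.
* **Plot spectra.** Linear mixtures
  $y(\lambda) = (1-\text{shade})\sum_s (f_s/100)\, b_{ps} E_s(\lambda) +
  \varepsilon(\lambda)$ with per-plot-per-species brightness factors
  $b_{ps} \sim \text{LogNormal}(0, 0.05)$, iid Gaussian noise of 0.002 RF,
  and an optional unmodelled shade fraction. Negative values are clamped
  at zero with a warning counter.
* **Defaults:** 60 plots per trophic level, six species per level, three
  replicate endmember spectra per species, a 100-point grid. All
  randomness is seeded per stage, so every object regenerates
  bit-identically; the committed 12-plot fixture under `inst/extdata/` is
  byte-compared against regeneration in the suite.

What the generator does **not** emulate: multi-layer canopy geometry,
nonlinear (bilinear/shadowing) mixing, within-plot spatial structure,
instrument-specific noise spectra, and the actual spectra of the deposited
libraries. Passing tests therefore demonstrate correctness of the
algorithms and well-posedness of the workflow under linear mixing — not
field-data accuracy, which on real data is limited by exactly the effects
the generator omits.

## Numerical choices and degenerate inputs

* Wavelength grids must be strictly increasing integer nm; fractional
  grids are rejected unless interpolation is explicitly requested.
* RF values outside [0, 1.5] warn but are never clamped (clamping would
  hide instrument problems).
* NNLS uses a dual-feasibility tolerance scaled to the problem
  (`1e-10 · max|Eᵀy|`) and resolves rank deficiency within the passive
  set by zeroing undetermined coefficients.
* Plots whose NNLS coefficients are all zero are flagged `degenerate`
  and excluded from evaluation rather than erroring.
* `fit_metrics` on zero-variance observations returns `NA` R² with a
  warning; RMSE and bias are still computed.
* PLS stops early (with the component count capped) when the deflated
  predictor matrix carries no covariance with the response, as happens
  beyond the rank of low-rank designs; CV ties go to the smaller count.

## Problem sizes used by the tests

The suite runs the full study at its default size (60 plots per level,
1427 retained wavelengths), the noise-ordering comparison at 40 plots,
the CV-selection benchmark at 100 replicates of a 100 × 30 design, and
the Monte-Carlo verifications (SG noise variance, cover unbiasedness,
binomial grid moments) at 2,000–12,000 draws — sizes at which the
asserted statistical tolerances are comfortably resolved while the whole
suite completes in well under a minute.

## Known limitations

* Linear mixing is assumed end to end; real peatland canopies mix
  nonlinearly (shadowing, multiple scattering, moisture gradients), and
  the NNLS abundances absorb those effects into bias.
* The single-label point-intercept convention (covers sum to 100) cannot
  represent multi-layer canopies.
* The per-wavelength R² profiles are descriptive; no multiple-testing
  control across wavelengths is attempted.
* The synthetic sensor responses are Gaussian stand-ins; band values from
  the real response tables will differ slightly near mask edges.
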