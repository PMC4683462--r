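---
title: "Measuring the colour gamut of an avifauna: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the colour gamut of an avifauna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avigamut)
```

## The problem

How much of the colour space available to a bird's eye does a whole
avifauna actually use, which colour-production mechanisms account for that
use, and how is it divided between the sexes and among clades? `avigamut`
implements a reusable pipeline for this question: reflectance spectra go in,
and out come tetrahedral colour-space coordinates, gamut metrics, mechanism
assignments and bootstrap comparisons. Because large museum-spectra
collections are rarely deposited, the package also ships a parametric
generator of labelled synthetic avifaunas, so every stage can be exercised
and tested end to end without access to measured data.

## Visual model

Birds are tetrachromats. For each spectrum we compute four cone quantum
catches on a common 300–700 nm grid at 5 nm steps (81 points),

$$Q_i = \sum_\lambda R(\lambda)\, I(\lambda)\, C_i(\lambda), \qquad
  i \in \{u, s, m, l\},$$

with reflectance $R$ as a proportion, an ideal flat irradiance
$I(\lambda) = 1$ by default (the analysis is about reflectance colour, not
illuminants), and sensitivity curves $C_i$. Summation is a plain rectangle
rule: on a uniform grid it differs from the trapezoid rule only by boundary
terms, which cancel when catches are normalized. Relative catches
$f_i = Q_i / \sum_j Q_j$ live on the 3-simplex and are embedded as

$$x = \tfrac{1 - 2s - m - l}{2}\sqrt{3/2}, \quad
  y = \tfrac{-1 + 3m + l}{2\sqrt{2}}, \quad
  z = l - \tfrac14,$$

a regular tetrahedron of circumradius 0.75 centred on the achromatic point,
with the long-wavelength (L) vertex at the apex $(0, 0, 0.75)$. Any affine
map satisfying regularity and that orientation would do; this one is fixed
so that coordinates are portable and testable (the tests verify circumradius,
edge length $\sqrt{3/2}$, affinity, and the apex convention).

Sensitivity curves are configuration, not measurement: templates are
Govardovskii A1 alpha-band pigments at peak wavelengths (u, s, m, l) =
(372, 456, 544, 609) nm for ultraviolet-sensitive (U-type) eyes and
(419, 478, 542, 607) nm for violet-sensitive (V-type) eyes — widely used
averages, replaceable either by custom peak wavelengths or by a measured
curve file which is then used bit for bit. The beta band is off by default
and oil-droplet filtering is not modelled separately; curves that include it
can be supplied. No receptor-noise model, chromatic adaptation, or log
transform is applied: the downstream analysis is purely geometric in linear
relative-catch space. Replicate scans of one specimen are averaged at the
reflectance level; specimens of a species and sex are averaged later, in
colour space, one point per (species, sex, patch).

## Gamut metrics

Two complementary measures of occupied colour space:

* **Convex-hull volume** (`hull_volume()`), optionally as a percentage of
  the reference tetrahedron volume $a^3/(6\sqrt2) \approx 0.21651$ (with
  $a = \sqrt{3/2}$) — "percent of the theoretical avian colour space". Hulls
  are computed by a compiled incremental algorithm that also returns facet
  half-spaces; `hull_overlap()` intersects two hulls exactly by polar
  duality about an interior point, with a Monte-Carlo rejection-sampling
  route retained both as a numerical fallback for near-degenerate geometry
  and as an independent oracle in the tests. Every reported volume fraction
  names its denominator, because hull volumes are scale-free only relative
  to a stated total.
* **Chromatic loci** (`rasterize_loci()`): the space is partitioned into
  half-open cubic cells of edge 0.022 anchored at the achromatic point, and
  occupancy is counted. Direct 3D flooring is used; intersecting two 2D
  grids on the yz and yx planes is mathematically identical (they share the
  y axis and cell size) and is kept as a property test, not an
  implementation. The grid anchor is a genuine free choice — the origin
  (achromatic point) is used and exposed as a parameter, and locus counts
  shift slightly under other anchors. Locus abundance (patches per cell)
  gives a concentration measure: the smallest fraction of occupied loci
  holding half of all patches.

Hull volume is outlier-driven and mostly empty space; locus counts are
robust to outliers but resolution-bound. The two are reported side by side
throughout.

## Mechanism classification

Spectra are assigned to one of six colour-production mechanisms — melanin,
carotenoid, psittacofulvin, structural, carotenoid + structure,
psittacofulvin + structure — from spectral shape, the way it is done by
expert inspection, but operationalized as named features with explicit
thresholds (`classifier_thresholds()`): flatness, monotonicity, interior
peak prominences, the 400–510 nm absorption trough, carotenoid fine
structure (twin absorption dips near 430/460 nm flanking a small maximum
near 445 nm, detected on a detrended residual so a bell or sigmoid flank
cannot mask them), the long-wavelength "shoulder" plateau, the
mid-peak/long-trough signature of pigment + structure colours, and a UV-peak
ratio for ultraviolet bells truncated at the grid edge. Rule precedence:
pigment + structure first, then carotenoid-type, then structural, with
melanin (which by convention includes white) as the explicit fall-through.
Carotenoid-shaped spectra in parrot orders are labelled psittacofulvin; with
an unknown order the label stays carotenoid and a warning is raised.

The thresholds are this module's own calibration. They were chosen once to
separate the synthetic generator's families cleanly (100% recovery
noise-free; at the generator's default noise the tests require at least 95%)
and are deliberately conservative — e.g. an interior peak must rise 7% above
its surroundings, so that smooth correlated noise cannot fabricate a
structural colour. They are not claimed to reproduce any particular expert's
per-species assignments on real spectra, and chemically intermediate colours
will always be rough calls; the thresholds are exported configuration for
exactly that reason.

## Bootstrap inference

The species is the exchangeable unit everywhere: a bootstrap replicate draws
whole species with replacement and carries each drawn species' full per-sex
patch point set; patches are never resampled independently.

* `bootstrap_sex_ratio()`: replicates draw N species (those with both sexes
  measured), compute the gamut metric for males and for females of the same
  drawn species, and record the female/male ratio; the 2.5%/97.5% quantiles
  are read against the equal-diversity null ratio of 1. Replicates with a
  zero male metric are redrawn and counted.
* `bootstrap_order_null()`: an order's observed gamut (as percent of the
  full sample) is compared with replicates drawing the same number of
  species from the entire avifauna. Drawing is with replacement by default,
  mirroring the sex-ratio procedure; a without-replacement variant is an
  option.
* `two_tailed_p()`: the doubled smaller tail with an add-one correction,
  $p = \min(1,\, 2\min\{(1 + \#\{r \le o\})/(B+1),\ (1 + \#\{r \ge o\})/(B+1)\})$,
  so finite resampling can never report $p = 0$; the raw doubled proportion
  is available by option. Doubling the smaller tail is one of two defensible
  two-sided readings; it is the implemented default.

Quantiles use the inclusive linear-interpolation convention (R type 7),
named here because at $B = 10^4$ the convention is visible in the fourth
decimal. All resampling is driven by a single integer seed of R's default
Mersenne-Twister generator; identical seeds give identical results across
runs, and the pipeline splits one root seed into per-stage seeds.

## The synthetic avifauna generator

`gen_avifauna()` emulates the structure of a museum-spectra campaign:
species nested in orders of very unequal sizes, two sexes, three specimens
per species and sex, 17 standardized patches, and per-patch mechanism
families drawn from order-specific frequency vectors. Spectral families are
parametric shapes carrying each mechanism's defining features: flat or
monotonically rising curves (melanin, with white as a flat high-reflectance
variant), logistic rises with a long-wavelength plateau and optionally a UV
bump plus 430/460 nm absorption fine structure (carotenoid/psittacofulvin),
Gaussian bells with an optional second bell for iridescence (structural),
and mid-wavelength bells with fine structure and suppressed far-red
reflectance (pigment + structure). Noise is spectrally correlated
(white noise smoothed to ~25 nm correlation length) because real
reflectance noise is smooth; independent per-wavelength noise would defeat
shape classification in a way real data do not.

Defaults: 60 species in 4 orders (30/15/10/5) with one parrot-like order
given disproportionate psittacofulvin and structural colour; melanin-dominant
frequencies; noise sd 1.5%; dichromatism 0.5, implemented as female
substitution of ornamental patches by melanin/white rather than parameter
shrinkage, which reproduces the qualitative structure of male-exclusive
peripheral colours. These sizes keep a full pipeline run under a minute
while leaving every comparison well-populated.

What the generator does **not** emulate: phylogenetic autocorrelation of
colour within orders, physically based optics (thin films, photonic
crystals), patch-to-patch covariance within a specimen, measurement-geometry
artefacts, and the long tail of intermediate, hard-to-classify real spectra.
Passing tests on synthetic avifaunas therefore demonstrate that the
machinery is correct and calibrated under known ground truth — not that any
particular real avifauna's numbers would be reproduced.

## Numerical choices and degenerate inputs

* Resampling to the 5 nm grid is linear interpolation, clamped to [0, 100];
  linear interpolation is idempotent and exact for affine spectra.
* An all-zero spectrum yields an all-zero quantum catch; this is an explicit
  error (no silent achromatic-black convention).
* Hull degeneracy (fewer than 4 points, affine dimension < 3) is a result —
  volume 0 with a flag — not an error; overlap of degenerate hulls is 0.
* Hull facet tests use an absolute tolerance of 1e-9 scaled to the data;
  the exact overlap method requires a strictly interior point of the
  intersection and falls back to reporting zero overlap when none exists.
* Cell assignment is half-open, `floor((v - origin)/cell)`: boundary points
  belong to the higher-index cell's lower face exactly once.
* Modal mechanism labels per (species, sex, patch) break ties
  alphabetically, keeping aggregation deterministic.

## Reporting scales in this vignette and the tests

The test-suite checks run at deliberately reduced scale so the whole suite
stays fast: bootstrap calibration uses 200 simulated avifaunas of 40 species
with B = 500 replicates; oracle comparisons use 20 random hull pairs with
up to 200 points and 10^6 Monte-Carlo samples; classifier calibration uses
100 spectra per family. The acceptance script runs the default 60-species
avifauna with B = 2000. All of these sizes are package choices exposed as
parameters; the classical choice of B = 10000 is a config value away.

## Known limitations

* Mechanism thresholds are calibrated on the generator's families; real
  spectra near category boundaries (notably structural purples vs
  carotenoid purples, and weak pigment + structure combinations) will need
  threshold adjustment and expert review.
* The bootstrap ignores phylogeny: orders are compared against species
  drawn exchangeably from the whole avifauna, and no multiple-testing
  correction is applied across orders.
* Discriminability (receptor noise, just-noticeable differences), double
  cones and achromatic channels are out of scope; the analysis is purely
  geometric.
* Hull overlap of nearly coplanar point clouds is numerically fragile in
  any exact method; prefer the Monte-Carlo route when hull volumes are
  close to degenerate.
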