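---
title: "Methods: topography screening statistics in toposcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topography screening statistics in toposcreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`toposcreen` implements the statistics of a designed surface-topography
screen of per-cell marker expression: a library of microtopography designs
presented on a chip of 300 µm wells (2176 unique designs, each in duplicate,
plus 4 unpatterned flat wells on a 66 × 66 grid), imaged at single-cell
resolution over several chip replicas. The pipeline takes per-cell feature
tables (CellProfiler-style), applies quality control, classifies each cell
as marker-positive or -negative with a control-calibrated per-chip adaptive
threshold, calls High/Low hit surfaces with a chi-square test against the
on-chip flat wells, and relates hit class to surface design descriptors and
cell shape with a repeated-split random-forest protocol.

Because real screening feature tables of this kind are generally not public,
the package includes a first-class synthetic-screen generator with the
statistical structure the analysis assumes. Every stage is testable against
that generator, and the generator itself is part of the tested surface.

# Design library and descriptors

Topography units are built from three geometric primitives — circles,
triangles, and rectangles — placed in a square feature cell of side
`w ∈ {10, 20.7, 29}` µm (cell sizes are chosen so an integer number of cells
tiles the 290 µm active well area; a 10 µm wall separates wells of the
300 µm pitch). The feature cell tiles periodically across the well, so each
design is characterised by its cell pattern alone.

The in-silico generation algorithm draws, per unit: a size window
`(s_lo, s_hi)` inside `[3, min(30, 0.6 w)]` µm, a target coverage fraction
uniform on `[0.05, 0.65]`, and then as many primitives (1–16) as the target
coverage divided by the mean primitive area requires, each with a uniform
shape, size, position (constrained so its bounding circle stays inside the
cell), and rotation. A naive draw of 1–16 primitives with sizes up to 30 µm
covers most of the cell for nearly every design and produces a single merged
pillar; the coverage-targeted draw instead spans sparse-to-dense patterns
with per-pillar areas from roughly ten to several hundred µm², which is the
regime the screening analysis distinguishes. All draws derive from one
master seed through per-unit stream seeds, so catalogs are reproducible and
insensitive to generation order.

Descriptors per design, computed on the rasterized binary mask:

* **pattern area** — total foreground area divided by the number of
  4-connected components ("pillars");
* **space area** — its symmetric counterpart, background area per pillar
  (the per-pillar reading of "space area"; the total background is trivially
  derivable);
* **foreground fraction** — foreground area over active well area;
* **wave numbers `wn_q`** — the fraction of total non-DC spectral power of
  the mask at radial spatial frequencies ≤ `q` × Nyquist, for
  `q ∈ {0.1, 0.25, 0.5}`. `wn_0.1` captures jointly the density of
  structures and their size: coarse, widely spaced pillars concentrate
  power at low frequency. The exhaustive radial partition (up to the
  spectral corner at √2 × Nyquist) sums to one for any non-flat mask, which
  the tests assert.

Rasterization uses cell centres at half-resolution offsets, row-major with
the origin at the well's top-left. The default single-design resolution is
0.5 µm (≤ 5% area error for the smallest 3 µm primitive); catalog-scale
feature computation uses 1 µm, which keeps a 2176-design catalog under a
few seconds and is well within the tolerances of everything downstream.

**Archetypes.** For planting synthetic hits the package labels designs
`high_like` (pattern area 100–400 µm², foreground fraction ≤ 0.30, i.e.
moderate spacing) or `low_like` (pattern area < 100 µm², foreground
fraction ≥ 0.15, i.e. dense packing). The area windows follow the observed
hit-geometry regimes; the two density cutoffs are the package's own
calibration, chosen once from the generator's empirical feature
distribution so that both archetypes are well populated (about 10% and 50%
of designs respectively), and exposed as arguments.

# Synthetic screen generator

The generator emulates, per chip replica: Poisson cell counts per well with
mean `seeding density × well area` (10,000 cells/cm² × (300 µm)² = 9;
exposed directly as `cells_per_well_mean` so the observed per-well median
of 10 can be matched); a latent marker-positive class per cell with weight
0.07 at baseline; a two-component lognormal intensity mixture
(`meanlog` 4.0 / 5.18, `sdlog` 0.4, arbitrary units) scaled by a per-chip
lognormal batch factor (sd 0.15); and class-conditional shape features.
Planted High surfaces add +0.20 to the positive weight, planted Low
surfaces −0.05 (floored at 0.005); the default 112 High and 72 Low ids are
drawn from the high-like/low-like archetypes. Off-chip control samples
share the intensity components: the negative control at the baseline
weight, the stimulated positive control at weight 0.70 (a package choice:
the stimulated positive fraction is qualitative in the source material).

The intensity components were chosen so that the crossing point of the two
pure components sits at the 93rd percentile of the negative component
(Φ(1.475) ≈ 0.93). One consequence worth stating precisely: when *both*
control samples are mixtures of the *same* two components (negative at
weight 0.07, positive at 0.70), the density crossing coincides with the
component crossing, whose rank inside the negative *mixture* is
0.93 × 0.93 + 0.07 × 0.07 ≈ 0.87. The textbook 93rd-percentile outcome is
recovered exactly when the controls are pure components (weights 0 and 1),
which is how the calibration reference check is defined. With real data the
two controls are not literal mixtures of identical components, and the
calibrated percentile lands wherever the crossing falls; the pipeline
accepts either the calibrated value or a fixed percentile.

Shape features are drawn from class-conditional Gaussians over
(log area, logit solidity, logit form factor, eccentricity,
log median radius), with correlations capped at |ρ| ≤ 0.7, encoding the
reported orderings: cells on flat wells are large and spread (largest form
factor); marker-negative cells on topographies are the thinnest and most
eccentric. Perimeter is derived from area and form factor
(`P = sqrt(4πA/FF)`) so the four are mutually consistent. Actin intensity
is lognormal with correlation ρ = 0.5 to the marker *on the log scale* —
the scale on which both intensities are Gaussian — and the recovery
summary reports the Pearson r of the log intensities.

What the generator does **not** emulate: spatial structure within wells or
across the chip, segmentation errors beyond the QC-visible area/perimeter
outliers, intensity spillover between neighbouring cells, plate-edge
effects, or cell migration between wells (walls prevent it). Passing tests
therefore validate the statistical machinery under the stated model, not
image analysis on real micrographs.

# Quality control

A cell is excluded when its area *or* perimeter lies strictly outside
`median ± 1.5 × IQR`, computed over all cells of all replicas of that
cell's unique surface. "1.5 quantiles from the median" is not a standard
statistic; the median-centred Tukey reading is the closest defensible one,
and both the multiplier and the statistic are arguments. Boundary values
are retained (strict inequality excludes). Surfaces with fewer than 4 cells
pass unfiltered and are flagged, since quartiles are unstable there. With
the default generator the rule excludes ~10% of cells, as expected for
lognormal-tailed features under a ±1.5 IQR fence.

# Adaptive threshold

Two stages, deliberately separated:

1. **Calibration** — kernel-density estimates of the negative and positive
   control intensities (on the log scale, where the components are
   symmetric and equal-variance components cross at the midpoint of their
   log-means); the calibration percentile is the rank of the
   lowest-intensity density crossing inside the overlap region within the
   negative sample. Disjoint supports and indistinguishable samples are
   errors; a crossing above the 99th percentile warns.
2. **Application** — per chip, the cutoff is the calibration-percentile
   (type-7, linear interpolation — stated because small-sample percentiles
   depend on the convention) quantile of that chip's own post-QC intensity
   distribution; positivity is strict exceedance. Each chip therefore flags
   ≈ `1 − p/100` of its cells by construction, which absorbs
   chip-to-chip multiplicative batch effects without modelling them.

# Hit calling

Per unique surface, positive/negative counts pool over all 16 replica
wells and enter a 2 × 2 chi-square test (no continuity correction; at
~150 pooled cells the correction is immaterial) against the pooled counts
of the on-chip flat wells — chosen over the off-chip control because they
share chip batch effects; the off-chip controls serve only percentile
calibration. When any expected count falls below 5 the surface switches to
Fisher's exact test (recorded per row). Classes: `High`/`Low` require the
positive fraction on the appropriate side of the flat reference *and*
raw `p < 0.05`, following the source protocol, which applied no multiple-
testing correction; Benjamini–Hochberg adjusted p-values are reported
alongside and `adjusted = TRUE` gates classes on them instead. Surfaces
are ranked by pooled positive fraction (ties broken lexicographically;
zero-cell surfaces are `NS` with p = 1 and rank last). Pooling across
replicas is the default; ranking by the mean of per-replica fractions is
exposed as an option without a default claim, since the source is
ambiguous on this point.

Two statistical properties of this design are worth knowing. First, all
~2176 tests share one flat reference of only ~290 cells (4 flat wells ×
8 chips × ~9 cells), so the screen-wide hit rate under the null fluctuates
substantially from replicate to replicate of the whole experiment: the
reference fraction's binomial noise (sd ≈ 0.015 around 0.064) shifts every
test in common. Second, thresholding at the chip-wide 93rd percentile
attenuates planted mixture-weight differences: a cell flags positive with
probability `w·P_pos(>t) + (1−w)·P_neg(>t)` with slope ≈ 0.75 in `w`, so a
−0.05 planted weight shift becomes a ≈ −0.037 flag-rate shift. At ~144
pooled cells per surface this puts the power to call the planted Low
surfaces at roughly 0.1–0.4 (reference-realisation dependent), while
planted High surfaces (+0.20) are recovered essentially always with the
correct direction. The package reports what the data support; the
down-weighted Low-side power is a property of the screen geometry, not of
the implementation.

# Cell-shape measurement

Features per 8-connected cell mask (foreground 8-connected, background
4-connected — the standard complementary pair):

* area `A = n px²`; form factor `4πA/P²`; solidity `A / A_hull`;
* perimeter `P` by Moore boundary tracing with corner-corrected chain
  weights (0.980 per axial step, 1.406 per diagonal, −0.091 per direction
  change) plus a closed-boundary half-pixel offset (+π): the weights
  measure the pixel-centre polygon, and the offset accounts for the
  half-pixel band between pixel centres and the true outer boundary. A
  single multiplicative correction cannot satisfy the disk (FF = 1 ± 0.05)
  and square (FF = π/4 ± 0.05) oracles simultaneously; this estimator
  satisfies both. Its known weakness — inherited by all chain-code
  estimators — is block-upscaled (aliased) boundaries, where the error
  reaches ~10–15%; the scale-law tests state these tolerances explicitly.
* eccentricity from second central moments of pixel centres;
* median radius: exact Euclidean distance transform (two-pass separable
  lower-envelope algorithm, verified against all-pairs brute force) to the
  nearest background pixel centre, median over member pixels, minus half a
  pixel — so a boundary pixel sits at depth ≈ 0.5 px and a single-pixel
  mask yields exactly half a pixel. On a digitized disk of radius r this
  reproduces the closed form `(1 − 1/√2) r` within 5%.
* intensity: median (even counts: mean of the central order pair) and sum
  over member pixels; background never contributes.

Degenerate single-pixel masks return defined values and a `degenerate`
flag. All features are emitted in µm via `pixel_size_um`; the screening
statistics downstream are rank/percentile-based and unit-agnostic.

# Repeated-split random forest

For each of 100 repeats: a stratified 75/25 split (stratification guards
the 112/72 imbalance; no reweighting, mirroring the source protocol);
hyperparameters tuned by stratified 10-fold cross-validation *on the
training part only*; held-out accuracy recorded; permutation importance of
each feature measured on the held-out split (model-agnostic and comparable
across repeats; the source's importance metric is unnamed). Aggregation is
the mean and sd across repeats. The source material states the held-out
fraction inconsistently (25% in one place, 1/3 in another); 25% is the
default and the fraction is an argument.

The tuning grid covers `mtry` and `min.node.size` up to the intercept-only
limit (no splits — a majority-vote null model), and model selection uses
the one-standard-error rule: the least complex model within one standard
error of the best cross-validated accuracy. This matters for honesty under
weak signal: fully-grown forests on label-permuted data score
`p² + q² ≈ 0.52` held-out (they memorise noise and predict near the
training-point mix), whereas a protocol that can select the null model
collapses to the majority prior 112/184 ≈ 0.609 — the correct null
reference for the accuracy distribution. Under real signal the deeper
models win the CV comparison and the rule is inert.

Reproducibility: each repeat's split seed derives from the master seed and
the repeat index; reports serialise to JSON and reproduce exactly.

# Numerical and interface conventions

* Quantiles: type 7 everywhere.
* Seeds: one master seed; per-stage seeds by stable string hashing of the
  stage name, so adding a stage never shifts another stage's stream.
* CSV: UTF-8, comma, header, dot decimal; doubles rendered at 15
  significant digits, which makes write → read → write byte-stable.
* Grid coordinates 0-based, row 0 at the chip top.
* The end-to-end runner writes every stage artifact plus `provenance.json`
  with the full effective configuration; identical configuration and seed
  give byte-identical artifacts.

# Problem sizes used in the tests

Module tests run on a 16-design, 6 × 6 layout; the full-scale suite uses
the complete 2176-design catalog at 1 µm feature resolution, an 8-chip
simulated screen (~3 × 10⁵ cells), three null screens, and 100-repeat
model reports, which keeps the whole suite within a desk-scale run. The
acceptance script regenerates the full catalog, layout and screen from its
seed argument at the same sizes.

# Known limitations

* The generator's independence assumptions (no spatial correlation within
  or between wells) make the chi-square exactly applicable; real screens
  may be overdispersed, which would widen the null beyond α.
* Only ~290 reference cells back all surface tests; the screen-wide hit
  rate is correspondingly variable between whole-screen replicates.
* The perimeter estimator's staircase bias on aliased boundaries, and the
  ~0.4 px quantisation of the median radius on thin shapes, are stated in
  the test tolerances.
* The wave-number descriptor is defined relative to each mask's own
  Nyquist frequency; compare designs at a common resolution.
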