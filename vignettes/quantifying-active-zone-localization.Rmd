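---
title: "Quantifying active-zone protein localization from confocal and STED images"
author: "presynQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying active-zone protein localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynQuant)
```

## The measurement problem

Presynaptic voltage-gated Ca^2+^ channels (Ca~V~2s) sit in the active
zone, tens of nanometres from the postsynaptic density, while Ca~V~1s are
somatodendritic. Deciding whether a (possibly chimeric or tagged) channel
construct is targeted to the active zone therefore requires localizing it
relative to a synaptic reference at a resolution finer than the confocal
diffraction limit. The standard design images the synaptic-vesicle marker
synapsin in confocal mode, and PSD-95 plus the protein of interest
(an endogenous channel or an HA-tagged construct) in STED mode, then asks
two quantitative questions:

1. **Where** is the protein relative to the PSD-95 peak, along the
   trans-synaptic axis of synapses viewed from the side?
2. **How much** of it accumulates there (and in synapsin-defined ROIs,
   and in neuronal somata), compared across rescue conditions?

presynQuant implements this quantification end to end, together with a
synthetic-imaging generator that renders ground-truth synapses so every
stage can be validated by parameter recovery rather than by eye.

## Side-view line profiles

A side-view synapse shows a vesicle cloud with an elongated PSD-95 bar
along one edge. For each annotated synapse (centre + unit axis, the axis
pointing from the presynaptic to the postsynaptic side),
`extractProfiles()` samples every channel along a rectangular ROI of
~1000 × 200 nm drawn perpendicular to and across the centre of the
PSD-95 bar:

* one sample per pixel along the axis — 71 samples at 14.194 nm pixels
  (an odd count keeps the axis symmetric about the annotation centre);
* at each axial position, the mean of 15 bilinear interpolations evenly
  spanning the 200 nm transverse width (about one per pixel).

The PSD-95 trace only is smoothed with a 5-pixel centred rolling average
(`smoothPsd()`); the protein-of-interest trace is never smoothed, so its
peak value is not deflated before extraction. At the profile ends the
smoothing window shrinks to the available samples instead of padding —
no data are invented, and a valid synapse has its peak far from the ends
anyway. `alignProfiles()` then defines each synapse's zero position as
the argmax of the smoothed PSD-95 trace (smallest index on exact ties,
for determinism) at integer sample resolution — no sub-pixel fitting, so
a peak position is always an observed sample. Synapses with a flat
smoothed PSD-95 trace, or whose rectangle is clipped by the image
boundary, are excluded with a logged reason rather than silently
dropped.

`summarizeProfiles()` averages aligned profiles across synapses
(mean ± SEM per aligned position; SEM only where at least two synapses
contribute) and extracts per-synapse peak intensities as the maximum
within ±100 nm of the PSD-95 peak, boundary samples inclusive: 15
samples at 14.194 nm pixels. Protein peaks come from the raw trace,
PSD-95 peaks from the smoothed trace. The sampling unit for statistics
is the synapse.

```{r profiles}
cfg <- synthConfig(nSynapses = 5L, cavOffsetNm = -50, rngSeed = 1L)
field <- generateSynapseField(cfg)
lps <- alignProfiles(extractProfiles(field$image,
                                     annotationsFromTruth(field$truth)))
head(peakTable(summarizeProfiles(lps)))
```

Sign convention: negative aligned positions are presynaptic. The sign is
fixed geometrically — the synapsin centroid must lie on the negative side
of the axis — which is also how `detectSideView()` signs automatically
detected annotations.

## Confocal ROI and somatic donut quantification

`segmentSynapsin()` thresholds the synapsin channel with Otsu's method
and labels 8-connected components; components below 0.05 µm² are
discarded. The pixel-count cutoff is the smallest integer n with
n × pixelSize² ≥ 0.05 µm² — 249 px at 14.194 nm pixels and 7 px at
90.2 nm pixels. "At least" is taken literally: a component exactly at
the cutoff survives. `roiMeanLevels()` reports the mean raw target
intensity per ROI and summarizes an image as the *unweighted* mean of
per-ROI means — each synapse counts once regardless of its area, and the
image (not the ROI) is the sampling unit for statistics. Quantification
always runs on raw intensities; display-oriented brightness/contrast
adjustments play no role.

Somatic levels use donut-shaped ROIs (`somaDonutMean()`): the outer
somatic mask minus the nuclear mask, with the mean raw intensity of the
target channel over the remaining pixels and the cell as the sampling
unit. Masks are inputs — drawn by hand on real data or produced exactly
from generator ground truth via `makeDiscMask()`; automated soma
segmentation is deliberately out of scope.

Numerical contracts worth stating: a constant image has no Otsu
threshold and raises a degenerate-input error; on tied between-class
variances the smallest threshold wins; an empty ROI table makes the
image summary `NA` with a warning rather than a silent zero; an empty
donut is an error.

## Group statistics

The statistics module wires standard tests the way this experimental
design requires them:

* `kruskalDunn()` — Kruskal-Wallis across conditions, then Dunn's
  rank-sum z tests of every condition against a designated *reference*
  (the knockout background), with tie-corrected pooled variance and
  Bonferroni adjustment over the reference-contrast family. A full
  pairwise family is available behind `family = "all"`, but the default
  mirrors the control-referenced design.
* `friedmanDunn()` — Friedman across within-cell phases (before /
  blocker / blocker + blocker) with cells as complete blocks, Dunn's
  versus the "before" phase. Incomplete blocks are an error that names
  the offending cells; a fully tied design yields statistic 0, p = 1.
* `rmAnovaDunnett()` — classic split-plot ANOVA (between: genotype;
  within: phase; `Error(cell)` strata) with Dunnett contrasts against
  the reference genotype via emmeans. For blocker time courses the
  conventional input is the response normalized per cell to its
  "before" value (`normalizeToPhase()`, making the baseline identically
  1).
* `wilcoxonPaired()` — exact two-sided signed-rank p when the sample is
  small and free of ties, normal approximation otherwise; an all-zero
  difference vector is degenerate and reported as p = 1 with a note.

Significance is starred at 0.05 / 0.01 / 0.001, and adjusted p-values
are never smaller than raw ones.

## The synthetic-imaging model

`generateSynapseField()` renders fields with known geometry: a diffuse
synapsin cloud (isotropic Gaussian density), an elongated PSD-95 bar
(rectangle) tangent to the cloud edge, and a protein-of-interest bar
parallel to PSD-95 displaced by a configurable signed offset along the
trans-synaptic axis. Each channel is convolved with a Gaussian PSF —
60 nm FWHM for the STED channels, 250 nm for confocal, both
config-exposed — then background is added, the blurred signal is Poisson
resampled, and Gaussian read noise is added, in that order (shot noise
acts on blurred photon flux; read noise is a detector property).

The noiseless image is computed as the *exact closed form* of the scene
density convolved with the PSF, evaluated at pixel centres: a blurred
rectangle separates into a product of two error-function box responses
in the bar frame, and a Gaussian cloud convolves to a Gaussian with
variances added. This choice, rather than rasterizing hard-edged
primitives and convolving numerically, keeps the ground truth
analytically checkable and makes the render exactly rotation
equivariant — rasterizing a hard edge first would alias under rotation
and contaminate the equivariance checks with render artefacts. It also
makes two invariants exact: doubling an amplitude doubles the noiseless
signal bitwise, and channel argmax separations equal the configured
offset to within a pixel.

Default parameters and their status:

| parameter | default | status |
|---|---|---|
| pixel size | 14.194 nm (synapse), 90.2 nm (soma) | matches the acquisition settings being emulated |
| STED / confocal PSF FWHM | 60 / 250 nm | typical for the instrument class; config-exposed |
| PSD-95 bar | 400 × 80 nm | assumption — chosen to look like cultured-neuron side views |
| synapsin cloud sigma | 200 nm | assumption — no measured cloud size is being reproduced |
| protein offset | −50 nm (presynaptic) | configurable; the −50 nm default is the regime of interest |
| amplitudes / background / read noise | 80–120 / 5 / 2 (photon scale) | an SNR at which single-synapse peaks are clearly resolvable |

Synapse centres are placed uniformly at random with orientations on
[0, 2π) (so profile extraction is exercised at arbitrary angles), a
border margin that keeps every 1000 × 200 nm profile ROI inside the
image, and a minimum centre separation of 1100 nm that keeps profile
rectangles disjoint (bounding-circle argument). Placement failure after
bounded retries raises an error that names the requested density.
Identical configuration and seed reproduce every pixel byte-for-byte.

`generateSomaField()` renders NeuN-like somata, nested nuclear discs and
an HA channel constant within each soma, so each cell's true donut mean
is known exactly. No PSF is applied in soma mode: at 90.2 nm pixels and
~12 µm cells, diffraction is irrelevant to donut means and a hard edge
keeps the ground truth exact.

What the generator deliberately does **not** emulate: STED depletion
physics and anti-Stokes background, vesicle-scale molecular labelling,
3-D structure and defocus, chromatic offsets between channels, spatially
varying background, sample drift. Passing recovery tests on these images
therefore validates the *quantification pipeline* — geometry, alignment,
windowing, statistics — not robustness to every real-world imaging
artefact.

## Verification strategy and problem sizes

The test suite validates each stage against an independent oracle:
Otsu against exhaustive between-class-variance search; smoothing against
brute-force windowed means; the area filter against the arithmetic
cutoff at both acquisition pixel sizes; profile extraction against
grid-motion equivariance (whole-pixel translations and 90° rotations are
bitwise identical on dyadic grids, where the transformed coordinates are
exactly representable; arbitrary rotations agree to <1% relative, the
bilinear interpolation regime); offset recovery against generator truth
(100 noisy synapses at the default SNR recover a −50 nm offset to well
within half a sample step); and the statistical wiring against simulated
global nulls (rejection rate at α = 0.05 within ±0.015, estimated with
5000 Monte-Carlo replicates in the test suite — enough that the
Monte-Carlo error is small against the band — and n = 20 per group) and
power cases. A zero-amplitude condition is compared against a
*matched-null* background: the same windowed-maximum statistic computed
on profiles drawn in a synapse-free field, because a windowed maximum of
noise is upward-biased relative to the raw background mean and comparing
unlike statistics would fabricate a difference. End-to-end, a
three-condition demo (two expressing, one at amplitude zero) must
separate the expressing conditions from the null condition at Dunn-adjusted
p < 0.001 with 100 synapses per condition, on 512 × 512 px fields of 10
synapses each — sizes chosen so the whole suite runs in minutes on one
core while keeping ≥ 100 sampling units where variability matters.

## Known limitations

* Alignment is at integer sample resolution; peak positions inherit a
  quantization of one pixel (14.194 nm), which averages out across
  synapses but bounds single-synapse precision.
* The automatic side-view detector is a convenience for synthetic and
  exploratory data. The quantified experimental design selects side-view
  synapses manually; detector annotations carry provenance `"auto"` so
  downstream tables keep the distinction.
* Bilinear interpolation attenuates sharp peaks sampled off-grid by up
  to ~0.5% of the peak; all conditions in a comparison share this
  attenuation, so it cancels in contrasts.
* The statistics module assumes the sampling units declared by the
  design (synapse / image / cell) are exchangeable; it does not model
  nesting of synapses within cultures beyond the repeat label it stores.
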