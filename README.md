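# presynQuant

Quantification of presynaptic protein localization from dual
confocal/STED images of cultured neurons — with a synthetic-imaging
ground-truth generator so that every stage of the analysis is verifiable
by parameter recovery.

## The problem

Voltage-gated Ca²⁺ channels are sorted into distinct neuronal
compartments: Ca~V~2s into the presynaptic active zone, Ca~V~1s into the
somatodendritic membrane. Experiments that dissect this targeting
(knockout backgrounds rescued with wild-type, chimeric or tagged
channels) need to answer, per construct: does it reach the active zone,
and at what level? Because the active zone sits only tens of nanometres
from the postsynaptic density, the question is resolved with STED
nanoscopy (~60 nm) against a confocal synaptic-vesicle reference, and
answered with a specific quantification recipe that this package
implements as tested, reusable code:

* **STED line profiles** at side-view synapses: a ~1000 × 200 nm
  rectangular ROI is drawn perpendicular to the elongated PSD-95
  structure; per-channel intensity profiles I(x) are sampled at one
  point per pixel (71 samples at 14.194 nm/px), averaging across the
  200 nm width. The PSD-95 trace is smoothed with a 5-px rolling mean,
  each synapse is aligned so the smoothed PSD-95 argmax sits at x = 0,
  profiles are averaged across synapses (mean ± SEM), and per-synapse
  peak intensities are extracted as max I(x) over |x| ≤ 100 nm
  (raw trace for the protein of interest, smoothed for PSD-95).
* **Confocal ROI quantification**: Otsu-threshold segmentation of the
  synapsin channel, 8-connected components, ROIs = components with area
  ≥ 0.05 µm² (pixel cutoff = ⌈0.05 µm² / pixelSize²⌉: 249 px at
  14.194 nm, 7 px at 90.2 nm); per-image level = unweighted mean of
  per-ROI means of the target channel.
* **Somatic donut ROIs**: mean target intensity over (somatic mask ∖
  nuclear mask), one value per cell.
* **Group statistics** with the design's sampling units and
  control-referenced post-hocs: Kruskal–Wallis + Dunn vs a reference
  condition, Friedman + Dunn vs a "before" phase (complete blocks),
  two-way repeated-measures ANOVA + Dunnett on responses normalized to
  baseline, and the Wilcoxon matched-pairs signed-rank test, starred at
  0.05/0.01/0.001.

The synthetic generator renders side-view synapses (diffuse synapsin
cloud, PSD-95 bar at its edge, protein-of-interest bar at a configurable
signed trans-synaptic offset) and somatic fields under exact closed-form
Gaussian-PSF optics with Poisson + read noise, and records every true
position, orientation, offset and amplitude. See the methods vignette
(`vignettes/quantifying-active-zone-localization.Rmd`) for the model,
parameter defaults, numerical choices and limitations.

## Worked example

Simulate a field of eight side-view synapses whose protein-of-interest
bar truly sits 50 nm presynaptic of PSD-95, then run the STED and
confocal quantifications:

```r
library(presynQuant)

cfg <- synthConfig(nSynapses = 8L, imageSizePx = c(512L, 512L),
                   cavOffsetNm = -50, rngSeed = 42L)
field <- generateSynapseField(cfg)
field$image
#> MultiChannelImage: 512 x 512 px, 14.194 nm/px
#>   channels: synapsin (confocal), psd95 (STED), poi (STED)

lps <- alignProfiles(extractProfiles(field$image,
                                     annotationsFromTruth(field$truth)))
summarizeProfiles(lps)
#> ProfileSummary: 8 synapses, grid [-497, 497] nm, peak window +/- 100 nm
#>   mean protein peak: 92.4226 | mean PSD-95 peak: 97.5055

roiMeanLevels(field$image, segmentSynapsin(field$image), "poi")
#> RoiTable 'image': 8 ROIs at 14.194 nm/px
#>   image summary (mean of per-ROI means):
#>     mean_poi = 13.4543
```

The mean protein peak (~92, arbitrary units) reads back the configured
bar amplitude (100, attenuated by the 60 nm PSF over an 80 nm bar, plus
background 5); all eight synapsin clouds are found as ROIs, and the
per-image confocal level (~13) reflects the diffuse protein signal
averaged over whole vesicle-cloud ROIs rather than its active-zone peak.
An end-to-end demo — three conditions with protein amplitudes
(100, 100, 0), peak extraction, and Kruskal–Wallis + Dunn against the
null condition — runs with:

```r
runPipeline(pipelineConfig(mode = "full-demo", outputDir = "demo-run",
                           seed = 1L))
```

or from a shell via `Rscript inst/scripts/presynquant.R --mode full-demo
--out demo-run --seed 1`. Outputs (peak tables, statistics report, run
manifest with seed and config hash) land in the output directory with
stable names; identical config + seed reproduce them byte-for-byte.

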