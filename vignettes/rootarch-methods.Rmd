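---
title: "Measuring root system architecture from seedling images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring root system architecture from seedling images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootarch)
```

## The measurement problem

Seedlings grown on moist blue blotter paper present their root system in
an effectively two-dimensional plane, where a fixed camera images one
plant per frame at a known calibration (100 px/cm by default). The
yellow-white roots contrast strongly with the blue paper, which makes
colour segmentation tractable; everything downstream — lengths, counts,
areas, angles, shape — is computed from the binary mask and its 1-px
skeleton. This vignette documents the models each stage uses, the
tunable parameters with their defaults and units, and the design choices
made where the method itself left the choice open.

## Segmentation

**Heuristic HSV rule.** A pixel is root if its hue lies outside the blue
paper band and it is bright enough. Defaults: background hue band
190–250°, foreground value ≥ 0.35, any saturation. Cleanup removes
connected components below `min_object_px` (100 px) and closes 1-px gaps
with a 3×3 structuring element. An image in which nothing survives gets
an empty mask with a `"no_root"` flag rather than an error, so batches
continue. The exact thresholds are tunable (`tune_thresholds()` grid
searches the band edges and value floor against a reference mask),
because in practice specular over-saturation of the paper shifts the
usable operating point between imaging sessions.

**K-means.** The pixel colour cloud is clustered in an HSV-derived space
(hue encoded circularly as saturation-weighted cosine/sine, plus value).
Unsupervised clusters need a labelling rule: the cluster whose centroid
hue is circularly farthest from a background anchor (220°) is declared
root; near-grey centroids carry no hue information and are forced to
background. Centroids are fitted on a 20 000-pixel subsample for speed,
then all pixels are assigned; the seed fixes initialisation, so results
are reproducible.

**Convolutional auto-encoder.** For images where fixed colour rules
fail, a small learned segmenter is provided: three 3×3 convolution
layers of 32 feature maps with ReLU, 2×2 max pooling after the first and
second, a mirrored decoder using nearest-neighbour upsampling, and a
final sigmoid map. The loss is binary cross-entropy plus soft Jaccard
loss; the optimiser is Adam at learning rate 0.001. The network is
implemented directly in R (im2col convolutions with cached gather
indices); its gradients are verified against numerical differentiation
in the test suite. Training runs k-fold cross-validation (default five
folds) and reports pixelwise F1 and IoU both pooled over pixels and
averaged over images, since either convention is in use in the
literature. At desk scale the package trains on 32×32 patches of
synthetic pairs; on those the held-out IoU exceeds 0.85. That figure
says the engine learns; it says nothing about performance on real
photographs, which vary in illumination, paper texture and root
occlusion that the generator does not emulate.

## Skeleton topology

The mask is thinned with the Guo–Hall algorithm. Guo–Hall was chosen
over Zhang–Suen deliberately: Zhang–Suen leaves 2-px diagonal
staircases, which inflate skeleton length by up to ~25 % and fabricate
branch pixels; Guo–Hall yields cleanly 8-thin skeletons. Before
thinning, enclosed background pockets of at most 25 px are filled: where
a lateral stroke meets the taproot, rasterisation can trap a sliver of
background, and topology-preserving thinning would faithfully keep it as
a spurious skeleton loop.

Pixels are classified by their 8-neighbourhood: endpoints have exactly
one neighbour; junctions have Hilditch crossing number ≥ 3 (the number
of separate branches entering the ring), which is robust where a plain
neighbour count is not. The skeleton becomes a graph with 8-connectivity
edges weighted by Euclidean step length; only the largest component is
kept as the root system (smaller ones are counted as debris).

**Primary root.** The taproot of a dicot seedling runs from the seed at
the top to the deepest tip. The primary path is therefore the
minimum-cost path from the topmost endpoint to the deepest endpoint,
with cost = step length + `turn_penalty` (default 2 px/radian) per
direction change, computed on the directed-arc graph. The penalty keeps
the path off steep laterals when loops offer alternatives; ties break
toward the smaller column.

**Spur pruning.** Thinning a wide region leaves short terminal branches.
Any branch whose weighted distance from an endpoint to the nearest true
junction is below `spur_px` (default 10 px) is deleted, iteratively,
never touching the primary path. The pruning radius matches the scale of
the widest strokes the platform produces; genuine laterals are an order
of magnitude longer.

**Laterals.** Removing the primary path splits the remaining skeleton
into components; each attaches to its nearest primary pixel and is
assigned left or right by the sign of the attachment column offset (a
component attached exactly on the path is decided by its second pixel,
remaining ties going left, a documented convention).

**Length metric.** Path length is chain code: 1 px per orthogonal step,
√2 per diagonal (switchable). This convention is simple and standard but
overestimates digitised sloped curves — up to 8.2 % at a 22.5° slope —
and junction regions deflect the thinned centreline slightly. On the
synthetic scenes the combined effect is a mean +3–4 % on primary-root
length; consumers comparing genotypes are unaffected (the bias is common
mode), but absolute lengths carry it.

## Traits

The full trait catalogue is emitted by `extract_traits()`. Choices worth
recording:

* *Upper/lower split.* "Upper third" is the top third of the root's own
  depth extent, not of the image, so traits are invariant to the crop
  window.
* *Solidity.* SOL = projected root area / convex-hull area of pixel
  centres, clipped at 1 (a blocky mask's pixel-centre hull can slightly
  underestimate the pixel-square area). A `solidity_mode = "skeleton"`
  variant divides skeleton pixels by hull area instead; it is
  scale-dependent and off by default.
* *Centre of point.* COP is operationalised as the median occupied row,
  normalised by the depth extent — a robust "absolute centre"
  counterpart to the centre of mass.
* *Primary-root solids.* The radius profile is the raw Euclidean
  distance-transform value at each primary-path pixel; DIA, PRA and VOL
  treat the root as stacked frusta. The distance transform measures to
  background pixel centres, so diameters carry a ~+0.5 px convention
  bias; at realistic soybean taproot widths (1–1.5 mm ≈ 10–15 px) this
  is a few percent.
* *Branch counts.* LRB slides a 5-px-high horizontal band down the
  image one row at a time, counts connected lateral segments left and
  right of the primary separately (8-connected labelling — 4-connected
  labelling would fragment diagonal laterals), and sums the per-side
  maxima. NLR counts merged junction clusters after spur removal. IRB
  counts connected components of the skeleton minus the primary path.
  Tip counts exceed IRB whenever a lateral forks.
* *Row profile.* MED/RMAX are the median/maximum number of horizontal
  skeleton runs per occupied row (a diagonal root counts once per row);
  MNR is the 84th percentile of per-row pixel sums with linear
  interpolation between order statistics; BSH = RMAX/MED.

## Angles

Each angle estimate comes from a square window (default 100×100 px) of
skeleton pixels: the window is low-pass filtered in the frequency domain
(lowest 25 % of the radial frequency range kept, then re-binarised at
half maximum — strong enough to merge 1-px stair-stepping, weak enough
to keep 100-px lines), and the dominant straight line is read off a
Hough accumulator at 1° orientation and 1-px offset resolution. Angles
are reported from the gravity direction (0° = straight down, 90° =
horizontal).

Window placement defines the three methods: LBA centres one window on
each lateral's attachment (that lateral's first segment only, primary
masked out); LRA tiles non-overlapping windows along the lateral's full
path, merging a trailing remainder shorter than half a window into the
previous chunk (sub-half-window slivers give unreliable Hough
estimates); RTA centres one window on each tip (distal segment). Per-window
angles are binned into 45 bins of 2° over [0°, 90°]; the modal angle is
the midpoint of the fullest bin, ties toward the smaller angle. On
constructed straight laterals the modal bin lands within one bin of the
true angle across 15–75°. The directionality comparison between two
angle distributions is a two-sample Kolmogorov–Smirnov test on the raw
per-window samples — KS assumes continuous data, so the binned
histograms are for display only.

## Shape profiles

The *mean boundary* profile casts rays from the foreground centroid in
equally spaced directions and records the mean distance of all
foreground-to-background crossings per direction (directions that miss
the root are interpolated circularly). The *convex hull* contour is the
counter-clockwise polygon of hull vertices of foreground pixel centres,
starting from the minimum-row vertex. Radial profiles expand in a real
Fourier series (exact DFT sums); contours expand in elliptical Fourier
descriptors with the closed-form per-segment integrals of the arc-length
parameterisation, optionally normalised so the first-harmonic semi-major
axis is 1 (size invariance is a flag, not the default, since absolute
size is itself informative). Reconstruction error is non-increasing in
the harmonic count by construction; the default display uses 5
harmonics, storage 20, maximum 100 (bounded by half the sampling rate to
avoid aliasing).

## Quantitative genetics

Replicated panels follow the two-way random-effects model
`y_ik = μ + g_i + b_k + e_ik`, all factors random, fitted by REML via
lme4; with a single block the block term is dropped and flagged. On
balanced toy designs the REML components equal the classical ANOVA
method-of-moments estimates, which the test suite asserts. Outliers are
removed per genotype and trait with Tukey fences at `k = 1.5` — a
literal "outside the interquartile range" rule would delete half of
every sample — and groups of fewer than 4 observations pass through
flagged. Entry-mean heritability is `σ²_g / (σ²_g + σ²_e/n)`; Tukey
groupings use a parallel one-way fixed-genotype ANOVA for the MSE with
`HSD = q(α, k, df)·sqrt(MSE/n*)` (harmonic-mean replicate count for
near-balanced data) and a compact letter display built from the maximal
contiguous ranges of the sorted means; CV_G is `sqrt(σ²_g)/mean`. The
replicate structure is interpreted as replicates nested within
genotype × block.

## The synthetic generator

`sample_blueprint()`/`render_blueprint()` draw and rasterise a
parametric root system: a natural cubic spline taproot through jittered
control points (control-point jitter sd 2 px — strongly gravitropic,
mildly sinuous, consistent with seedling taproots on germination paper
and with the chain-code metric's digitisation bias staying well inside
the 5 % length-recovery envelope), a linear width taper, and straight or
constant-curvature laterals. Rasterisation is subpixel-exact (a pixel is
foreground iff its centre lies within the stroke radius of the
unrounded sample point), and the scene adds Gaussian pixel noise
(sd 0.02), a thin blended edge ring, and optional specular blotches.
Analytic truth (Gauss–Legendre arc lengths, extents, per-lateral angles
and counts) accompanies every scene.

The default *guarantee class* is the configuration under which skeleton
analysis provably recovers the topology: the same number of laterals on
each side, attachments on a global alternating slot grid in the
upper-middle taproot (same-side separation two slots, sides staggered
one slot, so all junction nodes are distinct), near-identical per-side
angles (±1.5°, capped at 55° when a side holds several laterals),
lengths extended so every lateral of a side is still descending at the
side's deepest attachment row (this is what guarantees one sliding band
crosses all of them, the property the LRB counter needs), and laterals
never reaching below the taproot tip (so the deepest endpoint is
unambiguous). `make_panel()` builds replicated genotype panels on top:
genotype, block and replicate effects shift the taproot depth with known
variances, and one panel-wide lateral template with lengths proportional
to depth keeps total root length exactly linear in the depth shift — so
the designed variance components, and hence the designed heritability,
carry over to the measured trait.

What the generator does *not* emulate: uneven illumination, shadows,
root hairs, second-order laterals, crossing or merged parallel roots,
camera blur, and lens distortion. Tests passing on generated scenes
therefore validate the algorithms and their numerics, not robustness to
real-image nuisance factors.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: 100 seeded scenes
(400×300 px) for segmentation, topology and length recovery; 50 tapered
taproots at realistic widths for diameter/volume; constructed single
laterals at 15°–75° for angle recovery; 50 image/mask pairs with
five-fold cross-validation for the auto-encoder (32×32 patches, 20
epochs); 50 simulations of the 115-genotype × 14-replicate × 2-block
variance-component design; and one full 10-genotype × 14-replicate ×
2-block image panel through manifest → batch → statistics. These sizes
were chosen so the entire verification runs comfortably on a single CPU
while every claim is still measured, not assumed.

## Known limitations

* Chain-code length overestimates sloped digitised curves (bounded by
  8.2 %); junction regions add a small further positive bias to
  primary-root length.
* Crossing roots and merged parallel strokes are segmented as one
  object; the platform's operating procedure (separating roots before
  imaging) is assumed.
* Second-order laterals are not classified; a forked lateral counts as
  one independent branch with two tips.
* The distance-transform diameter convention carries a ~+0.5 px bias,
  noticeable on strokes thinner than ~6 px.
* The CAE is a desk-scale implementation; training beyond a few hundred
  small patches is not its design point.
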