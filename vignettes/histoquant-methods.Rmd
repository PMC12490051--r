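---
title: "Methods: segmentation, stereology and statistics in histoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, stereology and statistics in histoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoquant)
```

# Scope

histoquant quantifies whole-section histology from rodent brain-injury
studies along two tracks — fluorescence cell counting and stained-section
volumetry — and compares treatment groups with an assumption-checked test
router. This vignette is the package's account of how each stage works,
which knobs matter, what the synthetic phantoms do and do not emulate, and
where design decisions were genuinely open.

# Image normalisation

Sections are acquired as tile grids (5 across x 6 lengthwise in the
reference design) in 12-bit grayscale. `stitch()` pastes tiles at nominal
offsets; with zero overlap the mosaic is lossless, and with positive overlap
the later tile overwrites the seam. No blending or registration is applied:
counting operates on segmented objects, and seam aesthetics do not change
object counts. Feature-based registration of misaligned stages is out of
scope.

`convert_bit_depth()` maps the full sensor range linearly,
`v -> floor(v * 255 / 4095)`. A per-image min–max stretch would tie every
grey level to the brightest outlier pixel of that image and make counts
irreproducible across sections, so the fixed map is deliberate.

`gamma_correct()` applies `v -> round(vmax * (v/vmax)^gamma)`. The default
is `gamma = 1`: the acquisition pipeline this package models applies a gamma
correction whose exponent is not recorded, so the package never corrects
silently — the user states the exponent or gets the identity. On an 8-bit
grid the transform is invertible to within one grey level only in the
expansive-first direction (`gamma < 1` then `1/gamma`); compressing first
collapses dark levels irrecoverably (e.g. `gamma = 2` maps 0–16 onto 0–1),
which is a quantisation fact, not an implementation artefact.

# Cell counting

The pipeline is blur → binarise → marker-based watershed → size filter.

**Blur.** Gaussian, `blur_sigma_px = 2` px by default — enough to suppress
shot noise at the scale of a nucleus (radius ~6 px at 0.65 µm/px and 10x
magnification) without merging neighbours.

**Binarisation.** Otsu's threshold on the blurred histogram, foreground
strictly above the threshold (a pixel numerically equal to the cut stays
background; a `1e-9` guard absorbs blur round-off). A constant image has no
Otsu cut and yields an all-background mask with a warning rather than an
error, so a blank section counts zero cells instead of aborting a batch. A
fixed threshold is available for calibrated rigs.

**Markers and flooding.** Let `D` be the Euclidean distance transform of
the foreground. Markers are 8-connected components of
`{D >= f * max(D per component)}`, computed per foreground component, so
every component gets at least one marker and a component with several
well-expressed distance maxima gets one per maximum. The inverted distance
map is then flooded from the markers, restricted to the mask (implemented
with EBImage's seeded propagation); the object count equals the marker
count by construction.

The fraction `f` is the single most consequential parameter. A pair of
touching equal disks with radius `r` and centre separation `s` has
saddle-to-peak distance ratio `sqrt(1 - (s/2r)^2)` analytically, but
rasterisation inflates this at small radii: for `r = 8, s = 12` the
rasterised ratio is 0.744, and for `r = 6, s = 9` (separation 1.5 radii) it
reaches 0.82. Splitting requires `f` above the saddle ratio, while isolated
convex blobs are safe at any `f` because their supra-threshold set is
connected. The default `f = 0.9` therefore splits touching pairs down to
centre separations of about 1.5 radii at nucleus radii of ~6 px and above
— the same contact regime the phantom generator produces — while leaving
isolated nuclei whole. Pairs overlapping even more heavily than that merge
into one object under any fixed fraction; that regime is ambiguous even for
a human rater and is declared out of the package's resolution.

**Size filter.** Two modes. `fixed` drops objects below `min_area_px`.
`data_driven` (default) drops objects smaller than `data_driven_fraction`
(default 0.25) times the *median* object area of the same image: the
cutoff tracks the typical nucleus size of each image, so one calibration
serves sections imaged at different magnifications or stains with
different object sizes. The median is robust to both debris (small) and
clumps (large). Raising either cutoff can only reduce the count
(monotonicity is tested).

**Connectivity and conventions.** Components and markers are 8-connected;
rasters are `(row, col)`, origin top-left; areas are counted in pixels and
converted by `(pixel_size_um / 1000)^2`. EBImage's `bwlabel` is
4-connected, so the package re-labels with a diagonal union-find merge.

# Volumetry

**Tissue classification.** Stained tissue is separated from the white
slide in HSV space: background is low saturation (`s < 0.08`) *and* bright
(`v > 0.85`); everything else is tissue. The two thresholds are
interpretable — how grey and how bright the empty slide is — and their
defaults are permissive for any stained pixel (eosin pink, haematoxylin
purple, haemorrhage) while excluding near-white glass. Tissue specks under
`cleanup_px = 64` px are removed as debris.

**Cavity.** The lesion cavity is background enclosed by tissue: background
components not connected to the raster border. Lesions that breach the
cortical surface leave the cavity open to the border; with
`close_radius_px > 0` the tissue silhouette is morphologically closed
first, bridging breaches narrower than the closing disc. The option is off
by default because closing also bridges genuine narrow fissures; it is the
package's explicit resolution of a question the source methodology leaves
open, and the breach width it can bridge equals the chosen radius.

**Cavalieri estimate.** With equally spaced levels (spacing `d`) and
per-level mean areas `A_i` (technical replicates averaged first), the
volume is `V = d * sum(A_i)`, computed independently for tissue and
cavity. No end correction or shrinkage correction is applied, and the
coefficient of error of the estimator is not computed (out of scope). The
default scheme is six levels from bregma +1 to −4 mm at 1 mm spacing, ten
sections per level. Unequal spacing and levels missing from the scheme are
errors, not warnings: a silently wrong `d` scales the volume linearly.

On analytic phantoms the estimator recovers the discrete Cavalieri sum to
rasterisation accuracy: a cylinder of cross-section `pi * 25` mm² sampled
at the six default levels yields 471.2 mm³ against the analytic 471.24
(0.015 % relative error at 40 µm pixels), and an annulus with a 1 mm² hole
measures its cavity to within one pixel-perimeter band.

# Counts to animals, validation

Technical replicates are averaged per animal and channel (arithmetic mean,
kept real-valued); an animal with no sections for a requested channel is
flagged missing, never imputed as zero. The three marker ratios
(Iba1/DAPI, ED1/DAPI, Iba1/ED1) are computed per animal after aggregation;
a zero denominator flags the ratio undefined rather than dropping the row.

Validation against blinded manual counts uses the manual count as the
ground-truth denominator: per image, `|auto − manual| / manual * 100`;
per staining, the mean and sample SD (n − 1) of those errors. Images with
a manual count of zero are excluded with a warning (the percent error is
undefined there), and unmatched images are an error listing the orphans.

# Group statistics

The router mirrors standard practice in small-n animal studies: per-group
Shapiro–Wilk (minimum group size 3) and median-centred Levene, both at the
same `alpha = 0.05` as the main test. If all groups look normal and
variances homogeneous, one-way ANOVA with Tukey's HSD; otherwise
Kruskal–Wallis (tie-corrected) with Dunn's post hoc test. Dunn's z
statistics use the rank-sum formula with tie correction
`T = sum(t^3 − t) / (12(N − 1))` and Holm adjustment by default
(Bonferroni and unadjusted available). Normality is assessed per group
rather than on pooled residuals — either reading is defensible; this one
is fixed and stated. Post hoc tables are computed only when the omnibus
test is significant. All tests are two-sided. Degenerate inputs are
defined: an all-constant group routes non-parametric (a point mass is not
normal), and identical groups yield p = 1, never a rejection.

The routing perturbs the procedure's size only mildly: under a normal null
with three groups of eight, the Monte-Carlo type-I error at nominal 0.05
stays within [0.02, 0.08] (2000 replicates in the acceptance run), and a
5-SD location shift is detected with power ~1.

# What the phantoms emulate — and what they do not

`make_fluor_phantom()` renders isotropic Gaussian nuclei (sigma 6 px) with
peak amplitude 10x the noise SD over a flat background, additive Gaussian
noise (optional Poisson shot noise), on a 1024² 12-bit raster at 0.65
µm/px by default — plausible for 10x magnification; the source methodology
records neither pixel size nor cell diameters, so these are the package's
stated defaults, chosen once. Placement is rejection-sampled at a minimum
separation, with an explicit capacity error rather than silent truncation;
a configurable fraction of nuclei is placed at 1.5 blob radii from a
neighbour to create touching pairs. `make_hes_phantom()` renders disks and
annuli in eosin pink on near-white, recording *rasterised* pixel-tally
truth areas.

The phantoms deliberately do not emulate: intensity gradients and
vignetting across a mosaic, chromatic or focus variation, anisotropic or
textured nuclei, densely clumped aggregates beyond pairwise contact,
staining artefacts, or real tissue texture in the stained-section
phantoms. Exact recovery on phantoms therefore demonstrates that the
algorithmic chain is correct and self-consistent — not that the same
configuration transfers to real sections, where the published experience
is a mean error of ~12.5 % for nuclear staining and substantially worse
for cytoplasmic immunomarkers. The validation module exists precisely to
quantify that gap on real data.

# Problem sizes and runtime

Unit tests run phantoms at 256–512 px; the acceptance checks run the
50-phantom exact-recovery suite at the full 1024 px default (~2 s per
phantom), 2000 Monte-Carlo replicates for the type-I error, and the demo
study twice (3 x 8 animals, 2 replicates, 256/320 px rasters) for
byte-determinism — about two minutes end to end on one CPU. These sizes
are the package's chosen reference conditions; all generators scale up by
argument.

# Known limitations

- Marker generation is geometric (distance transform only); intensity
  valleys between touching nuclei are ignored, and pairs overlapping
  closer than ~1.5 radii are not split.
- The HSV tissue rule assumes a bright, low-saturation slide; slides with
  strong background staining would need re-tuned thresholds.
- The Cavalieri estimator reports no coefficient of error.
- Counts are per-channel independent; co-localisation (e.g. Iba1+ED1
  double positives) is out of scope.
- The statistics module assumes one value per animal after replicate
  averaging; mixed models for the replicate structure are out of scope.
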