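# histoquant

Automated quantification of whole-section histology for rodent brain-injury
studies: fluorescence cell counting, Cavalieri tissue/cavity volumetry, and
the group-comparison statistics that sit on top of both.

## The problem

Penetrating brain injury in the rat leaves a lesion cavity and a chronic
neuroinflammatory response (microglia, macrophages). Quantifying either from
histology means processing whole coronal sections — mosaics of dozens of
microscope fields — across several animals, bregma levels and technical
replicate sections, objectively and reproducibly. This package implements
that stack:

1. **Mosaicking and normalisation** — tiles acquired on a `W x H` grid
   (the reference design scans 5 across by 6 lengthwise, 30 fields per
   section) are stitched at their nominal offsets; 12-bit acquisitions are
   mapped to 8 bit with a fixed full-range linear map
   `v ↦ ⌊255 v / 4095⌋`, and gamma correction
   `v ↦ vmax (v / vmax)^γ` is available explicitly (default γ = 1).
2. **Cell counting** — Gaussian blur, Otsu binarisation, then
   *marker-based watershed*: markers are connected components of
   `{D ≥ f · max(D)}` per foreground component, where `D` is the Euclidean
   distance transform, and the inverted distance map is flooded from the
   markers within the mask. Touching nuclei split at the ridge between
   their distance maxima; the object count equals the marker count.
   Debris is removed by a data-driven size filter (drop objects below a
   fraction of the median object area).
3. **Cavalieri volumetry** — tissue is classified against the white slide
   by HSV colour thresholds, the lesion cavity is the background enclosed
   by tissue, areas come from pixel counting at a declared pixel size, and
   the volume over equally spaced coronal levels is
   `V = d · Σᵢ Āᵢ` (spacing `d`, per-level mean area `Āᵢ` after averaging
   technical replicates).
4. **Validation** — automated counts against blinded manual counts:
   per-image absolute percent error `|auto − manual| / manual × 100`,
   summarised per staining as mean ± sample SD.
5. **Statistics router** — per-group Shapiro–Wilk plus median-centred
   Levene decide between one-way ANOVA + Tukey HSD and Kruskal–Wallis +
   Dunn (Holm-adjusted), at α = 0.05, with post hoc tables only after a
   significant omnibus test.

Because no real images ship with the package, a **phantom generator**
produces fluorescent nuclei fields and stained-section phantoms with exact
ground truth (counts, centroids, rasterised areas), so every stage is
testable end to end.

## Worked example

```r
library(histoquant)

# 25 synthetic nuclei, then count them back
ph  <- make_fluor_phantom(n_cells = 25, seed = 42)
res <- count_section(ph$image)
res$count
#> [1] 25            # ph$truth_count is 25

# validation metric on three images with 5 / 10 / 22.5 % errors
validate_counts(
  data.frame(image_id = c("a","b","c"), channel = "DAPI",
             count = c(210, 220, 245)),
  data.frame(image_id = c("a","b","c"), channel = "DAPI",
             manual_count = c(200, 200, 200)))
#> <validation_report> automated vs manual counts
#>   DAPI: mean absolute error 12.5% (+/- 9.0%), n = 3 images

# Cavalieri volumes from six 1 mm-spaced annulus phantoms
sch  <- sectioning_scheme()            # bregma +1 .. -4 mm
meas <- do.call(rbind, lapply(sch$levels_mm, function(l) {
  p <- make_hes_phantom("annulus", tissue_area_mm2 = 70,
                        cavity_area_mm2 = 6, pixel_size_um = 40,
                        width = 320, height = 320)
  p$image$meta$level_mm <- l
  measure_section(p$image)
}))
cavalieri_volume(meas, sch)
#> <volume_estimate> tissue 420.0 mm^3, cavity 35.9 mm^3 (6 levels, 1 mm apart)

# routed group comparison on three null groups of 8
set.seed(1)
route_and_compare(list(B = rnorm(8, 10), RvD1 = rnorm(8, 10),
                       S = rnorm(8, 10)))
#> <comparison_result> route: kruskal_dunn
#>   Shapiro-Wilk p per group: B=0.444, RvD1=0.697, S=0.00405
#>   Levene (median-centred) p = 0.771
#>   Kruskal-Wallis: statistic = 0.875, p = 0.6456 (not significant at alpha = 0.05)
```

The counts above mean: all 25 planted nuclei were recovered exactly; the
validation report reproduces the mean ± SD convention; the volume estimate
is `1 mm × Σ` of the six mean cross-sections (420 mm³ of tissue around a
36 mm³ cavity); and on null data one non-normal-looking group routed the
comparison to the rank-based test, which correctly found nothing.

A full synthetic study (3 groups × 8 animals, three channels, six levels)
runs with `run_demo(seed = 7, out_dir = "demo_out")`, writing the per-section,
per-animal, ratio, volume and comparison tables as CSV. A command-line
front end with the same subcommands lives at `inst/cli/histoquant`.

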