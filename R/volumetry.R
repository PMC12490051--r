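#' Serial-sectioning scheme
#'
#' Describes where the coronal sections were cut: the bregma levels (mm,
#' anterior positive), which must be equally spaced, and the number of
#' technical replicate sections per level. The default is the study design
#' of six equally spaced levels spanning bregma +1 to -4 mm (1 mm apart),
#' ten sections per level.
#'
#' @param levels_mm strictly decreasing, equally spaced bregma levels (mm).
#' @param sections_per_level technical replicates cut at each level.
#' @return An object of class `sectioning_scheme` with the levels, the
#'   inter-level `spacing_mm` and `sections_per_level`.
#' @export
sectioning_scheme <- function(levels_mm = c(1, 0, -1, -2, -3, -4),
                              sections_per_level = 10L) {
  stopifnot(length(levels_mm) >= 1, sections_per_level >= 1)
  spacing <- if (length(levels_mm) > 1) -diff(levels_mm) else NA_real_
  if (length(levels_mm) > 1) {
    if (any(spacing <= 0)) stop("levels_mm must be strictly decreasing")
    if (diff(range(spacing)) > 1e-9)
      stop("levels_mm must be equally spaced")
  }
  structure(list(levels_mm = as.numeric(levels_mm),
                 spacing_mm = if (length(levels_mm) > 1) spacing[1] else NA_real_,
                 sections_per_level = as.integer(sections_per_level)),
            class = "sectioning_scheme")
}

#' Classify tissue versus slide background by pixel colour
#'
#' Haematoxylin/eosin staining colours tissue pink-purple against the
#' near-white slide. In HSV space the slide background is low-saturation
#' *and* bright; everything else is tissue. After thresholding, tissue
#' specks smaller than `cleanup_px` (dust, debris) are removed.
#'
#' @param img an RGB [section_image()].
#' @param s_min background saturation ceiling (background has `s < s_min`).
#' @param v_min background brightness floor (background has `v > v_min`).
#' @param cleanup_px minimum area (px) of a tissue component to keep.
#' @return A list of two logical matrices, `tissue` and `background`
#'   (complements of each other).
#' @export
classify_tissue <- function(img, s_min = 0.08, v_min = 0.85,
                            cleanup_px = 64L) {
  stopifnot(inherits(img, "section_image"))
  px <- img$pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("classify_tissue expects an RGB image")
  d <- dim(px)[1:2]
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 2^img$bit_depth - 1)
  background <- matrix(hsv["s", ] < s_min & hsv["v", ] > v_min, d[1], d[2])
  tissue <- !background
  if (cleanup_px > 0L && any(tissue)) {
    comp <- label_components(tissue, connectivity = 8)
    areas <- tabulate(comp[comp > 0L])
    drop <- which(areas < cleanup_px)
    if (length(drop)) tissue[comp %in% drop] <- FALSE
  }
  list(tissue = tissue, background = !tissue)
}

#' Find the lesion cavity within a tissue mask
#'
#' The cavity is the background enclosed by tissue: background-connected
#' components that do not touch the raster border. A lesion that breaches
#' the section surface leaves the cavity open to the border and would
#' otherwise be missed; with `close_radius_px > 0` the tissue silhouette is
#' morphologically closed first, so a narrow breach is bridged and the
#' cavity behind it still counted.
#'
#' @param tissue logical tissue mask `(row, col)`.
#' @param close_radius_px radius (px) of the disc used to close the tissue
#'   silhouette before hole detection; 0 (default) disables breach handling.
#' @return A logical cavity mask, always disjoint from `tissue`.
#' @export
find_cavity <- function(tissue, close_radius_px = 0L) {
  stopifnot(is.logical(tissue) || all(tissue %in% c(0, 1)))
  tissue <- tissue > 0
  silhouette <- tissue
  if (close_radius_px > 0L && any(tissue)) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius_px) + 1L,
                                shape = "disc")
    silhouette <- from_ebi(EBImage::closing(as_ebi(tissue * 1), brush)) > 0
  }
  filled <- from_ebi(EBImage::fillHull(as_ebi(silhouette * 1))) > 0
  cavity <- filled & !silhouette & !tissue
  cavity
}

#' Measure mask areas in physical units
#'
#' Pixel counting with an explicit pixel size: `area_mm2 = n_pixels *
#' (pixel_size_um / 1000)^2`. The pixel size must be supplied — it is never
#' assumed.
#'
#' @param tissue,cavity logical masks of identical shape.
#' @param pixel_size_um pixel edge length, micrometres.
#' @param level_mm bregma level of the section (recorded in the output).
#' @param replicate technical replicate index.
#' @return A one-row data frame: `level_mm`, `replicate`,
#'   `tissue_area_mm2`, `cavity_area_mm2`.
#' @export
measure_areas <- function(tissue, cavity, pixel_size_um,
                          level_mm = NA_real_, replicate = 1L) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be supplied and positive")
  if (!identical(dim(tissue), dim(cavity)))
    stop("tissue and cavity masks must have the same shape")
  if (any(tissue & cavity))
    stop("tissue and cavity masks must be disjoint")
  px_mm2 <- (pixel_size_um / 1000)^2
  data.frame(level_mm = level_mm, replicate = as.integer(replicate),
             tissue_area_mm2 = sum(tissue) * px_mm2,
             cavity_area_mm2 = sum(cavity) * px_mm2)
}

#' Cavalieri volume estimate from serial section areas
#'
#' The Cavalieri principle estimates a solid's volume from equally spaced
#' parallel sections as `V = d * sum(A_i)`, where `d` is the inter-section
#' spacing and `A_i` the cross-sectional area at level `i`. Technical
#' replicate sections at the same level are averaged first, then the sum is
#' taken over levels. Tissue and cavity volumes are estimated independently
#' from their respective area columns. No end or shrinkage correction is
#' applied.
#'
#' @param measurements data frame of per-section areas as produced by
#'   [measure_areas()] (rows may repeat a level: technical replicates).
#' @param scheme a [sectioning_scheme()]; every measured level must appear
#'   in the scheme.
#' @return An object of class `volume_estimate`: list with
#'   `tissue_volume_mm3`, `cavity_volume_mm3`, `n_levels_used`,
#'   `spacing_mm` and the per-level mean areas.
#' @export
cavalieri_volume <- function(measurements, scheme = sectioning_scheme()) {
  stopifnot(inherits(scheme, "sectioning_scheme"),
            is.data.frame(measurements), nrow(measurements) >= 1)
  if (is.na(scheme$spacing_mm))
    stop("a single-level scheme has no spacing; supply >= 2 levels or use the area directly")
  bad <- setdiff(round(measurements$level_mm, 9), round(scheme$levels_mm, 9))
  if (length(bad))
    stop(sprintf("measured level(s) %s not in the sectioning scheme",
                 paste(bad, collapse = ", ")))
  if (any(measurements$tissue_area_mm2 < 0) ||
      any(measurements$cavity_area_mm2 < 0))
    stop("areas must be non-negative")
  mean_t <- tapply(measurements$tissue_area_mm2, measurements$level_mm, mean)
  mean_c <- tapply(measurements$cavity_area_mm2, measurements$level_mm, mean)
  structure(list(
    tissue_volume_mm3 = scheme$spacing_mm * sum(mean_t),
    cavity_volume_mm3 = scheme$spacing_mm * sum(mean_c),
    n_levels_used = length(mean_t),
    spacing_mm = scheme$spacing_mm,
    level_mean_areas = data.frame(
      level_mm = as.numeric(names(mean_t)),
      tissue_area_mm2 = as.numeric(mean_t),
      cavity_area_mm2 = as.numeric(mean_c))),
    class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf(
    "<volume_estimate> tissue %.1f mm^3, cavity %.1f mm^3 (%d levels, %.2g mm apart)\n",
    x$tissue_volume_mm3, x$cavity_volume_mm3, x$n_levels_used, x$spacing_mm))
  invisible(x)
}

#' Measure one stained section image end to end
#'
#' Colour classification, cavity detection and area measurement in one call.
#'
#' @param img an RGB [section_image()] of a stained section.
#' @param s_min,v_min,cleanup_px see [classify_tissue()].
#' @param close_radius_px see [find_cavity()].
#' @param level_mm,replicate provenance recorded in the output (defaults
#'   taken from the image metadata).
#' @return A one-row data frame as from [measure_areas()].
#' @export
measure_section <- function(img, s_min = 0.08, v_min = 0.85,
                            cleanup_px = 64L, close_radius_px = 0L,
                            level_mm = img$meta$level_mm,
                            replicate = img$meta$replicate) {
  cls <- classify_tissue(img, s_min = s_min, v_min = v_min,
                         cleanup_px = cleanup_px)
  cavity <- find_cavity(cls$tissue, close_radius_px = close_radius_px)
  measure_areas(cls$tissue, cavity, pixel_size_um = img$pixel_size_um,
                level_mm = level_mm,
                replicate = if (is.na(replicate)) 1L else replicate)
}
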