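#' Segmentation configuration
#'
#' Collects the tunable parameters of the nuclei-counting pipeline:
#' Gaussian pre-smoothing, binarisation, watershed marker generation and the
#' object size filter.
#'
#' @param blur_sigma_px standard deviation of the Gaussian pre-blur, px.
#' @param binarize_method `"otsu"` (threshold maximising between-class
#'   variance of the blurred histogram) or `"fixed"`.
#' @param fixed_threshold grey level for `binarize_method = "fixed"`;
#'   foreground is strictly above this value.
#' @param marker_distance_fraction fraction in `(0, 1)` of each foreground
#'   component's maximum distance-transform value at which watershed markers
#'   are cut. Higher values split more aggressively; the default 0.9 splits
#'   touching equal-sized nuclei whose centres are at least about 1.5 radii
#'   apart, while an isolated convex nucleus always yields exactly one
#'   marker.
#' @param size_filter_mode `"data_driven"` (drop objects smaller than
#'   `data_driven_fraction` times the median object area of the same image)
#'   or `"fixed"` (drop objects below `min_area_px`).
#' @param min_area_px fixed minimum object area, px; required iff
#'   `size_filter_mode = "fixed"`.
#' @param data_driven_fraction fraction of the median object area below
#'   which objects are discarded in data-driven mode.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(blur_sigma_px = 2, binarize_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       marker_distance_fraction = 0.9,
                       size_filter_mode = c("data_driven", "fixed"),
                       min_area_px = NULL, data_driven_fraction = 0.25) {
  binarize_method <- match.arg(binarize_method)
  size_filter_mode <- match.arg(size_filter_mode)
  stopifnot(blur_sigma_px > 0,
            marker_distance_fraction > 0, marker_distance_fraction < 1,
            data_driven_fraction > 0, data_driven_fraction <= 1)
  if (binarize_method == "fixed" && is.null(fixed_threshold))
    stop("`fixed_threshold` is required with binarize_method = \"fixed\"")
  if (binarize_method == "otsu" && !is.null(fixed_threshold))
    stop("`fixed_threshold` must be NULL with binarize_method = \"otsu\"")
  if (size_filter_mode == "fixed" && is.null(min_area_px))
    stop("`min_area_px` is required with size_filter_mode = \"fixed\"")
  structure(list(blur_sigma_px = blur_sigma_px,
                 binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold,
                 marker_distance_fraction = marker_distance_fraction,
                 size_filter_mode = size_filter_mode,
                 min_area_px = min_area_px,
                 data_driven_fraction = data_driven_fraction),
            class = "seg_config")
}

#' Binarize a grayscale section image
#'
#' Smooths the image with a Gaussian of `blur_sigma_px` and thresholds the
#' result: Otsu's method on the blurred histogram by default, or a fixed
#' grey level. Foreground is strictly above the threshold. A constant image
#' has no Otsu cut point and yields an all-background mask with a warning.
#'
#' @param img an 8-bit grayscale [section_image()].
#' @param cfg a [seg_config()].
#' @return A logical matrix `(row, col)`; `TRUE` is foreground.
#' @export
binarize <- function(img, cfg = seg_config()) {
  stopifnot(inherits(img, "section_image"), inherits(cfg, "seg_config"))
  if (length(dim(img$pixels)) == 3L)
    stop("binarize expects a grayscale image")
  if (img$bit_depth != 8L)
    stop("binarize expects an 8-bit image; apply convert_bit_depth() first")
  e <- as_ebi(img$pixels / 255)
  blurred <- from_ebi(EBImage::gblur(e, sigma = cfg$blur_sigma_px)) * 255
  if (cfg$binarize_method == "fixed") {
    thr <- cfg$fixed_threshold
  } else {
    if (diff(range(blurred)) < .Machine$double.eps^0.5) {
      warning("constant image: Otsu threshold undefined, returning all background")
      return(matrix(FALSE, nrow(blurred), ncol(blurred)))
    }
    thr <- EBImage::otsu(as_ebi(blurred / 255), range = c(0, 1),
                         levels = 256) * 255
  }
  # strict "above": the tiny guard keeps pixels numerically equal to the
  # threshold (up to blur round-off) in the background
  blurred > thr + 1e-9
}

#' Marker-based watershed segmentation
#'
#' The counting pipeline's central step. The binarised foreground is
#' distance-transformed; markers are the 8-connected components of the set
#' of pixels whose distance value reaches `marker_distance_fraction` of
#' their own component's maximum (so every foreground component receives at
#' least one marker, and a component containing several well-expressed
#' distance maxima receives one marker per maximum). The inverted distance
#' map is then flooded from the markers, restricted to the foreground mask,
#' which splits touching nuclei along the ridge between their distance
#' maxima. The number of labelled objects always equals the number of
#' markers.
#'
#' @param img an 8-bit grayscale [section_image()].
#' @param cfg a [seg_config()].
#' @return An object of class `label_map`: list with `labels` (integer
#'   matrix, 0 = background, `1..K` objects) and `K` (object count).
#' @export
watershed_segment <- function(img, cfg = seg_config()) {
  mask <- binarize(img, cfg)
  empty <- structure(list(labels = matrix(0L, nrow(mask), ncol(mask)), K = 0L),
                     class = "label_map")
  if (!any(mask)) return(empty)
  dist <- from_ebi(EBImage::distmap(as_ebi(mask * 1)))
  comp <- label_components(mask, connectivity = 8)
  maxd <- as.numeric(tapply(dist[comp > 0L], comp[comp > 0L], max))
  marker_mask <- comp > 0L &
    dist >= cfg$marker_distance_fraction * maxd[pmax(comp, 1L)]
  markers <- label_components(marker_mask, connectivity = 8)
  n_markers <- max(markers)
  ws <- EBImage::propagate(as_ebi(-dist), seeds = as_ebi(markers),
                           mask = as_ebi(mask))
  labels <- from_ebi(ws)
  storage.mode(labels) <- "integer"
  labels <- relabel_sequential(labels)
  K <- max(labels)
  if (K != n_markers)
    warning(sprintf("flooded %d objects from %d markers", K, n_markers))
  structure(list(labels = labels, K = K), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d objects\n",
              nrow(x$labels), ncol(x$labels), x$K))
  invisible(x)
}

#' Per-object measurements of a label map
#'
#' @param labels a [watershed_segment()] result.
#' @param img the [section_image()] the labels were derived from (supplies
#'   pixel size and intensities).
#' @return A data frame with one row per object: `label`, `area_px`,
#'   `area_mm2`, `centroid_row`, `centroid_col`, `mean_intensity`.
#' @export
region_table <- function(labels, img) {
  stopifnot(inherits(labels, "label_map"), inherits(img, "section_image"))
  L <- labels$labels
  if (labels$K == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      area_mm2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), mean_intensity = numeric(0)))
  idx <- which(L > 0L)
  lab <- L[idx]
  rows <- (idx - 1L) %% nrow(L) + 1L
  cols <- (idx - 1L) %/% nrow(L) + 1L
  area <- tabulate(lab, nbins = labels$K)
  px_mm2 <- (img$pixel_size_um / 1000)^2
  data.frame(
    label = seq_len(labels$K),
    area_px = area,
    area_mm2 = area * px_mm2,
    centroid_row = as.numeric(rowsum(rows, lab)) / area,
    centroid_col = as.numeric(rowsum(cols, lab)) / area,
    mean_intensity = as.numeric(rowsum(as.numeric(img$pixels[idx]), lab)) / area)
}

#' Filter labelled objects by size
#'
#' Removes segmentation debris. In fixed mode, objects with `area_px <
#' min_area_px` are dropped. In data-driven mode the cutoff adapts to the
#' image itself: objects smaller than `data_driven_fraction` times the
#' median object area are dropped, so the rule tracks the typical nucleus
#' size of each image rather than an absolute calibration. Surviving labels
#' are re-indexed `1..K'` preserving their original order.
#'
#' @param labels a `label_map`.
#' @param regions the matching [region_table()].
#' @param cfg a [seg_config()].
#' @return A list with the filtered `labels` and `regions`.
#' @export
size_filter <- function(labels, regions, cfg = seg_config()) {
  stopifnot(inherits(labels, "label_map"))
  if (nrow(regions) == 0L) return(list(labels = labels, regions = regions))
  cutoff <- if (cfg$size_filter_mode == "fixed") cfg$min_area_px
            else cfg$data_driven_fraction * stats::median(regions$area_px)
  keep <- regions$area_px >= cutoff
  L <- labels$labels
  map <- integer(labels$K)
  map[regions$label[keep]] <- seq_len(sum(keep))
  L[L > 0L] <- map[L[L > 0L]]
  storage.mode(L) <- "integer"
  new_regions <- regions[keep, , drop = FALSE]
  new_regions$label <- seq_len(sum(keep))
  rownames(new_regions) <- NULL
  list(labels = structure(list(labels = L, K = sum(keep)), class = "label_map"),
       regions = new_regions)
}

#' Count segmented cells
#'
#' @param labels a `label_map`.
#' @return Integer object count `K`.
#' @export
count_cells <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  labels$K
}

#' Run the full counting pipeline on one section image
#'
#' Bit-depth conversion (if needed), gamma correction, binarisation,
#' marker-based watershed, measurement and size filtering in one call.
#'
#' @param img a grayscale [section_image()] (8-, 12- or 16-bit).
#' @param cfg a [seg_config()].
#' @param gamma gamma-correction exponent applied before segmentation.
#' @return A list: `count`, `labels` (`label_map`), `regions` (data frame),
#'   `mask` (logical matrix).
#' @export
count_section <- function(img, cfg = seg_config(), gamma = 1) {
  if (img$bit_depth != 8L) img <- convert_bit_depth(img)
  img <- gamma_correct(img, gamma)
  labels <- watershed_segment(img, cfg)
  regions <- region_table(labels, img)
  filt <- size_filter(labels, regions, cfg)
  list(count = count_cells(filt$labels), labels = filt$labels,
       regions = filt$regions, mask = filt$labels$labels > 0L)
}
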