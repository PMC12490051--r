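#' Section image container
#'
#' A `section_image` wraps one channel of a scanned section: an integer pixel
#' raster plus the acquisition metadata the downstream quantification needs
#' (bit depth, physical pixel size, channel label, and the section's place in
#' the study design).
#'
#' @param pixels integer matrix `(row, col)` for grayscale, or an
#'   `row x col x 3` array for RGB.
#' @param bit_depth one of 8, 12, 16. All pixel values must be strictly
#'   below `2^bit_depth`.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param channel channel label, e.g. `"DAPI"`, `"Iba1"`, `"ED1"`, `"HES"`.
#' @param animal,group,level_mm,replicate optional provenance: animal id,
#'   treatment group, bregma level in mm, technical replicate index.
#' @return An object of class `section_image`.
#' @export
section_image <- function(pixels, bit_depth = 8L, pixel_size_um = 0.65,
                          channel = "unknown", animal = NA_character_,
                          group = NA_character_, level_mm = NA_real_,
                          replicate = NA_integer_) {
  stopifnot(bit_depth %in% c(8L, 12L, 16L), is.numeric(pixel_size_um),
            pixel_size_um > 0)
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3L)))
    stop("`pixels` must be a matrix (grayscale) or a 3-plane array (RGB)")
  if (any(pixels < 0) || any(pixels >= 2^bit_depth))
    stop("pixel values must lie in [0, 2^bit_depth)")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um, channel = channel,
         meta = list(animal = animal, group = group, level_mm = level_mm,
                     replicate = as.integer(replicate))),
    class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("<section_image> %d x %d %s, %d-bit, %.3g um/px, channel %s\n",
              d[1], d[2], kind, x$bit_depth, x$pixel_size_um, x$channel))
  if (!is.na(x$meta$animal))
    cat(sprintf("  animal %s (group %s), bregma %+.1f mm, replicate %d\n",
                x$meta$animal, x$meta$group, x$meta$level_mm, x$meta$replicate))
  invisible(x)
}

#' Convert a high-bit-depth image to 8 bit
#'
#' Linear full-range mapping `v -> floor(v * 255 / (2^bit_depth - 1))`. The
#' map uses the fixed sensor range rather than the per-image min/max so that
#' the grey level assigned to a structure never depends on the brightest
#' outlier in the field; the ordering of pixel values is preserved.
#'
#' @param img a grayscale [section_image()] with bit depth 12 or 16
#'   (an 8-bit input is returned unchanged with a warning).
#' @param target target bit depth; only 8 is supported.
#' @return An 8-bit [section_image()].
#' @export
convert_bit_depth <- function(img, target = 8L) {
  stopifnot(inherits(img, "section_image"), target == 8L)
  if (img$bit_depth == 8L) {
    warning("image is already 8-bit; returning unchanged")
    return(img)
  }
  out <- img
  out$pixels <- floor(img$pixels * 255 / (2^img$bit_depth - 1))
  storage.mode(out$pixels) <- "integer"
  out$bit_depth <- 8L
  out
}

#' Gamma-correct an image
#'
#' Applies the normalised power transform
#' `v -> round(vmax * (v / vmax)^gamma)` with `vmax = 2^bit_depth - 1`
#' (round half up). The transform is monotone non-decreasing and fixes both
#' endpoints, so it changes contrast, never ordering. The default
#' `gamma = 1` is the identity: any correction must be requested explicitly.
#'
#' @param img a grayscale [section_image()].
#' @param gamma positive exponent; `< 1` brightens, `> 1` darkens.
#' @return A [section_image()] of the same bit depth.
#' @export
gamma_correct <- function(img, gamma = 1) {
  stopifnot(inherits(img, "section_image"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive number")
  if (gamma == 1) return(img)
  vmax <- 2^img$bit_depth - 1
  out <- img
  out$pixels <- floor(vmax * (img$pixels / vmax)^gamma + 0.5)
  storage.mode(out$pixels) <- "integer"
  out
}

#' Tile grid for whole-section mosaics
#'
#' Holds the rectangular grid of fields acquired across one section. Tiles
#' are indexed `(col, row)`, 0-based, matching the acquisition order: `grid_w`
#' fields across the width and `grid_h` lengthwise (the study design scans
#' 5 across by 6 lengthwise, 30 fields per section).
#'
#' @param tiles list of [section_image()] tiles, or `NULL` entries for
#'   missing slots. Ordered row-major: slot `(col = i, row = j)` is element
#'   `j * grid_w + i + 1`.
#' @param grid_w,grid_h grid dimensions (columns across width, rows along
#'   length).
#' @param overlap_px overlap between adjacent tiles in pixels.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, grid_w, grid_h, overlap_px = 0L) {
  stopifnot(length(tiles) == grid_w * grid_h, overlap_px >= 0)
  structure(list(tiles = tiles, grid_w = as.integer(grid_w),
                 grid_h = as.integer(grid_h),
                 overlap_px = as.integer(overlap_px)),
            class = "tile_grid")
}

#' Stitch a tile grid into one whole-section image
#'
#' Pastes tiles at their nominal grid offsets. With zero overlap the mosaic
#' is lossless: every tile is recoverable by cropping. With positive overlap
#' the later tile (raster-scan order) overwrites the shared band; no blending
#' is applied because downstream counting operates on segmented objects, not
#' on seam appearance.
#'
#' @param grid a [tile_grid()]; all slots must be filled and all tiles must
#'   share dimensions, bit depth and channel.
#' @return A [section_image()] of size
#'   `grid_h * tile_h - (grid_h - 1) * overlap` by
#'   `grid_w * tile_w - (grid_w - 1) * overlap`.
#' @export
stitch <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  idx <- function(i, j) j * grid$grid_w + i + 1L
  for (j in seq_len(grid$grid_h) - 1L)
    for (i in seq_len(grid$grid_w) - 1L)
      if (is.null(grid$tiles[[idx(i, j)]]))
        stop(sprintf("missing tile at grid slot (col %d, row %d)", i, j))
  t1 <- grid$tiles[[1]]
  dims <- dim(t1$pixels)
  for (tl in grid$tiles) {
    if (!identical(dim(tl$pixels), dims)) stop("tiles differ in dimensions")
    if (tl$bit_depth != t1$bit_depth) stop("tiles differ in bit depth")
    if (!identical(tl$channel, t1$channel)) stop("tiles differ in channel")
  }
  th <- dims[1]; tw <- dims[2]; ov <- grid$overlap_px
  if (ov >= min(th, tw)) stop("overlap_px must be smaller than the tile size")
  H <- grid$grid_h * th - (grid$grid_h - 1L) * ov
  W <- grid$grid_w * tw - (grid$grid_w - 1L) * ov
  out <- matrix(0L, H, W)
  for (j in seq_len(grid$grid_h) - 1L) {
    for (i in seq_len(grid$grid_w) - 1L) {
      r0 <- j * (th - ov); c0 <- i * (tw - ov)
      out[(r0 + 1):(r0 + th), (c0 + 1):(c0 + tw)] <-
        grid$tiles[[idx(i, j)]]$pixels
    }
  }
  res <- t1
  res$pixels <- out
  res
}

#' Read a section image from a TIFF file
#'
#' Grayscale images are returned as integer rasters at the declared bit
#' depth; RGB images as an `row x col x 3` 8-bit array.
#'
#' @param path TIFF file path.
#' @param bit_depth declared acquisition bit depth (12-bit data is stored in
#'   16-bit containers; the declaration controls the value range checks and
#'   the 12-to-8-bit conversion).
#' @param ... further arguments passed to [section_image()].
#' @return A [section_image()].
#' @export
read_section_tiff <- function(path, bit_depth = 8L, ...) {
  raw <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    px <- round(raw[, , 1:3] * 255)
    storage.mode(px) <- "integer"
    return(section_image(px, bit_depth = 8L, ...))
  }
  scale <- if (max(raw) <= 1) 2^bit_depth - 1 else 1
  px <- round(raw * scale)
  storage.mode(px) <- "integer"
  section_image(px, bit_depth = bit_depth, ...)
}

#' Write a section image to a TIFF file
#'
#' Grayscale 8-bit images are saved as 8-bit RGB (the grey plane replicated
#' three times), matching the acquisition software's save convention; all
#' computation in this package stays single-channel. Higher bit depths are
#' saved as 16-bit grayscale.
#'
#' @param img a [section_image()].
#' @param path output file path.
#' @param rgb save 8-bit grayscale as replicated RGB (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(img, path, rgb = TRUE) {
  stopifnot(inherits(img, "section_image"))
  px <- img$pixels
  if (length(dim(px)) == 3L) {
    tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  } else if (img$bit_depth == 8L && rgb) {
    arr <- array(px / 255, dim = c(dim(px), 3L))
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    tiff::writeTIFF(px / (2^img$bit_depth - 1), path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}
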