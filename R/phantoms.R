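# Synthetic phantoms with exact ground truth. Every downstream module is
# testable against these without any external data.

#' Generate a fluorescent-nuclei phantom
#'
#' Renders `n_cells` blob-like nuclei on a noisy background. Each nucleus is
#' an isotropic Gaussian intensity profile of scale `blob_radius_px`, with
#' peak amplitude `amplitude_factor * noise_sd` above the background level so
#' that well-separated nuclei are unambiguously recoverable. Noise is
#' additive Gaussian (optionally Poisson shot noise on top), clipped to the
#' declared bit range.
#'
#' A fraction `overlap_fraction` of the nuclei is deliberately placed within
#' one blob diameter of an already-placed nucleus to create touching pairs;
#' the remaining nuclei keep all pairwise centre distances at or above
#' `min_separation_px`.
#'
#' @param n_cells number of nuclei to place (`>= 0`).
#' @param width,height raster size in pixels.
#' @param blob_radius_px Gaussian scale (sigma) of the nucleus profile, px.
#' @param min_separation_px minimum pairwise centre distance for
#'   non-overlapping placements, px.
#' @param overlap_fraction fraction in `[0, 1]` of nuclei placed touching a
#'   neighbour.
#' @param bit_depth raster bit depth (default 12, as acquired).
#' @param background background grey level.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param amplitude_factor blob peak amplitude in units of `noise_sd`.
#' @param shot_noise if `TRUE`, replace each pixel by a Poisson draw with
#'   that mean before clipping.
#' @param pixel_size_um physical pixel size recorded in the output.
#' @param channel channel label in `{nuclear, marker1, marker2}`.
#' @param seed RNG seed; the phantom is a pure function of its arguments.
#' @return A list of class `fluor_phantom` with elements `image` (a
#'   [section_image()]), `truth_centroids` (n x 2 matrix, `(row, col)`),
#'   `truth_count`, `channel` and `params`.
#' @export
make_fluor_phantom <- function(n_cells, width = 1024L, height = 1024L,
                               blob_radius_px = 6, min_separation_px = 40,
                               overlap_fraction = 0, bit_depth = 12L,
                               background = 200, noise_sd = 50,
                               amplitude_factor = 10, shot_noise = FALSE,
                               pixel_size_um = 0.65, channel = "nuclear",
                               seed = 1L) {
  stopifnot(n_cells >= 0, overlap_fraction >= 0, overlap_fraction <= 1,
            blob_radius_px > 0, min_separation_px > 0)
  margin <- ceiling(3 * blob_radius_px) + 1
  if (n_cells > 0 &&
      (width - 2 * margin <= 0 || height - 2 * margin <= 0))
    stop("raster too small for the requested blob radius")
  # capacity guard: disks of radius min_separation/2 must fit in the field
  if (n_cells * pi * (min_separation_px / 2)^2 >
      0.6 * (width - 2 * margin) * (height - 2 * margin))
    stop(sprintf(
      "cannot place %d nuclei at min separation %.1f px in a %d x %d field",
      n_cells, min_separation_px, width, height))

  with_seed(seed, {
    n_touch <- round(overlap_fraction * n_cells)
    n_free <- n_cells - n_touch
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_free) {
      cand <- c(stats::runif(1, margin, height - margin),
                stats::runif(1, margin, width - margin))
      ok <- nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_separation_px
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 200L * max(n_free, 1L))
        stop("placement infeasible: could not satisfy min_separation_px")
    }
    # touching partners: offset ~1.5 blob radii from an existing nucleus
    for (k in seq_len(n_touch)) {
      anchor <- centers[sample.int(nrow(centers), 1L), ]
      repeat {
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- anchor + 1.5 * blob_radius_px * c(cos(ang), sin(ang))
        if (cand[1] >= margin && cand[1] <= height - margin &&
            cand[2] >= margin && cand[2] <= width - margin) break
      }
      centers <- rbind(centers, cand)
    }

    vmax <- 2^bit_depth - 1
    amplitude <- amplitude_factor * noise_sd
    img <- matrix(background, height, width)
    # render each blob on a local 3-sigma window
    r3 <- ceiling(3 * blob_radius_px)
    for (k in seq_len(nrow(centers))) {
      rc <- centers[k, ]
      rows <- max(1, floor(rc[1]) - r3):min(height, ceiling(rc[1]) + r3)
      cols <- max(1, floor(rc[2]) - r3):min(width, ceiling(rc[2]) + r3)
      dr <- outer(rows - rc[1], cols - rc[2], function(a, b) a^2 + b^2)
      img[rows, cols] <- img[rows, cols] +
        amplitude * exp(-dr / (2 * blob_radius_px^2))
    }
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    if (shot_noise) img <- stats::rpois(length(img), pmax(img, 0))
    img <- matrix(pmin(pmax(round(img), 0), vmax), height, width)
    storage.mode(img) <- "integer"

    si <- section_image(img, bit_depth = bit_depth,
                        pixel_size_um = pixel_size_um, channel = channel)
    structure(
      list(image = si,
           truth_centroids = unname(centers),
           truth_count = nrow(centers),
           channel = channel,
           params = list(blob_radius_px = blob_radius_px,
                         min_separation_px = min_separation_px,
                         overlap_fraction = overlap_fraction,
                         background = background, noise_sd = noise_sd,
                         amplitude = amplitude, shot_noise = shot_noise,
                         seed = seed)),
      class = "fluor_phantom")
  })
}

#' Generate a stained-section phantom with known areas
#'
#' Renders an RGB phantom of a haematoxylin/eosin-stained section: tissue in
#' eosin pink on a near-white slide background, optionally with an enclosed
#' cavity (a background-coloured hole inside the tissue). The recorded truth
#' areas are the *rasterised* pixel tallies converted to mm^2, not the
#' analytic request — rasterisation makes the two differ by up to about one
#' perimeter band of pixels.
#'
#' @param shape `"disk"` (solid tissue disk; cavity must be 0),
#'   `"annulus"` (tissue ring around a cavity) or `"cylinder-slice"`
#'   (alias for a constant-cross-section disk, used for volumetric phantoms).
#' @param tissue_area_mm2 analytic tissue area to draw, mm^2.
#' @param cavity_area_mm2 analytic cavity area, mm^2 (0 for none).
#' @param pixel_size_um pixel edge length, micrometres.
#' @param width,height raster size in pixels.
#' @param open_cavity if `TRUE`, a channel is cut from the cavity to the
#'   raster border, emulating a lesion that breaches the cortical surface.
#' @param tissue_rgb,background_rgb 8-bit colours used for the two classes.
#' @return A list of class `hes_phantom` with the RGB [section_image()], the
#'   rasterised `truth_tissue_area_mm2` and `truth_cavity_area_mm2`, and
#'   `pixel_size_um`.
#' @export
make_hes_phantom <- function(shape = c("disk", "annulus", "cylinder-slice"),
                             tissue_area_mm2, cavity_area_mm2 = 0,
                             pixel_size_um = 10, width = 512L, height = 512L,
                             open_cavity = FALSE,
                             tissue_rgb = c(214, 121, 148),
                             background_rgb = c(247, 246, 245)) {
  shape <- match.arg(shape)
  stopifnot(tissue_area_mm2 >= 0, cavity_area_mm2 >= 0)
  if (shape == "disk" && cavity_area_mm2 > 0)
    stop("a disk has no cavity; use shape = \"annulus\"")
  px_mm <- (pixel_size_um / 1000)^2            # mm^2 per pixel
  r_out_px <- sqrt((tissue_area_mm2 + cavity_area_mm2) / pi) /
    (pixel_size_um / 1000)
  r_in_px <- sqrt(cavity_area_mm2 / pi) / (pixel_size_um / 1000)
  if (2 * r_out_px + 4 > min(width, height))
    stop("requested areas do not fit the raster at this pixel size")

  cr <- (height + 1) / 2; cc <- (width + 1) / 2
  d2 <- outer((seq_len(height) - cr)^2, (seq_len(width) - cc)^2, `+`)
  footprint <- d2 <= r_out_px^2
  cavity <- d2 <= r_in_px^2 & cavity_area_mm2 > 0
  if (open_cavity && any(cavity)) {
    # cut a channel straight up from the cavity to the border
    chan_w <- max(3, round(r_in_px / 3))
    cols <- round(cc + seq(-chan_w / 2, chan_w / 2))
    cavity[1:ceiling(cr), cols] <- cavity[1:ceiling(cr), cols] |
      footprint[1:ceiling(cr), cols]
  }
  tissue <- footprint & !cavity

  img <- array(0L, dim = c(height, width, 3L))
  for (p in 1:3)
    img[, , p] <- ifelse(tissue, tissue_rgb[p], background_rgb[p])
  storage.mode(img) <- "integer"
  si <- section_image(img, bit_depth = 8L, pixel_size_um = pixel_size_um,
                      channel = "HES")
  structure(
    list(image = si,
         truth_tissue_area_mm2 = sum(tissue) * px_mm,
         truth_cavity_area_mm2 = sum(cavity) * px_mm,
         truth_tissue_px = sum(tissue),
         truth_cavity_px = sum(cavity),
         pixel_size_um = pixel_size_um,
         open_cavity = open_cavity),
    class = "hes_phantom")
}

#' Generate a study cohort design
#'
#' Randomly divides the surviving animals into treatment groups of equal
#' size, and attaches the serial-sectioning scheme (bregma levels and
#' technical replicates per level) used for histology.
#'
#' @param n_operated number of animals operated.
#' @param n_deaths number lost before group assignment.
#' @param n_groups number of treatment groups.
#' @param group_labels labels, recycled to `n_groups` (defaults to the
#'   baseline / treated / saline design `B`, `RvD1`, `S`).
#' @param levels_mm bregma levels sampled, mm (anterior positive), strictly
#'   decreasing.
#' @param sections_per_level technical replicates cut at each level.
#' @param seed RNG seed for the random assignment.
#' @return A list of class `cohort_design` with a `animals` data frame
#'   (`animal_id`, `group`), the levels, `sections_per_level` and the
#'   attrition count.
#' @export
make_cohort <- function(n_operated = 25L, n_deaths = 1L, n_groups = 3L,
                        group_labels = c("B", "RvD1", "S"),
                        levels_mm = c(1, 0, -1, -2, -3, -4),
                        sections_per_level = 10L, seed = 1L) {
  stopifnot(n_operated >= 1, n_deaths >= 0, n_deaths < n_operated,
            n_groups >= 1, sections_per_level >= 1)
  if (any(diff(levels_mm) >= 0))
    stop("levels_mm must be strictly decreasing (anterior to posterior)")
  n <- n_operated - n_deaths
  if (n %% n_groups != 0L)
    stop(sprintf("%d surviving animals cannot be divided equally into %d groups",
                 n, n_groups))
  labels <- rep_len(group_labels, n_groups)
  assignment <- with_seed(seed, sample(rep(labels, each = n / n_groups)))
  structure(
    list(animals = data.frame(
           animal_id = sprintf("A%02d", seq_len(n)),
           group = assignment,
           stringsAsFactors = FALSE),
         levels_mm = levels_mm,
         sections_per_level = as.integer(sections_per_level),
         attrition = as.integer(n_deaths),
         seed = seed),
    class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  tab <- table(x$animals$group)
  cat(sprintf("<cohort_design> %d animals (%d lost), groups: %s\n",
              nrow(x$animals), x$attrition,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d bregma levels (%+.1f to %+.1f mm), %d sections/level\n",
              length(x$levels_mm), max(x$levels_mm), min(x$levels_mm),
              x$sections_per_level))
  invisible(x)
}

#' Write a phantom and its ground truth to disk
#'
#' Saves the raster as TIFF and the ground truth as a sidecar CSV (one row
#' per object for fluorescence phantoms; one row of areas for stained-section
#' phantoms).
#'
#' @param phantom a `fluor_phantom` or `hes_phantom`.
#' @param path output TIFF path; the CSV is written next to it with suffix
#'   `_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  truth_path <- sub("\\.tiff?$", "", path)
  truth_path <- paste0(truth_path, "_truth.csv")
  write_section_tiff(phantom$image, path, rgb = FALSE)
  if (inherits(phantom, "fluor_phantom")) {
    df <- data.frame(object = seq_len(phantom$truth_count),
                     row = phantom$truth_centroids[, 1],
                     col = phantom$truth_centroids[, 2])
    utils::write.csv(df, truth_path, row.names = FALSE)
  } else {
    utils::write.csv(
      data.frame(tissue_area_mm2 = phantom$truth_tissue_area_mm2,
                 cavity_area_mm2 = phantom$truth_cavity_area_mm2,
                 pixel_size_um = phantom$pixel_size_um),
      truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a cohort design to CSV
#'
#' One row per (animal, level, replicate), the layout consumed by the
#' quantification and volumetry drivers.
#'
#' @param design a [make_cohort()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(design, path) {
  stopifnot(inherits(design, "cohort_design"))
  grid <- expand.grid(replicate = seq_len(design$sections_per_level),
                      level_mm = design$levels_mm,
                      animal_id = design$animals$animal_id,
                      stringsAsFactors = FALSE)
  grid$group <- design$animals$group[match(grid$animal_id,
                                           design$animals$animal_id)]
  utils::write.csv(grid[, c("animal_id", "group", "level_mm", "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}
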