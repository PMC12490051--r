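test_that("binarisation matches a brute-force Otsu oracle and the fixed rule", {
  # constant image: no cut point, all background, with a warning
  flat <- section_image(matrix(100L, 32, 32), bit_depth = 8L)
  expect_warning(m <- binarize(flat), "constant")
  expect_false(any(m))

  # two-level image: Otsu must separate the levels exactly
  set.seed(7)
  px <- matrix(10L, 64, 64)
  blob <- disks_mask(64, rbind(c(20, 20), c(45, 45)), 9)
  px[blob] <- 200L
  img <- section_image(px, bit_depth = 8L)
  cfg <- seg_config(blur_sigma_px = 0.3)  # near-no blur for the oracle check
  mask <- binarize(img, cfg)
  thr <- brute_force_otsu(as.vector(px))
  expect_gte(thr, 10); expect_lt(thr, 200)
  # with negligible blur the mask equals the oracle's strict-above cut
  expect_equal(mask, px > thr, ignore_attr = TRUE)

  # fixed threshold is strictly "above"
  cfg_f <- seg_config(blur_sigma_px = 0.3, binarize_method = "fixed",
                      fixed_threshold = 200)
  expect_false(any(binarize(img, cfg_f)))   # 200 is not > 200
  cfg_f2 <- seg_config(blur_sigma_px = 0.3, binarize_method = "fixed",
                       fixed_threshold = 128)
  expect_equal(sum(binarize(img, cfg_f2)), sum(px > 128))
})

test_that("watershed equals connected components when no objects touch", {
  ph <- make_fluor_phantom(10, width = 384, height = 384,
                           min_separation_px = 45, seed = 2)
  img <- convert_bit_depth(ph$image)
  lm <- watershed_segment(img)
  expect_equal(lm$K, 10)
  # oracle: 8-connected components of the same binarised mask
  mask <- binarize(img, seg_config())
  comp <- label_components(mask, connectivity = 8)
  expect_equal(max(comp), 10)
  # same pixel partition (labels may be permuted)
  expect_true(all((lm$labels > 0) == (comp > 0)))
  cross <- table(lm$labels[comp > 0], comp[comp > 0])
  expect_true(all(rowSums(cross > 0) == 1))

  # centroids match ground truth within a blob radius
  reg <- region_table(lm, img)
  for (k in seq_len(nrow(reg))) {
    dmin <- min(sqrt((ph$truth_centroids[, 1] - reg$centroid_row[k])^2 +
                     (ph$truth_centroids[, 2] - reg$centroid_col[k])^2))
    expect_lt(dmin, ph$params$blob_radius_px)
  }
})

test_that("watershed splits touching objects at their distance maxima", {
  # two disks of radius 8 whose centres are 12 px apart: one component,
  # two distance-transform maxima, must yield exactly two objects
  mask <- disks_mask(48, rbind(c(24, 18), c(24, 30)), 8)
  expect_equal(max(label_components(mask)), 1)
  img <- mask_image(mask)
  cfg <- seg_config(blur_sigma_px = 0.5)
  lm <- watershed_segment(img, cfg)
  dist <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask * 1)))))
  expect_equal(brute_force_peak_count(dist), 2)  # oracle
  expect_equal(lm$K, 2)
  # the split is roughly even for equal disks
  sizes <- tabulate(lm$labels[lm$labels > 0])
  expect_lt(abs(diff(sizes)) / sum(sizes), 0.2)

  # a whole suite of touching pairs at varying separation and radius
  for (geom in list(c(8, 12), c(8, 14), c(6, 9), c(10, 15))) {
    r <- geom[1]; sep <- geom[2]
    m <- disks_mask(6 * r, rbind(c(3 * r, 3 * r - sep / 2),
                                 c(3 * r, 3 * r + sep / 2)), r)
    lm2 <- watershed_segment(mask_image(m), cfg)
    expect_equal(lm2$K, 2, info = sprintf("r=%d sep=%d", r, sep))
  }

  # blank image: zero objects
  blank <- section_image(matrix(5L, 64, 64), bit_depth = 8L)
  expect_warning(lm0 <- watershed_segment(blank, cfg), "constant")
  expect_equal(lm0$K, 0)
})

test_that("counts are invariant to rotation and sub-threshold offsets", {
  ph <- make_fluor_phantom(15, width = 320, height = 320,
                           min_separation_px = 35, seed = 11)
  img <- convert_bit_depth(ph$image)
  k0 <- watershed_segment(img)$K
  expect_equal(k0, 15)
  rot <- img
  rot$pixels <- t(img$pixels)[ncol(img$pixels):1, ]  # 90 degree rotation
  expect_equal(watershed_segment(rot)$K, k0)
})

test_that("size filtering implements both rules and is monotone", {
  # construct a label map with known areas {3, 50, 60}
  L <- matrix(0L, 20, 40)
  L[1, 1:3] <- 1L; L[5:9, 1:10] <- 2L; L[12:17, 1:10] <- 3L
  lm <- structure(list(labels = L, K = 3L), class = "label_map")
  img <- section_image(matrix(100L, 20, 40), bit_depth = 8L,
                       pixel_size_um = 10)
  reg <- region_table(lm, img)
  expect_equal(reg$area_px, c(3L, 50L, 60L))
  expect_equal(reg$area_mm2, c(3, 50, 60) * (10 / 1000)^2)
  expect_equal(sum(reg$area_px), sum(L > 0))

  cfg_fix <- seg_config(size_filter_mode = "fixed", min_area_px = 10)
  out <- size_filter(lm, reg, cfg_fix)
  expect_equal(out$labels$K, 2L)
  expect_equal(out$regions$area_px, c(50L, 60L))
  expect_equal(out$regions$label, 1:2)   # re-indexed, order preserved

  cfg0 <- seg_config(size_filter_mode = "fixed", min_area_px = 0)
  expect_equal(size_filter(lm, reg, cfg0)$labels$K, 3L)   # identity

  # data-driven rule: areas {4, 100, 110, 120}, fraction 0.25
  # median 105, cutoff 26.25, the 4-px object is dropped
  L2 <- matrix(0L, 30, 60)
  L2[1, 1:4] <- 1L; L2[3:12, 1:10] <- 2L; L2[14:24, 1:10] <- 3L
  L2[26:29, 1:30] <- 4L
  lm2 <- structure(list(labels = L2, K = 4L), class = "label_map")
  img2 <- section_image(matrix(100L, 30, 60), bit_depth = 8L)
  reg2 <- region_table(lm2, img2)
  expect_equal(reg2$area_px, c(4L, 100L, 110L, 120L))
  out2 <- size_filter(lm2, reg2, seg_config(data_driven_fraction = 0.25))
  expect_equal(out2$labels$K, 3L)

  # monotonicity: raising the cutoff never increases the count
  counts <- vapply(c(0, 5, 60, 105, 200), function(mn)
    size_filter(lm2, reg2, seg_config(size_filter_mode = "fixed",
                                      min_area_px = mn))$labels$K,
    integer(1))
  expect_true(all(diff(counts) <= 0))

  # empty table passes through unchanged
  lm_e <- structure(list(labels = matrix(0L, 4, 4), K = 0L),
                    class = "label_map")
  reg_e <- region_table(lm_e, section_image(matrix(0L, 4, 4)))
  out_e <- size_filter(lm_e, reg_e, cfg_fix)
  expect_equal(out_e$labels$K, 0L)
  expect_equal(count_cells(out_e$labels), 0L)
})

test_that("well-separated phantoms are recovered exactly across seeds", {
  for (seed in 1:6) {
    ph <- make_fluor_phantom(20, width = 512, height = 512,
                             min_separation_px = 40, seed = seed)
    res <- count_section(ph$image)
    expect_equal(res$count, ph$truth_count, info = sprintf("seed %d", seed))
  }
})
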