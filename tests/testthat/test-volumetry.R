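test_that("colour classification separates stain from slide background", {
  # single pixels with known colours
  white <- section_image(array(255L, dim = c(1, 1, 3)), bit_depth = 8L)
  expect_true(classify_tissue(white, cleanup_px = 0)$background[1, 1])
  pink <- section_image(array(c(230L, 120L, 150L), dim = c(1, 1, 3)),
                        bit_depth = 8L)
  expect_true(classify_tissue(pink, cleanup_px = 0)$tissue[1, 1])

  # phantom: tissue pixel tally matches ground truth
  hp <- make_hes_phantom("annulus", tissue_area_mm2 = 4, cavity_area_mm2 = 1,
                         pixel_size_um = 10, width = 300, height = 300)
  cls <- classify_tissue(hp$image)
  expect_equal(sum(cls$tissue), hp$truth_tissue_px)
  expect_true(all(cls$tissue == !cls$background))

  # grayscale input is rejected
  expect_error(classify_tissue(section_image(matrix(0L, 4, 4))), "RGB")
})

test_that("cavity detection agrees with a border flood-fill oracle", {
  # solid disk: no cavity
  solid <- disks_mask(80, rbind(c(40, 40)), 25)
  expect_false(any(find_cavity(solid)))

  # annulus: the hole is the cavity, oracle is a flood fill from the border
  hole <- disks_mask(80, rbind(c(40, 40)), 12)
  ring <- disks_mask(80, rbind(c(40, 40)), 25) & !hole
  cav <- find_cavity(ring)
  expect_equal(cav, brute_force_holes(ring))
  expect_false(any(cav & ring))            # disjoint from tissue
  expect_equal(sum(cav), sum(hole))

  # full-background image has nothing enclosed
  expect_false(any(find_cavity(matrix(FALSE, 50, 50))))

  # a breached cavity is missed without closing, captured with it
  breach <- ring
  breach[38:42, 1:40] <- FALSE             # cut a channel to the border
  expect_false(any(find_cavity(breach)))
  cav_closed <- find_cavity(breach, close_radius_px = 6)
  expect_gt(sum(cav_closed), 0.7 * sum(hole))
  expect_false(any(cav_closed & breach))
})

test_that("area measurement is plain pixel counting at the stated scale", {
  m <- matrix(FALSE, 50, 50); m[1:40, 1:25] <- TRUE   # 1000 px
  none <- matrix(FALSE, 50, 50)
  a <- measure_areas(m, none, pixel_size_um = 10)
  expect_equal(a$tissue_area_mm2, 0.1)     # 1000 x (0.01 mm)^2
  expect_equal(a$cavity_area_mm2, 0)
  # doubling the pixel size quadruples the area
  a2 <- measure_areas(m, none, pixel_size_um = 20)
  expect_equal(a2$tissue_area_mm2, 4 * a$tissue_area_mm2)
  expect_error(measure_areas(m, none), "pixel_size_um")
  expect_error(measure_areas(m, m, pixel_size_um = 10), "disjoint")
})

test_that("Cavalieri estimate is spacing times the sum of level means", {
  sch <- sectioning_scheme(c(1, 0, -1, -2, -3, -4))
  expect_equal(sch$spacing_mm, 1)
  expect_equal(length(sch$levels_mm), 6)

  # six levels of 1 mm^2 at 1 mm spacing -> 6 mm^3
  meas <- data.frame(level_mm = sch$levels_mm, replicate = 1L,
                     tissue_area_mm2 = 1, cavity_area_mm2 = 0)
  v <- cavalieri_volume(meas, sch)
  expect_equal(v$tissue_volume_mm3, 6)
  expect_equal(v$cavity_volume_mm3, 0)

  # replicates are averaged within level before the sum
  meas2 <- rbind(meas, transform(meas, tissue_area_mm2 = 3, replicate = 2L))
  expect_equal(cavalieri_volume(meas2, sch)$tissue_volume_mm3, 6 * 2)

  # linearity and permutation invariance
  set.seed(1)
  meas3 <- data.frame(level_mm = sch$levels_mm, replicate = 1L,
                      tissue_area_mm2 = runif(6, 10, 80),
                      cavity_area_mm2 = runif(6, 0, 5))
  v3 <- cavalieri_volume(meas3, sch)
  v3c <- cavalieri_volume(transform(meas3, tissue_area_mm2 = 2.5 * tissue_area_mm2,
                                    cavity_area_mm2 = 2.5 * cavity_area_mm2), sch)
  expect_equal(v3c$tissue_volume_mm3, 2.5 * v3$tissue_volume_mm3)
  expect_equal(v3c$cavity_volume_mm3, 2.5 * v3$cavity_volume_mm3)
  perm <- meas3[sample(6), ]
  expect_equal(cavalieri_volume(perm, sch)$tissue_volume_mm3,
               v3$tissue_volume_mm3)

  # two-level scheme: single level with spacing d gives d * A
  sch2 <- sectioning_scheme(c(0, -2))
  v1 <- cavalieri_volume(data.frame(level_mm = 0, replicate = 1L,
                                    tissue_area_mm2 = 7, cavity_area_mm2 = 0),
                         sch2)
  expect_equal(v1$tissue_volume_mm3, 2 * 7)

  # contract violations
  expect_error(sectioning_scheme(c(1, 0, -2)), "equally spaced")
  expect_error(cavalieri_volume(transform(meas, level_mm = level_mm - 10),
                                sch), "not in the sectioning scheme")
})

test_that("an imaged cylinder phantom recovers the analytic volume", {
  sch <- sectioning_scheme()
  area <- pi * 5^2   # 78.54 mm^2 cross-section
  meas <- do.call(rbind, lapply(sch$levels_mm, function(l) {
    p <- make_hes_phantom("cylinder-slice", tissue_area_mm2 = area,
                          pixel_size_um = 40, width = 320, height = 320)
    p$image$meta$level_mm <- l
    measure_section(p$image)
  }))
  v <- cavalieri_volume(meas, sch)
  analytic <- sch$spacing_mm * 6 * area    # discrete Cavalieri sum
  expect_lt(abs(v$tissue_volume_mm3 - analytic) / analytic, 0.005)

  # annulus phantom: measured cavity within one perimeter band of truth
  hp <- make_hes_phantom("annulus", tissue_area_mm2 = 5, cavity_area_mm2 = 1,
                         pixel_size_um = 10, width = 400, height = 400)
  m <- measure_section({hp$image$meta$level_mm <- 0; hp$image})
  r_in_mm <- sqrt(1 / pi)
  band <- 2 * pi * r_in_mm * (10 / 1000)   # perimeter x one pixel, mm^2
  expect_lt(abs(m$cavity_area_mm2 - 1), band)
  expect_equal(m$cavity_area_mm2, hp$truth_cavity_area_mm2)
})

test_that("refining the sectioning spacing converges for a convex solid", {
  # sphere of radius 4 mm sampled on coronal planes: A(z) = pi (R^2 - z^2)
  R <- 4
  vol_true <- 4 / 3 * pi * R^3
  est <- vapply(c(2, 1, 0.5, 0.25), function(d) {
    z <- seq(R - d / 2, -(R - d / 2), by = -d)
    sch <- sectioning_scheme(z, sections_per_level = 1L)
    meas <- data.frame(level_mm = z, replicate = 1L,
                       tissue_area_mm2 = pi * (R^2 - z^2),
                       cavity_area_mm2 = 0)
    cavalieri_volume(meas, sch)$tissue_volume_mm3
  }, numeric(1))
  err <- abs(est - vol_true) / vol_true
  expect_true(all(diff(err) < 0))          # monotone improvement
  expect_lt(err[4], 0.01)
})
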