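# Shared fixture builders for the test suite.

# A small section image with a single bright disk on dark background.
disk_image <- function(size = 64L, center = c(32, 32), radius = 10,
                       fg = 200L, bg = 10L, bit_depth = 8L) {
  d2 <- outer((seq_len(size) - center[1])^2, (seq_len(size) - center[2])^2, `+`)
  px <- matrix(ifelse(d2 <= radius^2, fg, bg), size, size)
  storage.mode(px) <- "integer"
  section_image(px, bit_depth = bit_depth)
}

# Binary mask of n disks at given centers (row, col) and radius.
disks_mask <- function(size, centers, radius) {
  m <- matrix(FALSE, size, size)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(size) - centers[k, 1])^2,
                (seq_len(size) - centers[k, 2])^2, `+`)
    m <- m | (d2 <= radius^2)
  }
  m
}

# Mask -> high-contrast 8-bit section image (mask value 200, background 10).
mask_image <- function(mask, fg = 200L, bg = 10L) {
  px <- ifelse(mask, fg, bg)
  storage.mode(px) <- "integer"
  section_image(px, bit_depth = 8L)
}

# Independent brute-force Otsu: maximise between-class variance over all
# 8-bit cut points; foreground is strictly above the returned threshold.
brute_force_otsu <- function(v) {
  v <- as.integer(round(v))
  best_t <- 0L; best_var <- -1
  for (t in 0:254) {
    w0 <- mean(v <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- mean(v[v <= t]); m1 <- mean(v[v > t])
    bv <- w0 * w1 * (m0 - m1)^2
    if (bv > best_var) { best_var <- bv; best_t <- t }
  }
  best_t
}

# Independent flood fill of the background from the raster border
# (4-connected); returns the mask of enclosed background (holes).
brute_force_holes <- function(tissue) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  reach <- matrix(FALSE, nr, nc)
  queue <- which(!tissue & (row(tissue) %in% c(1, nr) |
                            col(tissue) %in% c(1, nc)))
  reach[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        j <- (cc - 1) * nr + rr
        if (!tissue[j] && !reach[j]) { reach[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  !tissue & !reach
}

# Brute-force count of local maxima of the distance transform (a pixel at
# least as large as all 8 neighbours and above half the global max),
# clustering plateau maxima that touch.
brute_force_peak_count <- function(dist) {
  nr <- nrow(dist); nc <- ncol(dist)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dist
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (dist >= pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  is_max <- is_max & dist > 0.5 * max(dist)
  max(label_components(is_max, connectivity = 8))
}
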