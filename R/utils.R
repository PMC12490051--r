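# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# (row, col) matrix -> EBImage Image (x = col, y = row).
as_ebi <- function(mat) EBImage::Image(t(mat))

# EBImage Image -> (row, col) matrix.
from_ebi <- function(img) t(EBImage::imageData(img))

#' Label connected components of a binary mask
#'
#' Integer labelling of the foreground of a binary mask. The package
#' convention is 8-connectivity (pixels touching edge- or corner-wise belong
#' to the same object); 4-connectivity is available for completeness.
#'
#' @param mask logical or 0/1 matrix, `(row, col)` indexed.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 is background, objects are
#'   labelled `1..K` in raster-scan order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- (mask > 0) * 1
  lab <- from_ebi(EBImage::bwlabel(as_ebi(m)))  # 4-connected
  storage.mode(lab) <- "integer"
  k <- max(lab)
  if (connectivity == 8L && k > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal adjacencies missed by 4-connectivity
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(k)
      find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(k), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_sequential(lab)
}

# Re-index nonzero labels as 1..K in scan order of first occurrence.
relabel_sequential <- function(lab) {
  v <- as.vector(lab)
  old <- unique(v[v > 0L])
  if (length(old) == 0L) return(lab)
  map <- integer(max(old))
  map[old] <- seq_along(old)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  storage.mode(lab) <- "integer"
  lab
}
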