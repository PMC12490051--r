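#' Average technical replicates into per-animal counts
#'
#' Each animal contributes one or more technical replicate sections per
#' channel; the per-animal value is the arithmetic mean of its replicate
#' counts (kept real-valued, never rounded). The operation is idempotent:
#' applying it to an already-aggregated table returns the table unchanged.
#'
#' @param counts data frame with columns `animal_id`, `group`, `channel`,
#'   `count` and (optionally) `section_id`, `replicate`.
#' @param channels channels that every animal is expected to have; animals
#'   with no rows for one of these are reported in the `missing` attribute,
#'   never silently treated as zero.
#' @return A data frame with one row per (animal, channel): `animal_id`,
#'   `group`, `channel`, `count`, `n_replicates`. Missing (animal, channel)
#'   pairs, if any, are attached as attribute `"missing"`.
#' @export
aggregate_replicates <- function(counts, channels = unique(counts$channel)) {
  stopifnot(is.data.frame(counts),
            all(c("animal_id", "group", "channel", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  agg <- stats::aggregate(count ~ animal_id + group + channel, data = counts,
                          FUN = mean)
  nrep <- stats::aggregate(count ~ animal_id + group + channel, data = counts,
                           FUN = length)
  agg$n_replicates <- nrep$count
  agg <- agg[order(agg$animal_id, agg$channel),
             c("animal_id", "group", "channel", "count", "n_replicates")]
  rownames(agg) <- NULL
  expected <- expand.grid(animal_id = unique(counts$animal_id),
                          channel = channels, stringsAsFactors = FALSE)
  have <- paste(agg$animal_id, agg$channel)
  miss <- expected[!paste(expected$animal_id, expected$channel) %in% have, ,
                   drop = FALSE]
  if (nrow(miss) > 0L) {
    rownames(miss) <- NULL
    attr(agg, "missing") <- miss
    warning(sprintf("%d (animal, channel) pair(s) have no counts; see attr(,'missing')",
                    nrow(miss)))
  }
  agg
}

#' Marker ratios per animal
#'
#' Computes the three standard marker ratios from an aggregated count table:
#' `Iba1/DAPI` (microglia per cell), `ED1/DAPI` (phagocytes per cell) and
#' `Iba1/ED1` (microglia per phagocyte). A zero denominator makes the ratio
#' undefined; such rows are flagged (`defined = FALSE`, value `NA`), never
#' dropped.
#'
#' @param per_animal aggregated table from [aggregate_replicates()] with
#'   channels `DAPI`, `Iba1`, `ED1`.
#' @param ratios named list mapping ratio name to `c(numerator, denominator)`
#'   channel names.
#' @return A data frame: `animal_id`, `group`, `ratio`, `value`, `defined`.
#' @export
compute_ratios <- function(per_animal,
                           ratios = list("Iba1/DAPI" = c("Iba1", "DAPI"),
                                         "ED1/DAPI" = c("ED1", "DAPI"),
                                         "Iba1/ED1" = c("Iba1", "ED1"))) {
  stopifnot(is.data.frame(per_animal))
  wide <- stats::reshape(
    per_animal[, c("animal_id", "group", "channel", "count")],
    idvar = c("animal_id", "group"), timevar = "channel", direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  out <- do.call(rbind, lapply(names(ratios), function(nm) {
    num <- ratios[[nm]][1]; den <- ratios[[nm]][2]
    if (!num %in% names(wide) || !den %in% names(wide))
      stop(sprintf("channel(s) for ratio %s absent from the table", nm))
    denv <- wide[[den]]
    data.frame(animal_id = wide$animal_id, group = wide$group, ratio = nm,
               value = ifelse(denv > 0, wide[[num]] / denv, NA_real_),
               defined = denv > 0, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$animal_id, out$ratio), ]
  rownames(out) <- NULL
  out
}

#' Validate automated counts against blinded manual counts
#'
#' For every matched (image, channel) pair the absolute percent error of the
#' automated count relative to the manual count is
#' `|auto - manual| / manual * 100` — the manual count is the ground-truth
#' denominator. Per staining, the mean and the sample standard deviation
#' (n - 1) of these per-image errors are reported.
#'
#' @param auto data frame of automated counts: `image_id`, `channel`,
#'   `count`.
#' @param manual data frame of manual counts: `image_id`, `channel`,
#'   `manual_count` (or `count`).
#' @return An object of class `validation_report`: list with `per_image`
#'   (the matched pairs and their percent errors) and `per_channel`
#'   (`channel`, `n_images`, `mean_abs_error_pct`, `sd_abs_error_pct`).
#' @export
validate_counts <- function(auto, manual) {
  stopifnot(is.data.frame(auto), is.data.frame(manual))
  if ("count" %in% names(manual) && !"manual_count" %in% names(manual))
    names(manual)[names(manual) == "count"] <- "manual_count"
  key_a <- paste(auto$image_id, auto$channel)
  key_m <- paste(manual$image_id, manual$channel)
  orphans <- c(setdiff(key_a, key_m), setdiff(key_m, key_a))
  if (length(orphans))
    stop("unmatched (image, channel) pair(s): ",
         paste(orphans, collapse = "; "))
  m <- merge(auto[, c("image_id", "channel", "count")],
             manual[, c("image_id", "channel", "manual_count")],
             by = c("image_id", "channel"))
  zero <- m$manual_count == 0
  if (any(zero)) {
    warning(sprintf("%d pair(s) with manual count 0 excluded (percent error undefined)",
                    sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  m$abs_error_pct <- abs(m$count - m$manual_count) / m$manual_count * 100
  per_channel <- do.call(rbind, lapply(split(m, m$channel), function(g)
    data.frame(channel = g$channel[1], n_images = nrow(g),
               mean_abs_error_pct = mean(g$abs_error_pct),
               sd_abs_error_pct = stats::sd(g$abs_error_pct))))
  rownames(per_channel) <- NULL
  structure(list(per_image = m, per_channel = per_channel),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> automated vs manual counts\n")
  for (i in seq_len(nrow(x$per_channel))) {
    r <- x$per_channel[i, ]
    cat(sprintf("  %s: mean absolute error %.1f%% (+/- %.1f%%), n = %d images\n",
                r$channel, r$mean_abs_error_pct, r$sd_abs_error_pct,
                r$n_images))
  }
  invisible(x)
}
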