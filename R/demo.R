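#' Run the full pipeline end to end on a synthetic study
#'
#' Generates a complete synthetic study — a cohort of three groups of eight
#' animals, fluorescence sections in three channels (nuclear DAPI plus the
#' Iba1 and ED1 immunomarkers) with technical replicates, and stained
#' sections at six equally spaced bregma levels per animal — then runs
#' segmentation-based counting, marker ratios, Cavalieri volumetry and the
#' routed group statistics, writing every intermediate and final table to
#' `out_dir`. The whole run is a pure function of `seed`: the same seed
#' produces byte-identical CSV outputs.
#'
#' The synthetic effect sizes default to the null (no group differences);
#' `cavity_effect` and `count_effect` multiply the lesion-cavity area and
#' the immunomarker counts of the treated group, for power experiments.
#'
#' @param seed integer seed controlling the whole run.
#' @param out_dir output directory (created if needed; must be writable).
#' @param n_per_group animals per group (the study design uses 8).
#' @param n_replicates technical replicate sections per animal and channel.
#' @param cavity_effect multiplier on the treated group's cavity areas
#'   (1 = null).
#' @param count_effect multiplier on the treated group's Iba1/ED1 counts
#'   (1 = null).
#' @param fluor_px raster size of the fluorescence phantoms, px.
#' @param hes_px raster size of the stained-section phantoms, px.
#' @param debug also write a three-panel segmentation illustration
#'   (original / watershed / size-filtered) for one example section.
#' @return Invisibly, a list with the tables written: `cohort`,
#'   `section_counts`, `animal_counts`, `ratios`, `volumes`,
#'   `comparisons` and the per-metric `comparison_results`.
#' @export
run_demo <- function(seed = 1L, out_dir, n_per_group = 8L,
                     n_replicates = 2L, cavity_effect = 1,
                     count_effect = 1, fluor_px = 256L, hes_px = 320L,
                     debug = TRUE) {
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop(sprintf("output directory %s is not writable", out_dir))

  levels_mm <- c(1, 0, -1, -2, -3, -4)
  scheme <- sectioning_scheme(levels_mm, sections_per_level = n_replicates)
  # per-level analytic profiles (mm^2): tissue rises then falls along the
  # anteroposterior axis; the cavity peaks around the lesion centre
  tissue_profile <- c(70, 74, 75, 72, 68, 62)
  cavity_profile <- c(1, 5, 8, 8, 5, 2)
  channel_mean <- c(DAPI = 60, Iba1 = 24, ED1 = 12)
  treated_group <- "RvD1"

  with_seed(seed, {
    cohort <- make_cohort(n_operated = 3L * n_per_group + 1L, n_deaths = 1L,
                          n_groups = 3L, levels_mm = levels_mm,
                          sections_per_level = n_replicates,
                          seed = sample.int(2^31 - 1, 1))
    seg_cfg <- seg_config()

    section_counts <- list()
    areas_by_animal <- list()
    example <- NULL
    for (a in seq_len(nrow(cohort$animals))) {
      aid <- cohort$animals$animal_id[a]
      grp <- cohort$animals$group[a]
      animal_scale <- exp(stats::rnorm(1, 0, 0.15))
      for (ch in names(channel_mean)) {
        eff <- if (grp == treated_group && ch != "DAPI") count_effect else 1
        for (rep_i in seq_len(n_replicates)) {
          n_true <- stats::rpois(1, channel_mean[[ch]] * animal_scale * eff)
          ph <- make_fluor_phantom(
            n_cells = n_true, width = fluor_px, height = fluor_px,
            blob_radius_px = 4, min_separation_px = 16,
            seed = sample.int(2^31 - 1, 1), channel = ch)
          res <- count_section(ph$image, seg_cfg)
          section_counts[[length(section_counts) + 1L]] <- data.frame(
            animal_id = aid, group = grp, section_id = sprintf(
              "%s_%s_r%d", aid, ch, rep_i),
            replicate = rep_i, channel = ch, count = res$count,
            truth_count = ph$truth_count, stringsAsFactors = FALSE)
          if (is.null(example) && ch == "DAPI") {
            example <- list(phantom = ph, result = res, cfg = seg_cfg)
          }
        }
      }
      vol_scale <- exp(stats::rnorm(1, 0, 0.05))
      cav_scale <- exp(stats::rnorm(1, 0, 0.20)) *
        (if (grp == treated_group) cavity_effect else 1)
      meas <- list()
      for (l in seq_along(levels_mm)) {
        for (rep_i in seq_len(n_replicates)) {
          t_mm2 <- tissue_profile[l] * vol_scale * exp(stats::rnorm(1, 0, 0.02))
          c_mm2 <- cavity_profile[l] * cav_scale * exp(stats::rnorm(1, 0, 0.05))
          hp <- make_hes_phantom("annulus", tissue_area_mm2 = t_mm2,
                                 cavity_area_mm2 = c_mm2,
                                 pixel_size_um = 40, width = hes_px,
                                 height = hes_px)
          hp$image$meta$level_mm <- levels_mm[l]
          hp$image$meta$replicate <- rep_i
          meas[[length(meas) + 1L]] <- measure_section(hp$image)
        }
      }
      areas <- do.call(rbind, meas)
      vol <- cavalieri_volume(areas, scheme)
      areas_by_animal[[aid]] <- data.frame(
        animal_id = aid, group = grp,
        tissue_volume_mm3 = vol$tissue_volume_mm3,
        cavity_volume_mm3 = vol$cavity_volume_mm3,
        stringsAsFactors = FALSE)
    }

    section_counts <- do.call(rbind, section_counts)
    animal_counts <- aggregate_replicates(
      section_counts[, c("animal_id", "group", "channel", "count")])
    ratios <- compute_ratios(animal_counts)
    volumes <- do.call(rbind, areas_by_animal)
    rownames(volumes) <- NULL

    metrics <- list()
    for (ch in names(channel_mean)) {
      sub <- animal_counts[animal_counts$channel == ch, ]
      metrics[[paste0("count_", ch)]] <- split(sub$count, sub$group)
    }
    for (rn in unique(ratios$ratio)) {
      sub <- ratios[ratios$ratio == rn & ratios$defined, ]
      metrics[[paste0("ratio_", gsub("/", "_", rn))]] <-
        split(sub$value, sub$group)
    }
    metrics$tissue_volume <- split(volumes$tissue_volume_mm3, volumes$group)
    metrics$cavity_volume <- split(volumes$cavity_volume_mm3, volumes$group)

    comparison_results <- lapply(metrics, route_and_compare)
    comparisons <- do.call(rbind, lapply(names(comparison_results), function(m) {
      r <- comparison_results[[m]]
      data.frame(metric = m, route = r$route,
                 statistic = r$omnibus$statistic, p_value = r$omnibus$p.value,
                 significant = r$significant, stringsAsFactors = FALSE)
    }))

    wcsv <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    wcsv(section_counts, "section_counts.csv")
    wcsv(animal_counts, "animal_counts.csv")
    wcsv(ratios, "ratios.csv")
    wcsv(volumes, "volumes.csv")
    wcsv(comparisons, "comparisons.csv")
    config <- list(seed = seed, n_per_group = n_per_group,
                   n_replicates = n_replicates, levels_mm = levels_mm,
                   cavity_effect = cavity_effect, count_effect = count_effect,
                   fluor_px = fluor_px, hes_px = hes_px,
                   tissue_profile = tissue_profile,
                   cavity_profile = cavity_profile,
                   channel_mean = as.list(channel_mean),
                   segmentation = unclass(seg_cfg))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (debug && !is.null(example)) {
      dbg <- file.path(out_dir, "debug")
      dir.create(dbg, showWarnings = FALSE)
      img8 <- convert_bit_depth(example$phantom$image)
      pre <- watershed_segment(img8, example$cfg)
      EBImage::writeImage(as_ebi(img8$pixels / 255),
                          file.path(dbg, "example_original.png"))
      EBImage::writeImage(as_ebi(pre$labels / max(pre$K, 1)),
                          file.path(dbg, "example_watershed.png"))
      EBImage::writeImage(as_ebi(example$result$labels$labels /
                                   max(example$result$count, 1)),
                          file.path(dbg, "example_size_filtered.png"))
    }

    invisible(list(cohort = cohort, section_counts = section_counts,
                   animal_counts = animal_counts, ratios = ratios,
                   volumes = volumes, comparisons = comparisons,
                   comparison_results = comparison_results,
                   out_dir = out_dir))
  })
}
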