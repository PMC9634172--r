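#' Per-compartment phenotype density
#'
#' Counts cells of a phenotype (optionally restricted to a flagged subset,
#' e.g. Ki67+ proliferating cells) in the tumor and stroma compartments and
#' divides by the compartment area.  Excluded cells are never counted.  A
#' compartment with zero area yields a missing (`NA`) density, not zero.
#'
#' @param specimen A gated, compartment-assigned [specimen_table()].
#' @param cmap The [compartment_map()] used for assignment (provides areas);
#'   defaults to the one stored on the specimen by [assign_cells()].
#' @param phenotype Phenotype label to count.
#' @param flag_filter `"none"` (default) or one of `"Ki67+"`, `"PD1+"`,
#'   `"GzmB+"`, `"proliferating"`, `"nonproliferating"`.
#' @return Tibble with one row per compartment (`tumor`, `stroma`):
#'   `count`, `area_mm2`, `density` (cells/mm^2).
#' @export
compute_density <- function(specimen, cmap = NULL, phenotype,
                            flag_filter = "none") {
  cmap <- cmap %||% specimen$compartment_map
  if (is.null(cmap)) abort("no compartment map; run assign_cells() first")
  purrr::map_dfr(c("tumor", "stroma"), function(comp) {
    area <- cmap$areas_mm2[[comp]]
    cnt <- nrow(.phenotype_cells(specimen, phenotype, flag_filter, comp))
    tibble(specimen_id = specimen$specimen_id, phenotype = phenotype,
           flag_filter = flag_filter, compartment = comp,
           count = cnt, area_mm2 = area,
           density = if (area > 0) cnt / area else NA_real_)
  })
}

#' Classify parenchymal inclusion vs exclusion
#'
#' The ratio-based classifier for immune infiltration patterns: a
#' tumor:stroma density ratio above 1.5 defines substantial parenchymal
#' inclusion; a stroma:tumor ratio above 4.5 defines substantial parenchymal
#' exclusion.  Both thresholds are strict.  Zero-denominator conventions:
#' stroma 0 with tumor > 0 is included (ratio +Inf), tumor 0 with stroma > 0
#' is excluded, both zero is undefined; anything crossing neither threshold
#' is intermediate.
#'
#' @param tumor_density,stroma_density Nonnegative densities in cells/mm^2.
#' @param include_ratio,exclude_ratio The two ratio cutoffs.
#' @return Character: `"included"`, `"excluded"`, `"intermediate"` or
#'   `"undefined"`.  Vectorized over the densities.
#' @export
classify_infiltration <- function(tumor_density, stroma_density,
                                  include_ratio = 1.5, exclude_ratio = 4.5) {
  if (any(tumor_density < 0, na.rm = TRUE) ||
      any(stroma_density < 0, na.rm = TRUE)) {
    abort("densities must be nonnegative")
  }
  n <- max(length(tumor_density), length(stroma_density))
  td <- rep_len(tumor_density, n)
  sd_ <- rep_len(stroma_density, n)
  out <- rep("intermediate", n)
  out[td == 0 & sd_ == 0] <- "undefined"
  out[is.na(td) | is.na(sd_)] <- "undefined"
  inc <- td > 0 & (sd_ == 0 | td / sd_ > include_ratio)
  exc <- sd_ > 0 & (td == 0 | sd_ / td > exclude_ratio)
  out[!is.na(td) & !is.na(sd_) & inc] <- "included"
  out[!is.na(td) & !is.na(sd_) & exc] <- "excluded"
  out
}

#' Infiltration call for one specimen/phenotype
#'
#' @inheritParams compute_density
#' @return One-row tibble with densities and the category.
#' @export
infiltration_call <- function(specimen, cmap = NULL, phenotype,
                              flag_filter = "none") {
  d <- compute_density(specimen, cmap, phenotype, flag_filter)
  td <- d$density[d$compartment == "tumor"]
  sd_ <- d$density[d$compartment == "stroma"]
  tibble(specimen_id = specimen$specimen_id, phenotype = phenotype,
         flag_filter = flag_filter,
         tumor_density = td, stroma_density = sd_,
         category = if (is.na(td) || is.na(sd_)) "undefined"
                    else classify_infiltration(td, sd_))
}

#' Local density heat map
#'
#' Divides the field into square tiles of `grid_um` and reports the local
#' density of a phenotype per tile in cells/mm^2.  When a compartment map is
#' supplied, tiles whose raster pixels are mostly excluded are masked
#' (`NA`).  Summing `value * tile_area` over unmasked tiles recovers the
#' total counted cells (exact whenever no mask is applied).
#'
#' @inheritParams compute_density
#' @param grid_um Tile edge in micrometers.
#' @param mask_threshold Excluded-pixel fraction above which a tile is
#'   masked.
#' @return Matrix of tile densities (rows = y, columns = x) with attributes
#'   `grid_um` and `tile_area_mm2`.
#' @export
density_heatmap <- function(specimen, phenotype, grid_um = 100,
                            flag_filter = "none", cmap = NULL,
                            mask_threshold = 0.5) {
  if (grid_um <= 0) abort("grid_um must be positive")
  nx <- max(1L, as.integer(ceiling(specimen$field_width_um / grid_um)))
  ny <- max(1L, as.integer(ceiling(specimen$field_height_um / grid_um)))
  tile_mm2 <- grid_um^2 * 1e-6
  cells <- if ("phenotype" %in% names(specimen$cells)) {
    .phenotype_cells(specimen, phenotype, flag_filter)
  } else abort("phenotypes not assigned; run assign_phenotypes() first")
  counts <- matrix(0, ny, nx)
  if (nrow(cells) > 0) {
    j <- pmin(pmax(ceiling(cells$x_um / grid_um), 1L), nx)
    i <- pmin(pmax(ceiling(cells$y_um / grid_um), 1L), ny)
    for (r in seq_along(i)) counts[i[r], j[r]] <- counts[i[r], j[r]] + 1
  }
  dens <- counts / tile_mm2
  cmap <- cmap %||% specimen$compartment_map
  if (!is.null(cmap)) {
    res <- cmap$resolution_um
    excl <- cmap$grid == .compartments[["excluded"]]
    for (ii in seq_len(ny)) {
      for (jj in seq_len(nx)) {
        i0 <- max(1L, ceiling(((ii - 1) * grid_um) / res + 1e-9))
        i1 <- min(nrow(excl), ceiling(ii * grid_um / res))
        j0 <- max(1L, ceiling(((jj - 1) * grid_um) / res + 1e-9))
        j1 <- min(ncol(excl), ceiling(jj * grid_um / res))
        if (i0 > i1 || j0 > j1) next
        if (mean(excl[i0:i1, j0:j1]) > mask_threshold) dens[ii, jj] <- NA
      }
    }
  }
  attr(dens, "grid_um") <- grid_um
  attr(dens, "tile_area_mm2") <- tile_mm2
  dens
}

#' Write a heat map as CSV grid and rendered image
#'
#' @param hm Matrix from [density_heatmap()].
#' @param path_csv CSV destination (tile densities, row = y).
#' @param path_png Optional PNG destination.
#' @return `path_csv`, invisibly.
#' @export
write_heatmap <- function(hm, path_csv, path_png = NULL) {
  df <- as.data.frame(hm)
  names(df) <- paste0("x", seq_len(ncol(hm)))
  readr::write_csv(df, path_csv, progress = FALSE)
  if (!is.null(path_png)) {
    grDevices::png(path_png, width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    m <- t(hm[rev(seq_len(nrow(hm))), , drop = FALSE])
    graphics::image(m, useRaster = TRUE, axes = FALSE,
                    col = grDevices::hcl.colors(64, "inferno"),
                    main = "cell density (cells/mm^2)")
  }
  invisible(path_csv)
}

#' Cohort density table with per-phenotype summaries
#'
#' Stacks per-specimen densities and appends cohort median, mean and SEM
#' (sd/sqrt(n)) per phenotype/flag/compartment.  With a single specimen the
#' SEM is reported as `NA` by convention.  `n` counts specimens with a
#' defined density.
#'
#' @param specimens List of gated, compartment-assigned specimens.
#' @param phenotypes Phenotype labels to tabulate.
#' @param flag_filters Flag filters (default just `"none"`).
#' @return A [result_table()] (`analysis = "density"`) with per-specimen
#'   rows (`metric = "density"`) and cohort rows (`metric` in
#'   `median`/`mean`/`sem`/`n`).
#' @export
cohort_density_table <- function(specimens, phenotypes,
                                 flag_filters = "none") {
  per <- purrr::map_dfr(specimens, function(sp) {
    purrr::map_dfr(phenotypes, function(ph) {
      purrr::map_dfr(flag_filters, function(fl) {
        compute_density(sp, phenotype = ph, flag_filter = fl)
      })
    })
  })
  spec_rows <- per |>
    mutate(metric = "density", value = .data$density,
           units = "cells/mm^2") |>
    select(all_of(c("specimen_id", "phenotype", "flag_filter", "compartment",
                    "metric", "value", "units")))
  cohort <- per |>
    filter(!is.na(.data$density)) |>
    group_by(.data$phenotype, .data$flag_filter, .data$compartment) |>
    summarise(median = median(.data$density), mean = mean(.data$density),
              sem = if (n() > 1) sd(.data$density) / sqrt(n()) else NA_real_,
              n = as.numeric(n()), .groups = "drop") |>
    tidyr::pivot_longer(all_of(c("median", "mean", "sem", "n")),
                        names_to = "metric", values_to = "value") |>
    mutate(specimen_id = "cohort",
           units = ifelse(.data$metric == "n", "specimens", "cells/mm^2"))
  result_table("density", bind_rows(spec_rows, cohort))
}
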