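#' @section Spatial statistics:
#' Distances are Euclidean between nuclear centroids, in micrometers.  No
#' edge correction is applied for cells near the field border; this mirrors
#' typical slide-analysis platform behavior and is documented as a
#' limitation.
#' @name spatial
NULL

# Nearest-target distance and index for every source point, chunked so the
# distance matrix never exceeds ~1e7 entries.  Ties in distance are broken
# toward the target with the lexicographically lowest cell_id (targets are
# scanned in cell_id order).  `self` marks source/target as the same
# population: a cell's own record is removed from its candidate targets.
.nearest_target <- function(sx, sy, tx, ty, target_ids, self = FALSE,
                            source_pos = NULL) {
  ns <- length(sx); nt <- length(tx)
  ord <- order(target_ids, method = "radix")
  tx <- tx[ord]; ty <- ty[ord]
  if (self) {
    # position of each source within the reordered target vector
    self_pos <- match(source_pos, ord)
  }
  dist <- rep(Inf, ns)
  idx <- rep(NA_integer_, ns)
  chunk <- max(1L, as.integer(1e7 / max(1L, nt)))
  for (s0 in seq(1L, ns, by = chunk)) {
    s1 <- min(ns, s0 + chunk - 1L)
    d2 <- outer(sx[s0:s1], tx, `-`)^2 + outer(sy[s0:s1], ty, `-`)^2
    if (self) {
      rows <- s0:s1
      d2[cbind(seq_along(rows), self_pos[rows])] <- Inf
    }
    best <- max.col(-d2, ties.method = "first")
    dist[s0:s1] <- sqrt(d2[cbind(seq_len(s1 - s0 + 1L), best)])
    idx[s0:s1] <- ord[best]
  }
  list(dist = dist, index = idx)
}

# Same-population heuristic: identical id sets with identical coordinates.
.same_population <- function(s, t_) {
  if (length(s$id) != length(t_$id) || !setequal(s$id, t_$id)) return(FALSE)
  m <- match(s$id, t_$id)
  all(s$x == t_$x[m]) && all(s$y == t_$y[m])
}

# Extract coordinates/ids from a specimen+phenotype or from a raw tibble.
.spatial_points <- function(x, phenotype = NULL, flag_filter = NULL) {
  cells <- if (inherits(x, "specimen_table")) {
    if (is.null(phenotype)) x$cells[x$cells$compartment != "excluded", ]
    else .phenotype_cells(x, phenotype, flag_filter)
  } else as_tibble(x)
  list(x = cells$x_um, y = cells$y_um, id = as.character(cells$cell_id))
}

#' Nearest-neighbor statistics between two cell populations
#'
#' For every source cell, the distance to the nearest target cell.  Reports
#' the mean and sd of these distances, and the number of unique neighbors:
#' distinct target cells that are the nearest neighbor of at least one
#' source cell.  When source and target are the same population each cell's
#' own record is excluded from its candidates.  With no target cells the
#' result is flagged undefined (`NA` statistics), never zero.
#'
#' @param source,target Cell tibbles (columns `cell_id`, `x_um`, `y_um`),
#'   e.g. from [phenotype_cells()] selections; excluded cells should already
#'   be removed (automatic when selecting from a specimen).
#' @param same_population Set `TRUE` when source and target are the same
#'   cells (self-exclusion); auto-detected when the id sets are identical.
#' @return One-row tibble: `n_source`, `n_target`, `mean_nn_distance_um`,
#'   `sd_nn_distance_um`, `unique_neighbors`, `undefined`.
#' @export
nearest_neighbor <- function(source, target, same_population = NULL) {
  s <- .spatial_points(source)
  t_ <- .spatial_points(target)
  if (is.null(same_population)) {
    same_population <- .same_population(s, t_)
  }
  undefined <- length(s$id) == 0 || length(t_$id) == 0 ||
    (same_population && length(t_$id) < 2)
  if (undefined) {
    return(tibble(n_source = length(s$id), n_target = length(t_$id),
                  mean_nn_distance_um = NA_real_,
                  sd_nn_distance_um = NA_real_,
                  unique_neighbors = NA_integer_, undefined = TRUE))
  }
  nn <- .nearest_target(s$x, s$y, t_$x, t_$y, t_$id, self = same_population,
                        source_pos = if (same_population)
                          match(s$id, t_$id) else NULL)
  tibble(n_source = length(s$id), n_target = length(t_$id),
         mean_nn_distance_um = mean(nn$dist),
         sd_nn_distance_um = if (length(nn$dist) > 1) sd(nn$dist) else NA_real_,
         unique_neighbors = length(unique(nn$index)), undefined = FALSE)
}

#' Proximity (radius and band) statistics between two populations
#'
#' Per source cell, the nearest-target distance `d`.  `fraction_within` is
#' the proportion of source cells with at least one target within
#' `radius_um`; the band histogram counts source cells with `d` in
#' half-open bands `[k*w, (k+1)*w)` of width `w` up to the radius.  The
#' upper boundary is closed: `d` exactly equal to the radius counts as
#' within, landing in the final band.
#'
#' @inheritParams nearest_neighbor
#' @param radius_um Search radius (> 0).
#' @param band_width_um Band width; must divide the radius evenly.
#' @return One-row tibble with `fraction_within`, `n_within`, `n_source`,
#'   `n_target`, a `bands` list-column (tibble `band_start`, `band_end`,
#'   `count`), `mean_targets_within` (secondary statistic: mean number of
#'   target cells within the radius per source cell), and `undefined`.
#' @export
proximity <- function(source, target, radius_um, band_width_um = radius_um,
                      same_population = NULL) {
  if (radius_um <= 0) abort("radius_um must be positive")
  n_bands <- radius_um / band_width_um
  if (abs(n_bands - round(n_bands)) > 1e-9) {
    abort("band_width_um must divide radius_um evenly")
  }
  n_bands <- as.integer(round(n_bands))
  bands0 <- tibble(band_start = (seq_len(n_bands) - 1) * band_width_um,
                   band_end = seq_len(n_bands) * band_width_um,
                   count = 0L)
  s <- .spatial_points(source)
  t_ <- .spatial_points(target)
  if (is.null(same_population)) {
    same_population <- .same_population(s, t_)
  }
  if (length(s$id) == 0 || length(t_$id) == 0 ||
      (same_population && length(t_$id) < 2)) {
    return(tibble(n_source = length(s$id), n_target = length(t_$id),
                  fraction_within = NA_real_, n_within = NA_integer_,
                  mean_targets_within = NA_real_,
                  bands = list(bands0), undefined = TRUE))
  }
  self_pos <- if (same_population) match(s$id, t_$id) else NULL
  nn <- .nearest_target(s$x, s$y, t_$x, t_$y, t_$id, self = same_population,
                        source_pos = self_pos)
  d <- nn$dist
  within <- d <= radius_um
  k <- pmin(floor(d / band_width_um), n_bands - 1L)  # closed upper bound
  counts <- tabulate(k[within] + 1L, nbins = n_bands)
  bands <- bands0
  bands$count <- counts

  # secondary statistic: mean count of targets within the radius
  r2 <- radius_um^2
  ns <- length(s$x); nt <- length(t_$x)
  cnt_within <- numeric(ns)
  chunk <- max(1L, as.integer(1e7 / max(1L, nt)))
  for (s0 in seq(1L, ns, by = chunk)) {
    s1 <- min(ns, s0 + chunk - 1L)
    d2 <- outer(s$x[s0:s1], t_$x, `-`)^2 + outer(s$y[s0:s1], t_$y, `-`)^2
    if (same_population) {
      d2[cbind(seq_len(s1 - s0 + 1L), self_pos[s0:s1])] <- Inf
    }
    cnt_within[s0:s1] <- rowSums(d2 <= r2)
  }

  tibble(n_source = ns, n_target = nt,
         fraction_within = mean(within), n_within = sum(within),
         mean_targets_within = mean(cnt_within),
         bands = list(bands), undefined = FALSE)
}

#' Select the cells of one phenotype for spatial analysis
#'
#' @param specimen A gated [specimen_table()].
#' @param phenotype Label to select.
#' @param flag_filter Optional flag restriction (see [compute_density()]).
#' @return Tibble of cells (excluded-compartment cells removed).
#' @export
phenotype_cells <- function(specimen, phenotype, flag_filter = "none") {
  .phenotype_cells(specimen, phenotype, flag_filter)
}

#' Treg proximity contrast to proliferating vs nonproliferating CD8 T cells
#'
#' For each specimen: the percentage of Tregs with at least one
#' nonproliferating (Ki67-) CD8 T cell within `radius_um`, and the same for
#' proliferating (Ki67+) CD8 T cells.  The cohort comparison is a paired
#' Wilcoxon signed-rank test on the two percentages.  Specimens lacking
#' Tregs or lacking one of the CD8 classes are dropped from the pairing and
#' counted.
#'
#' @param specimens List of gated specimens (T-cell panel).
#' @param radius_um Proximity radius, default 20 um.
#' @return List with `pairs` (tibble: specimen_id, pct_near_nonproliferating,
#'   pct_near_proliferating), `n_dropped`, and `test` (a
#'   [wilcoxon_signed_rank()] result, or `NULL` with fewer than 2 usable
#'   pairs).
#' @export
treg_cd8_contrast <- function(specimens, radius_um = 20) {
  rows <- purrr::map_dfr(specimens, function(sp) {
    tregs <- phenotype_cells(sp, "treg")
    cd8_prolif <- phenotype_cells(sp, "cd8_cytotoxic", "proliferating")
    cd8_non <- phenotype_cells(sp, "cd8_cytotoxic", "nonproliferating")
    if (nrow(tregs) == 0 || nrow(cd8_prolif) == 0 || nrow(cd8_non) == 0) {
      return(tibble(specimen_id = sp$specimen_id, usable = FALSE,
                    pct_near_nonproliferating = NA_real_,
                    pct_near_proliferating = NA_real_))
    }
    p_non <- proximity(tregs, cd8_non, radius_um)
    p_pro <- proximity(tregs, cd8_prolif, radius_um)
    tibble(specimen_id = sp$specimen_id, usable = TRUE,
           pct_near_nonproliferating = 100 * p_non$fraction_within,
           pct_near_proliferating = 100 * p_pro$fraction_within)
  })
  usable <- rows[rows$usable, ]
  test <- NULL
  if (nrow(usable) >= 2) {
    test <- wilcoxon_signed_rank(usable$pct_near_nonproliferating,
                                 usable$pct_near_proliferating,
                                 comparison = "treg near nonproliferating vs proliferating CD8")
  }
  list(pairs = usable[, c("specimen_id", "pct_near_nonproliferating",
                          "pct_near_proliferating")],
       n_dropped = sum(!rows$usable), test = test)
}

#' Cohort spatial summary over phenotype pairs
#'
#' Per specimen and (source, target) phenotype pair: the mean
#' nearest-neighbor distance and the percentage of source cells within
#' 100 um of a target cell (target typically `tumor`), plus cohort
#' mean +/- SD rows.
#'
#' @param specimens List of gated specimens.
#' @param pairs Data frame with columns `source` and `target` (phenotype
#'   labels).
#' @param radius_um Proximity radius for the percentage, default 100 um.
#' @return A [result_table()] (`analysis = "spatial"`).
#' @export
spatial_summary <- function(specimens, pairs, radius_um = 100) {
  per <- purrr::map_dfr(specimens, function(sp) {
    purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
      src <- phenotype_cells(sp, pairs$source[k])
      tgt <- phenotype_cells(sp, pairs$target[k])
      nn <- nearest_neighbor(src, tgt,
                             same_population = identical(pairs$source[k],
                                                         pairs$target[k]))
      pr <- proximity(src, tgt, radius_um,
                      same_population = identical(pairs$source[k],
                                                  pairs$target[k]))
      tibble(specimen_id = sp$specimen_id, source = pairs$source[k],
             target = pairs$target[k],
             mean_nn_distance_um = nn$mean_nn_distance_um,
             pct_within = 100 * pr$fraction_within)
    })
  })
  spec_rows <- per |>
    tidyr::pivot_longer(all_of(c("mean_nn_distance_um", "pct_within")),
                        names_to = "metric", values_to = "value") |>
    mutate(phenotype = paste(.data$source, "->", .data$target),
           units = ifelse(.data$metric == "pct_within", "%", "um")) |>
    select(all_of(c("specimen_id", "phenotype", "metric", "value", "units")))
  cohort <- per |>
    group_by(.data$source, .data$target) |>
    summarise(
      mean_nn_distance_um_mean = mean(.data$mean_nn_distance_um, na.rm = TRUE),
      mean_nn_distance_um_sd = sd(.data$mean_nn_distance_um, na.rm = TRUE),
      pct_within_mean = mean(.data$pct_within, na.rm = TRUE),
      pct_within_sd = sd(.data$pct_within, na.rm = TRUE),
      .groups = "drop") |>
    tidyr::pivot_longer(-all_of(c("source", "target")),
                        names_to = "metric", values_to = "value") |>
    mutate(specimen_id = "cohort",
           phenotype = paste(.data$source, "->", .data$target),
           units = ifelse(grepl("^pct", .data$metric), "%", "um")) |>
    select(all_of(c("specimen_id", "phenotype", "metric", "value", "units")))
  result_table("spatial", bind_rows(spec_rows, cohort))
}
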