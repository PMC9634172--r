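#' Compartment map
#'
#' A label raster over the specimen field at `resolution_um` per pixel.
#' Pixel (i, j) covers `[(j-1), j] x [(i-1), i] * resolution_um` and is
#' assigned by its center point.  Labels: 0 background, 1 tumor, 2 stroma,
#' 3 excluded.  Areas are exact pixel counts times the pixel area.
#'
#' @param specimen_id Specimen the map belongs to.
#' @param grid Integer matrix (rows = y, columns = x) of labels.
#' @param resolution_um Pixel edge length in micrometers.
#' @param provenance `"annotation"` or `"ck_density"`.
#' @return A `compartment_map` with an `areas_mm2` element.
#' @export
compartment_map <- function(specimen_id, grid, resolution_um,
                            provenance = c("annotation", "ck_density")) {
  provenance <- match.arg(provenance)
  storage.mode(grid) <- "integer"
  px_mm2 <- (resolution_um^2) * 1e-6
  areas <- vapply(.compartments, function(code) sum(grid == code) * px_mm2,
                  numeric(1))
  structure(list(specimen_id = specimen_id, grid = grid,
                 resolution_um = resolution_um,
                 areas_mm2 = areas, provenance = provenance),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  cat(sprintf("<compartment_map> %s: %d x %d px @ %g um (%s)\n",
              x$specimen_id, nrow(x$grid), ncol(x$grid), x$resolution_um,
              x$provenance))
  a <- x$areas_mm2
  cat(sprintf("  areas (mm^2): tumor %.4f, stroma %.4f, excluded %.4f\n",
              a[["tumor"]], a[["stroma"]], a[["excluded"]]))
  invisible(x)
}

# Raster dimensions covering the field.
.raster_dims <- function(specimen, resolution_um) {
  list(nx = max(1L, as.integer(ceiling(specimen$field_width_um / resolution_um))),
       ny = max(1L, as.integer(ceiling(specimen$field_height_um / resolution_um))))
}

# Logical matrix: pixel centers inside any of the polygons.
.rasterize_polys <- function(polys, nx, ny, resolution_um) {
  mask <- matrix(FALSE, ny, nx)
  if (length(polys) == 0) return(mask)
  cx <- (seq_len(nx) - 0.5) * resolution_um
  cy <- (seq_len(ny) - 0.5) * resolution_um
  for (p in polys) {
    jr <- which(cx >= min(p[, 1]) & cx <= max(p[, 1]))
    ir <- which(cy >= min(p[, 2]) & cy <= max(p[, 2]))
    if (length(jr) == 0 || length(ir) == 0) next
    pts <- cbind(rep(cx[jr], each = length(ir)), rep(cy[ir], length(jr)))
    bnd <- rbind(p, p[1, , drop = FALSE])
    inside <- mgcv::in.out(bnd, pts)
    mask[ir, jr] <- mask[ir, jr] | matrix(inside, length(ir), length(jr))
  }
  mask
}

#' Build a compartment map from manual annotations
#'
#' Rasterizes the annotation polygons with precedence
#' excluded > tumor > stroma > background; each pixel is classified by its
#' center point.
#'
#' @param specimen A [specimen_table()] (defines the field extent).
#' @param ann An [annotation_set()].
#' @param resolution_um Raster resolution; the 5 um default is well below
#'   cell spacing.
#' @return A [compartment_map()].
#' @export
compartments_from_annotations <- function(specimen, ann, resolution_um = 5) {
  if (resolution_um <= 0) abort("resolution_um must be positive")
  d <- .raster_dims(specimen, resolution_um)
  grid <- matrix(.compartments[["background"]], d$ny, d$nx)
  grid[.rasterize_polys(ann$stroma, d$nx, d$ny, resolution_um)] <-
    .compartments[["stroma"]]
  grid[.rasterize_polys(ann$tumor, d$nx, d$ny, resolution_um)] <-
    .compartments[["tumor"]]
  grid[.rasterize_polys(ann$exclude, d$nx, d$ny, resolution_um)] <-
    .compartments[["excluded"]]
  cmap <- compartment_map(specimen$specimen_id, grid, resolution_um,
                          "annotation")
  if (cmap$areas_mm2[["tumor"]] + cmap$areas_mm2[["stroma"]] <= 0) {
    abort("annotations contain no usable tissue (zero tumor + stroma area)")
  }
  cmap
}

# Separable Gaussian blur of a matrix, kernel sd in pixels, truncated at 4 sd.
.gaussian_blur <- function(mat, sd_px) {
  half <- max(1L, as.integer(ceiling(4 * sd_px)))
  k <- dnorm(seq(-half, half), sd = sd_px)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    # pad with zeros, convolve columns via filter matrix
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-half, half), `+`)
    valid <- idx >= 1 & idx <= n
    idx[!valid] <- 1L
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) {
      rows <- idx[, t]
      vals <- m[rows, , drop = FALSE]
      vals[!valid[, t], ] <- 0
      out <- out + k[t] * vals
    }
    out
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

#' Build a compartment map from cytokeratin-positive cell density
#'
#' A transparent stand-in for slide-level tissue classification: the density
#' of CK+ (tumor-labeled) cells is kernel-smoothed on the raster; pixels at
#' or above the cutoff become tumor, remaining pixels within the tissue hull
#' become stroma.  The hull is the dilation of the all-cells point set, so
#' empty glass stays background.
#'
#' @param specimen A gated [specimen_table()] (tumor labels available).
#' @param bandwidth_um Gaussian kernel sd; default 50 um.
#' @param density_cutoff Tumor cutoff in cells/mm^2; `NULL` (default) picks
#'   the Otsu split of the smoothed density histogram over the tissue hull.
#' @param resolution_um Raster resolution.
#' @param hull_radius_um Dilation radius defining the tissue hull; default
#'   `2 * bandwidth_um`.
#' @return A [compartment_map()] with provenance `"ck_density"`.
#' @export
compartments_from_ck <- function(specimen, bandwidth_um = 50,
                                 density_cutoff = NULL, resolution_um = 5,
                                 hull_radius_um = 2 * bandwidth_um) {
  if (bandwidth_um <= 0 || resolution_um <= 0) {
    abort("bandwidth_um and resolution_um must be positive")
  }
  cells <- specimen$cells
  if (nrow(cells) == 0) abort("specimen has no cells (no tissue)")
  if (!"phenotype" %in% names(cells)) {
    abort("phenotypes not assigned; run assign_phenotypes() first")
  }
  d <- .raster_dims(specimen, resolution_um)
  px_of <- function(x, y) {
    j <- pmin(pmax(ceiling(x / resolution_um), 1L), d$nx)
    i <- pmin(pmax(ceiling(y / resolution_um), 1L), d$ny)
    cbind(i, j)
  }

  # tissue hull: pixels within hull_radius_um of any cell
  occ <- matrix(0, d$ny, d$nx)
  occ[px_of(cells$x_um, cells$y_um)] <- 1
  dist_px <- EBImage::distmap(1 - occ)
  hull <- dist_px * resolution_um <= hull_radius_um

  ck <- cells[cells$phenotype == "tumor", ]
  if (nrow(ck) == 0) {
    warn("no CK+ cells; returning an all-stroma map")
    grid <- matrix(.compartments[["background"]], d$ny, d$nx)
    grid[hull] <- .compartments[["stroma"]]
    return(compartment_map(specimen$specimen_id, grid, resolution_um,
                           "ck_density"))
  }
  counts <- matrix(0, d$ny, d$nx)
  pos <- px_of(ck$x_um, ck$y_um)
  for (r in seq_len(nrow(pos))) {
    counts[pos[r, 1], pos[r, 2]] <- counts[pos[r, 1], pos[r, 2]] + 1
  }
  dens <- .gaussian_blur(counts, bandwidth_um / resolution_um) /
    (resolution_um^2 * 1e-6)  # cells / mm^2

  if (is.null(density_cutoff)) {
    v <- dens[hull]
    rng <- range(v)
    density_cutoff <- if (diff(rng) <= 0) rng[1] else {
      EBImage::otsu(matrix(v, ncol = 1), range = rng, levels = 256)
    }
  }
  grid <- matrix(.compartments[["background"]], d$ny, d$nx)
  grid[hull & dens < density_cutoff] <- .compartments[["stroma"]]
  grid[hull & dens >= density_cutoff] <- .compartments[["tumor"]]
  cmap <- compartment_map(specimen$specimen_id, grid, resolution_um,
                          "ck_density")
  cmap$density_cutoff <- density_cutoff
  cmap
}

#' Assign each cell to its compartment
#'
#' A cell belongs to the compartment of the raster pixel containing its
#' nuclear centroid.  Cells in excluded regions are retained in the table
#' but carry `compartment = "excluded"` and are omitted from every density
#' and spatial analysis downstream.
#'
#' @param specimen A [specimen_table()].
#' @param cmap A [compartment_map()] covering the field.
#' @return The specimen with the `compartment` column filled.
#' @export
assign_cells <- function(specimen, cmap) {
  cells <- specimen$cells
  if (nrow(cells) == 0) return(specimen)
  res <- cmap$resolution_um
  j <- pmin(pmax(ceiling(cells$x_um / res), 1L), ncol(cmap$grid))
  i <- pmin(pmax(ceiling(cells$y_um / res), 1L), nrow(cmap$grid))
  cells$compartment <- .compartment_name(cmap$grid[cbind(i, j)])
  cells$compartment[cells$compartment == "background"] <- "unassigned"
  specimen$cells <- cells
  specimen$compartment_map <- cmap
  specimen
}
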