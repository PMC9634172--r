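#' Construct a specimen table
#'
#' A specimen is the unit of analysis: one whole slide or one TMA core,
#' holding every segmented cell with its centroid, nuclear area and marker
#' mean intensities.  Coordinates are in micrometers with the image
#' convention (origin top-left, y increasing downward); this convention is
#' inherited by every other module.
#'
#' @param cells Tibble/data frame with one row per cell.  Required columns:
#'   `cell_id`, `x_um`, `y_um`, `nuclear_area_um2`, plus one numeric column
#'   per marker named exactly as the marker.  Optional columns added by later
#'   stages: `pos_<marker>` logicals, `compartment`, `phenotype`, and flag
#'   columns.
#' @param specimen_id Non-empty identifier.
#' @param field_width_um,field_height_um Field extent in micrometers.  When
#'   `NULL`, taken as the ceiling of the maximum coordinate.
#' @param markers Character vector of marker names carried by this specimen.
#'   Defaults to every numeric column that is not one of the reserved ones.
#' @param source `"whole-slide"` or `"TMA-core"`.
#' @param panel_name Optional panel label (`"myeloid"`, `"tcell"`, `"nk"`).
#'
#' @return An object of class `specimen_table`.
#' @export
specimen_table <- function(cells, specimen_id,
                           field_width_um = NULL, field_height_um = NULL,
                           markers = NULL,
                           source = c("whole-slide", "TMA-core"),
                           panel_name = NULL) {
  source <- match.arg(source)
  cells <- as_tibble(cells)
  if (!nzchar(specimen_id)) abort("`specimen_id` must be non-empty")
  required <- c("cell_id", "x_um", "y_um", "nuclear_area_um2")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    abort(sprintf("duplicate cell_id in specimen '%s'", specimen_id))
  }
  if (nrow(cells) > 0 &&
      (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))) {
    abort("cell coordinates must be finite")
  }
  if (nrow(cells) > 0 && any(cells$nuclear_area_um2 < 0, na.rm = TRUE)) {
    abort("nuclear_area_um2 must be nonnegative")
  }
  if (is.null(markers)) {
    reserved <- c(required, "compartment", "phenotype",
                  grep("^(pos_|flag_)", names(cells), value = TRUE))
    markers <- names(cells)[vapply(cells, is.numeric, logical(1))]
    markers <- setdiff(markers, reserved)
  }
  bad <- markers[!markers %in% names(cells)]
  if (length(bad) > 0) {
    abort(paste0("marker column(s) absent from cell table: ",
                 paste(bad, collapse = ", ")))
  }
  for (m in markers) {
    if (nrow(cells) > 0 && any(cells[[m]] < 0, na.rm = TRUE)) {
      abort(sprintf("marker '%s' has negative intensities", m))
    }
  }
  if (is.null(field_width_um)) {
    field_width_um <- if (nrow(cells)) ceiling(max(cells$x_um)) else 1
  }
  if (is.null(field_height_um)) {
    field_height_um <- if (nrow(cells)) ceiling(max(cells$y_um)) else 1
  }
  if (field_width_um <= 0 || field_height_um <= 0) {
    abort("field dimensions must be positive")
  }
  if (nrow(cells) > 0 &&
      (any(cells$x_um < 0 | cells$x_um > field_width_um) ||
       any(cells$y_um < 0 | cells$y_um > field_height_um))) {
    abort("all cells must lie within [0, width] x [0, height]")
  }
  if (!"compartment" %in% names(cells)) cells$compartment <- "unassigned"
  structure(
    list(specimen_id = as.character(specimen_id),
         cells = cells,
         markers = markers,
         field_width_um = field_width_um,
         field_height_um = field_height_um,
         source = source,
         panel_name = panel_name),
    class = "specimen_table")
}

#' @export
print.specimen_table <- function(x, ...) {
  cat(sprintf("<specimen_table> %s: %d cells, %g x %g um field (%s)\n",
              x$specimen_id, nrow(x$cells),
              x$field_width_um, x$field_height_um, x$source))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  if ("phenotype" %in% names(x$cells)) {
    tab <- table(x$cells$phenotype)
    cat("  phenotypes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells in a specimen
#' @param specimen A `specimen_table`.
#' @return Integer cell count.
#' @export
n_cells <- function(specimen) nrow(specimen$cells)

# Internal: cells of a phenotype, optionally restricted by flag and
# compartment; excluded cells are never returned.
.phenotype_cells <- function(specimen, phenotype, flag_filter = NULL,
                             compartment = NULL) {
  cells <- specimen$cells
  if (!"phenotype" %in% names(cells)) {
    abort("phenotypes not assigned yet; run assign_phenotypes() first")
  }
  keep <- cells$phenotype == phenotype & cells$compartment != "excluded"
  if (!is.null(flag_filter) && !identical(flag_filter, "none")) {
    col <- switch(flag_filter,
      "Ki67+" = "flag_ki67", "proliferating" = "flag_ki67",
      "PD1+" = "flag_pd1", "GzmB+" = "flag_gzmb",
      "nonproliferating" = "flag_ki67",
      abort(sprintf("unknown flag filter '%s'", flag_filter)))
    if (!col %in% names(cells)) {
      abort(sprintf("flag column '%s' absent; run assign_phenotypes()", col))
    }
    keep <- keep & if (identical(flag_filter, "nonproliferating"))
      !cells[[col]] else cells[[col]]
  }
  if (!is.null(compartment)) keep <- keep & cells$compartment == compartment
  cells[which(keep), , drop = FALSE]
}
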