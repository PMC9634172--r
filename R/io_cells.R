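#' Read a segmented-cell table from CSV
#'
#' Reads an object-level export (one row per segmented cell) into one or more
#' [specimen_table()]s.  Column names vary between image-analysis platform
#' versions, so the mapping from file columns to the data model is supplied
#' externally as `column_map` rather than hard-coded.
#'
#' @param path CSV file (comma-separated, UTF-8, header required).
#' @param column_map A list describing the file schema:
#'   \describe{
#'     \item{x, y}{column names of the centroid coordinates (required).}
#'     \item{area}{column of nuclear area; optional, defaults to 0 when absent.}
#'     \item{cell_id}{column of cell identifiers; optional, defaults to row
#'       number.}
#'     \item{specimen}{column identifying the specimen; when present the file
#'       is split into one specimen per distinct value.}
#'     \item{intensities}{named character vector `marker -> column`
#'       (required, at least one marker).}
#'     \item{units}{`"um"` (default) or `"px"`.}
#'     \item{um_per_px}{scale factor, required when `units = "px"`; applied
#'       to coordinates, and squared for areas.}
#'   }
#' @param field_width_um,field_height_um Optional field extent; defaults to
#'   the ceiling of the maximum coordinate per specimen.
#' @param on_bad_row `"error"` (default) stops at the first non-numeric
#'   coordinate, naming the row; `"drop"` removes offending rows and records
#'   the count in the `rejected_rows` attribute (never silently).
#' @param source,panel_name Passed to [specimen_table()].
#'
#' @return A single `specimen_table`, or a named list of them when
#'   `column_map$specimen` is set.  The returned object(s) carry a
#'   `rejected_rows` attribute with the number of dropped rows.
#' @export
read_cell_table <- function(path, column_map,
                            field_width_um = NULL, field_height_um = NULL,
                            on_bad_row = c("error", "drop"),
                            source = "whole-slide", panel_name = NULL) {
  on_bad_row <- match.arg(on_bad_row)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("empty cell table: %s", path))
  for (field in c("x", "y")) {
    if (is.null(column_map[[field]])) {
      abort(sprintf("column_map must name the '%s' column", field))
    }
  }
  if (is.null(column_map$intensities) || length(column_map$intensities) == 0) {
    abort("column_map$intensities must map at least one marker to a column")
  }
  column_map$intensities <- unlist(column_map$intensities)  # allow yaml lists
  mapped <- c(column_map$x, column_map$y, column_map$area,
              column_map$cell_id, column_map$specimen,
              unname(column_map$intensities))
  missing <- setdiff(mapped, names(raw))
  if (length(missing) > 0) {
    abort(paste0("mapped column(s) absent from file: ",
                 paste(missing, collapse = ", ")))
  }

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  x <- num(column_map$x)
  y <- num(column_map$y)
  bad <- which(is.na(x) | is.na(y))
  rejected <- 0L
  if (length(bad) > 0) {
    if (on_bad_row == "error") {
      abort(sprintf("non-numeric coordinate at row %d of %s", bad[1], path))
    }
    rejected <- length(bad)
    raw <- raw[-bad, , drop = FALSE]
    x <- x[-bad]; y <- y[-bad]
  }

  scale <- 1
  units <- column_map$units %||% "um"
  if (identical(units, "px")) {
    if (is.null(column_map$um_per_px)) {
      abort("column_map$um_per_px required when units = 'px'")
    }
    scale <- column_map$um_per_px
  } else if (!identical(units, "um")) {
    abort(sprintf("unknown units '%s' (use 'um' or 'px')", units))
  }

  area <- if (!is.null(column_map$area)) {
    a <- num(column_map$area)
    if (anyNA(a)) abort("non-numeric nuclear area value")
    a * scale^2
  } else rep(0, nrow(raw))
  cell_id <- if (!is.null(column_map$cell_id)) {
    as.character(raw[[column_map$cell_id]])
  } else as.character(seq_len(nrow(raw)))

  cells <- tibble(cell_id = cell_id, x_um = x * scale, y_um = y * scale,
                  nuclear_area_um2 = area)
  markers <- names(column_map$intensities)
  for (m in markers) {
    v <- num(column_map$intensities[[m]])
    if (anyNA(v)) abort(sprintf("non-numeric intensity in marker column '%s'",
                                column_map$intensities[[m]]))
    cells[[m]] <- v
  }

  build <- function(cells, id) {
    st <- specimen_table(cells, id,
                         field_width_um = field_width_um,
                         field_height_um = field_height_um,
                         markers = markers, source = source,
                         panel_name = panel_name)
    attr(st, "rejected_rows") <- rejected
    st
  }
  if (!is.null(column_map$specimen)) {
    ids <- as.character(raw[[column_map$specimen]])
    out <- lapply(split(seq_len(nrow(cells)), ids), function(idx) {
      build(cells[idx, , drop = FALSE], ids[idx[1]])
    })
    out[order(names(out))]
  } else {
    build(cells, column_map$specimen_id %||% "specimen_1")
  }
}

#' Write a specimen's cell table to CSV
#'
#' Inverse of [read_cell_table()]: emits `specimen_id`, `cell_id`, `x_um`,
#' `y_um`, `nuclear_area_um2` and one column per marker, always in
#' micrometers.  Numeric fields are written at full precision so a read/write
#' round trip reproduces coordinates and intensities.
#'
#' @param specimen A [specimen_table()].
#' @param path Output CSV path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_cells <- function(specimen, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(sprintf("file exists (use overwrite = TRUE): %s", path))
  }
  out <- specimen$cells[, c("cell_id", "x_um", "y_um", "nuclear_area_um2",
                            specimen$markers)]
  out <- tibble(specimen_id = specimen$specimen_id, out)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Column map matching [write_cells()] output
#'
#' Convenience for round trips and for the synthetic presets, whose CSVs are
#' written by [write_cells()].
#'
#' @param markers Marker names present in the file.
#' @return A `column_map` list for [read_cell_table()].
#' @export
default_column_map <- function(markers) {
  list(specimen = "specimen_id", cell_id = "cell_id", x = "x_um", y = "y_um",
       area = "nuclear_area_um2",
       intensities = setNames(markers, markers), units = "um")
}
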