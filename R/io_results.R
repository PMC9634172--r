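#' Long-format result table
#'
#' Every analysis emits results in a single long schema so cohort tables can
#' be concatenated and written uniformly.
#'
#' @param analysis Analysis name (becomes the output file name).
#' @param rows Tibble with any of the columns `specimen_id`, `phenotype`,
#'   `compartment`, `metric`, `value`, `units`; missing ones are filled with
#'   `NA`.
#' @return A `result_table` (tibble subclass with an `analysis` attribute).
#' @export
result_table <- function(analysis, rows) {
  cols <- c("specimen_id", "phenotype", "compartment", "metric", "value",
            "units")
  rows <- as_tibble(rows)
  for (col in setdiff(cols, names(rows))) {
    rows[[col]] <- if (col == "value") NA_real_ else NA_character_
  }
  rows <- rows[, c(cols, setdiff(names(rows), cols))]
  rows$analysis <- analysis
  structure(rows, class = c("result_table", class(rows)),
            analysis = analysis)
}

#' Write result tables to CSV
#'
#' One CSV per analysis, named `<analysis>.csv`, with rows ordered
#' deterministically by specimen, phenotype and compartment so identical
#' inputs yield byte-identical files.
#'
#' @param tables A `result_table` or list of them.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @return Character vector of paths written, invisibly.
#' @export
write_results <- function(tables, out_dir, overwrite = FALSE) {
  if (inherits(tables, "result_table")) tables <- list(tables)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in tables) {
    analysis <- attr(tab, "analysis")
    path <- file.path(out_dir, paste0(analysis, ".csv"))
    if (file.exists(path) && !overwrite) {
      abort(sprintf("output exists (use overwrite = TRUE): %s", path))
    }
    ord <- order(tab$specimen_id, tab$phenotype, tab$compartment, tab$metric,
                 method = "radix", na.last = TRUE)
    readr::write_csv(as_tibble(tab)[ord, , drop = FALSE], path,
                     progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
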