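#' Run configuration
#'
#' A single structured configuration drives a whole analysis run; the CLI
#' only selects the config file, output directory, verbosity and a seed
#' override, so every run is auditable from its config.
#'
#' @param input Either `list(cells = <csv>, annotations = <geojson or NULL>,
#'   column_map = <list>)` for real data, or `list(preset = <name>,
#'   n_specimens = <int>)` for synthetic data.  Exactly one of
#'   `cells`/`preset` must be given.
#' @param panel Panel name (`"myeloid"`, `"tcell"`, `"nk"`).
#' @param gating List: `method` (see [calibrate_thresholds()]) and optional
#'   `overrides`.
#' @param compartment `"annotation"` or `"ck_density"`; plus optional
#'   `resolution_um`, `bandwidth_um`.
#' @param analyses Toggles: `density`, `infiltration`, `spatial_pairs`
#'   (data frame of source/target or `NULL`), `treg_cd8`, `heatmaps`,
#'   `cohort_stats`.
#' @param out_dir Output directory.
#' @param seed Integer seed (used for synthetic generation).
#' @param metadata Optional tibble/path with `specimen_id` and `site` /
#'   `stage` columns for cohort comparisons.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, panel = "tcell",
                       gating = list(method = "two_component"),
                       compartment = list(mode = "annotation",
                                          resolution_um = 5),
                       analyses = list(density = TRUE, infiltration = TRUE,
                                       spatial_pairs = NULL,
                                       treg_cd8 = FALSE, heatmaps = FALSE,
                                       cohort_stats = TRUE),
                       out_dir = "chordoma_time_out", seed = 1,
                       metadata = NULL) {
  has_cells <- !is.null(input$cells)
  has_preset <- !is.null(input$preset)
  if (has_cells == has_preset) {
    abort("input must specify exactly one of `cells` (paths) or `preset`")
  }
  if (has_cells && !file.exists(input$cells)) {
    abort(sprintf("cell table not found: %s", input$cells))
  }
  if (has_cells && !is.null(input$annotations) &&
      !file.exists(input$annotations)) {
    abort(sprintf("annotation file not found: %s", input$annotations))
  }
  structure(list(input = input, panel = panel, gating = gating,
                 compartment = compartment, analyses = analyses,
                 out_dir = out_dir, seed = seed, metadata = metadata),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file mirroring the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$analyses$spatial_pairs)) {
    y$analyses$spatial_pairs <-
      purrr::map_dfr(y$analyses$spatial_pairs,
                     function(p) tibble(source = p$source, target = p$target))
  }
  do.call(run_config, y)
}

# Load or simulate the cohort; returns list(specimens, annotations, truths)
.load_cohort <- function(config) {
  if (!is.null(config$input$preset)) {
    cfg <- synthetic_preset(config$input$preset)
    n <- config$input$n_specimens %||% 1
    triples <- generate_cohort(cfg, n, config$seed)
    list(specimens = lapply(triples, `[[`, "specimen"),
         annotations = lapply(triples, `[[`, "annotations"),
         truths = lapply(triples, `[[`, "truth"),
         panel = default_panel(cfg$panel))
  } else {
    sp <- read_cell_table(config$input$cells, config$input$column_map,
                          panel_name = config$panel)
    if (inherits(sp, "specimen_table")) sp <- list(sp)
    ann <- if (!is.null(config$input$annotations)) {
      a <- read_annotations(config$input$annotations)
      rep(list(a), length(sp))
    } else vector("list", length(sp))
    list(specimens = sp, annotations = ann, truths = NULL,
         panel = default_panel(config$panel))
  }
}

# Gate + compartmentalize one specimen; returns the processed specimen plus
# log rows (thresholds, ambiguity, dropped-cell counts).
.process_specimen <- function(specimen, annotation, panel, config) {
  thr <- calibrate_thresholds(specimen, panel,
                              method = config$gating$method %||% "two_component",
                              overrides = config$gating$overrides %||% list())
  specimen <- assign_phenotypes(apply_positivity(specimen, thr), panel, thr)
  res_um <- config$compartment$resolution_um %||% 5
  cmap <- if (identical(config$compartment$mode %||% "annotation",
                        "annotation") && !is.null(annotation)) {
    compartments_from_annotations(specimen, annotation, res_um)
  } else {
    compartments_from_ck(specimen,
                         bandwidth_um = config$compartment$bandwidth_um %||% 50,
                         resolution_um = res_um)
  }
  specimen <- assign_cells(specimen, cmap)
  log_rows <- tibble(
    specimen_id = specimen$specimen_id,
    metric = c(paste0("pos_threshold_", names(thr$pos_threshold)),
               "size_threshold_um2", "ambiguity_count", "excluded_cells"),
    value = c(unname(thr$pos_threshold), thr$size_threshold_um2,
              attr(specimen, "ambiguity_count"),
              sum(specimen$cells$compartment == "excluded")))
  list(specimen = specimen, cmap = cmap, log = log_rows)
}

#' Run the full analysis for one specimen
#'
#' Sequences io -> gating -> compartments -> density/infiltration ->
#' spatial, writing per-specimen CSVs and a log of calibrated thresholds,
#' ambiguity counts and dropped cells.  Any stage failure aborts with the
#' stage name and specimen id.
#'
#' @param config A [run_config()].
#' @param specimen_id Which specimen to run (default: the first).
#' @return The report bundle (list of result tables), invisibly.
#' @export
run_specimen <- function(config, specimen_id = NULL) {
  cohort <- .load_cohort(config)
  ids <- vapply(cohort$specimens, `[[`, character(1), "specimen_id")
  k <- if (is.null(specimen_id)) 1L else match(specimen_id, ids)
  if (is.na(k)) abort(sprintf("specimen '%s' not found", specimen_id))
  bundle <- .run_one(cohort$specimens[[k]], cohort$annotations[[k]],
                     cohort$panel, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(bundle$tables, config$out_dir, overwrite = TRUE)
  readr::write_csv(bundle$log, file.path(config$out_dir, "run_log.csv"),
                   progress = FALSE)
  invisible(bundle)
}

.run_one <- function(specimen, annotation, panel, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] specimen %s: %s", name, specimen$specimen_id,
                    conditionMessage(e)))
    })
  }
  proc <- stage("gating/compartment",
                .process_specimen(specimen, annotation, panel, config))
  sp <- proc$specimen
  phenos <- panel_phenotypes(panel)
  tables <- list()
  an <- config$analyses
  if (isTRUE(an$density) || isTRUE(an$infiltration)) {
    dens <- stage("density",
                  cohort_density_table(list(sp), phenos))
    tables$density <- dens
    if (isTRUE(an$infiltration)) {
      inf <- stage("infiltration", purrr::map_dfr(phenos, function(ph) {
        infiltration_call(sp, phenotype = ph)
      }))
      tables$infiltration <- result_table(
        "infiltration",
        inf |> mutate(metric = "category", value = NA_real_,
                      units = .data$category))
    }
  }
  if (!is.null(an$spatial_pairs)) {
    tables$spatial <- stage("spatial",
                            spatial_summary(list(sp), an$spatial_pairs))
  }
  if (isTRUE(an$heatmaps)) {
    stage("heatmaps", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      for (ph in phenos) {
        hm <- density_heatmap(sp, ph, grid_um = 100)
        write_heatmap(hm, file.path(config$out_dir,
                                    sprintf("heatmap_%s_%s.csv",
                                            sp$specimen_id, ph)))
      }
    })
  }
  list(tables = tables, log = proc$log, specimen = sp, cmap = proc$cmap)
}

#' Run the full cohort analysis
#'
#' Per-specimen bundles plus cohort tables: per-phenotype paired
#' tumor-vs-stroma tests, infiltration category counts, spatial summaries,
#' the Treg-CD8 proximity contrast, and site/stage comparisons when
#' metadata is supplied.  Per-specimen failures are collected; cohort
#' statistics are computed over the successes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `tables` (named [result_table()]s /
#'   tibbles), `failures`, and `specimens` (the processed specimens).
#' @export
run_cohort <- function(config) {
  cohort <- .load_cohort(config)
  panel <- cohort$panel
  phenos <- panel_phenotypes(panel)
  processed <- list(); logs <- list(); failures <- character()
  for (k in seq_along(cohort$specimens)) {
    res <- tryCatch(
      .process_specimen(cohort$specimens[[k]], cohort$annotations[[k]],
                        panel, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s",
                                      cohort$specimens[[k]]$specimen_id,
                                      conditionMessage(res)))
    } else {
      processed[[length(processed) + 1]] <- res$specimen
      logs[[length(logs) + 1]] <- res$log
    }
  }
  if (length(processed) == 0) abort("every specimen failed processing")
  an <- config$analyses
  tables <- list()
  flag_filters <- if (identical(config$panel, "tcell") ||
                      identical(panel$panel_name, "tcell")) {
    c("none", "Ki67+", "PD1+")
  } else if (identical(panel$panel_name, "nk")) c("none", "GzmB+")
  else "none"
  dens <- cohort_density_table(processed, phenos, flag_filters)
  if (isTRUE(an$density)) tables$density <- dens
  if (isTRUE(an$infiltration)) {
    inf <- purrr::map_dfr(processed, function(sp) {
      purrr::map_dfr(phenos, function(ph) infiltration_call(sp, phenotype = ph))
    })
    counts <- inf |>
      group_by(.data$phenotype, .data$category) |>
      summarise(n = n(), .groups = "drop")
    tables$infiltration <- result_table(
      "infiltration",
      inf |> mutate(metric = "category", value = NA_real_,
                    units = .data$category))
    tables$infiltration_counts <- result_table(
      "infiltration_counts",
      counts |> mutate(specimen_id = "cohort", metric = .data$category,
                       value = as.numeric(.data$n), units = "specimens"))
  }
  if (!is.null(an$spatial_pairs)) {
    tables$spatial <- spatial_summary(processed, an$spatial_pairs)
  }
  if (isTRUE(an$heatmaps)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in processed) {
      for (ph in phenos) {
        hm <- density_heatmap(sp, ph, grid_um = 100)
        write_heatmap(hm, file.path(config$out_dir,
                                    sprintf("heatmap_%s_%s.csv",
                                            sp$specimen_id, ph)))
      }
    }
  }
  if (isTRUE(an$treg_cd8)) {
    ct <- treg_cd8_contrast(processed)
    tables$treg_cd8 <- result_table(
      "treg_cd8",
      bind_rows(
        ct$pairs |>
          tidyr::pivot_longer(-all_of("specimen_id"), names_to = "metric",
                              values_to = "value") |>
          mutate(units = "%"),
        if (!is.null(ct$test)) {
          tibble(specimen_id = "cohort",
                 metric = c("wilcoxon_p", "n_dropped"),
                 value = c(ct$test$p_value, ct$n_dropped), units = "")
        }))
  }
  if (isTRUE(an$cohort_stats)) {
    paired <- cohort_compare(dens, "compartment-paired")
    tables$stats_paired <- paired
    if (!is.null(config$metadata)) {
      md <- config$metadata
      if (is.character(md)) md <- readr::read_csv(md, show_col_types = FALSE)
      if ("site" %in% names(md)) {
        tables$stats_site <- cohort_compare(dens, "site", metadata = md)
      }
      if ("stage" %in% names(md)) {
        tables$stats_stage <- cohort_compare(dens, "stage", metadata = md)
      }
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rt <- purrr::keep(tables, ~ inherits(.x, "result_table"))
  write_results(rt, config$out_dir, overwrite = TRUE)
  for (nm in setdiff(names(tables), names(rt))) {
    readr::write_csv(as_tibble(tables[[nm]]),
                     file.path(config$out_dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  log_tab <- bind_rows(logs)
  if (length(failures) > 0) {
    log_tab <- bind_rows(log_tab,
                         tibble(specimen_id = "cohort", metric = "failure",
                                value = NA_real_))
  }
  readr::write_csv(log_tab, file.path(config$out_dir, "run_log.csv"),
                   progress = FALSE)
  if (length(failures) > 0) {
    writeLines(failures, file.path(config$out_dir, "failures.txt"))
  }
  invisible(list(tables = tables, failures = failures,
                 specimens = processed))
}
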