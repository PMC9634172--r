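# Marked point-process tissue simulator.  Specimens are generated as
# cytokeratin-positive tumor lobules embedded in stroma; each phenotype is
# an independent Poisson process with compartment-specific intensity, marker
# intensities are two-component lognormal (negative/positive populations),
# nuclear areas contrast tumor vs immune cells, and an optional attraction
# kernel pulls one phenotype toward another for proximity analyses.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Per-specimen seed derived from a master seed; the splitting rule is fixed
# so cohorts are reproducible regardless of call order.
.split_seed <- function(master_seed, i) {
  (as.numeric(master_seed) + 104729 * as.numeric(i)) %% 2147483647
}

#' Synthetic tissue configuration
#'
#' Defines the generative model: field size, tumor lobule geometry,
#' per-phenotype compartment intensities, the marker-intensity model, the
#' nuclear-size model, flag probabilities, and an optional attraction
#' kernel.
#'
#' @param panel Panel the specimen is "stained" with (`"myeloid"`,
#'   `"tcell"`, `"nk"`); fixes the marker set.
#' @param field_width_um,field_height_um Field size, default 2000 x 2000 um
#'   (a 2 x 2 mm field).
#' @param n_lobules Number of tumor lobules (discs, drawn as 64-gons).
#' @param lobule_radius_um Range (min, max) of lobule radii.
#' @param phenotypes Tibble with columns `phenotype`, `lambda_tumor`,
#'   `lambda_stroma` (cells/mm^2), `pos_markers` (list column of marker
#'   names drawn from the positive component) and `size` (`"immune"` or
#'   `"tumor"`).  Defaults are panel-specific (see
#'   [synthetic_preset()]).
#' @param neg_meanlog,intensity_sdlog,separation Marker intensity model on
#'   the log scale: negative component `N(neg_meanlog, sdlog)`, positive
#'   component shifted up by `separation` sd units.  The default of 6 sd
#'   puts the minimum-error boundary 3 sd from each mode (about 0.1%
#'   misclassification per marker side), i.e. nearly perfect gating;
#'   shrink it for stress tests.
#' @param immune_area_um2,tumor_area_um2,area_sdlog Lognormal nuclear-area
#'   medians for immune and tumor-sized cells; the contrast drives the NK
#'   size gate.
#' @param flag_probs Named list `flag -> named numeric` of per-phenotype
#'   flag probabilities (Ki67, PD1, GzmB); a value may be a scalar or a
#'   `c(tumor =, stroma =)` pair.
#' @param attraction `NULL`, or `list(source =, target =, target_flag =,
#'   scale_um =, strength =)`: a `strength` fraction of source cells is
#'   placed at a Gaussian offset (sd `scale_um`) from a random target cell.
#' @param heterogeneity_sdlog Between-specimen lognormal multiplier sd for
#'   the immune intensities (0 = all specimens share the true lambdas).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(panel = "tcell",
                             field_width_um = 2000, field_height_um = 2000,
                             n_lobules = 6,
                             lobule_radius_um = c(150, 350),
                             phenotypes = NULL,
                             neg_meanlog = 1.0, intensity_sdlog = 0.4,
                             separation = 6,
                             immune_area_um2 = 30, tumor_area_um2 = 80,
                             area_sdlog = 0.25,
                             flag_probs = NULL,
                             attraction = NULL,
                             heterogeneity_sdlog = 0) {
  if (is.null(phenotypes)) phenotypes <- .default_phenotypes(panel)
  phenotypes <- as_tibble(phenotypes)
  stopifnot(all(c("phenotype", "lambda_tumor", "lambda_stroma",
                  "pos_markers", "size") %in% names(phenotypes)))
  if (any(phenotypes$lambda_tumor < 0) || any(phenotypes$lambda_stroma < 0)) {
    abort("intensities (lambdas) must be nonnegative")
  }
  if (is.null(flag_probs)) flag_probs <- .default_flag_probs(panel)
  for (fl in flag_probs) {
    if (any(unlist(fl) < 0) || any(unlist(fl) > 1)) {
      abort("flag probabilities must lie in [0, 1]")
    }
  }
  if (separation <= 0) abort("positive component must lie above negative")
  structure(list(panel = panel,
                 field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 n_lobules = n_lobules,
                 lobule_radius_um = lobule_radius_um,
                 phenotypes = phenotypes,
                 neg_meanlog = neg_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 separation = separation,
                 immune_area_um2 = immune_area_um2,
                 tumor_area_um2 = tumor_area_um2,
                 area_sdlog = area_sdlog,
                 flag_probs = flag_probs,
                 attraction = attraction,
                 heterogeneity_sdlog = heterogeneity_sdlog),
            class = "synthetic_config")
}

# Panel-specific default populations.  Immune lambdas follow the magnitude
# of densities reported for chordoma (tens of cells/mm^2, stroma-skewed for
# T cells, tumor-skewed for macrophages); chordoma cells are dense inside
# lobules.  In the NK panel tumor cells also express CD56 (the key
# confound) and a sparse large CD56+CD16+ CK- distractor population
# exercises the size gate.
.default_phenotypes <- function(panel) {
  row <- function(phenotype, lt, ls, pos, size) {
    tibble(phenotype = phenotype, lambda_tumor = lt, lambda_stroma = ls,
           pos_markers = list(pos), size = size)
  }
  switch(panel,
    myeloid = bind_rows(
      row("tumor", 600, 20, "CK", "tumor"),
      row("pan_macrophage", 43.6, 25.1, "CD68", "immune"),
      row("monocyte", 15, 10, c("CD11b", "CD14"), "immune"),
      row("pmn_like", 10, 8, c("CD11b", "CD15"), "immune"),
      row("other", 100, 100, character(), "immune")),
    tcell = bind_rows(
      row("tumor", 600, 20, "CK", "tumor"),
      row("cd4_helper", 11.4, 30.6, "CD4", "immune"),
      row("cd8_cytotoxic", 10.1, 36.7, "CD8", "immune"),
      row("treg", 5, 15, c("CD4", "FOXP3"), "immune"),
      row("other", 100, 100, character(), "immune")),
    nk = bind_rows(
      row("tumor", 600, 20, c("CK", "CD56"), "tumor"),
      row("nk", 8, 12, c("CD16", "CD56"), "immune"),
      row("other", 40, 80, "CD3", "immune"),      # T cells: CD3+, not NK
      row("other", 100, 100, character(), "immune")),
    abort(sprintf("unknown panel '%s'", panel)))
}

.default_flag_probs <- function(panel) {
  switch(panel,
    tcell = list(ki67 = c(cd4_helper = 0.15, cd8_cytotoxic = 0.15,
                          treg = 0.02),
                 pd1 = c(cd4_helper = 0.10, cd8_cytotoxic = 0.35,
                         treg = 0.02)),
    nk = list(gzmb = c(nk = 0.3)),
    list())
}

# Regular 64-gon approximating a disc.
.disc_polygon <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# TRUE for points inside any lobule polygon.
.in_lobules <- function(x, y, lobules) {
  if (length(x) == 0) return(logical(0))
  inside <- rep(FALSE, length(x))
  pts <- cbind(x, y)
  for (p in lobules) {
    bb <- !inside & x >= min(p[, 1]) & x <= max(p[, 1]) &
      y >= min(p[, 2]) & y <= max(p[, 2])
    if (any(bb)) {
      inside[bb] <- mgcv::in.out(rbind(p, p[1, ]), pts[bb, , drop = FALSE])
    }
  }
  inside
}

#' Generate one synthetic specimen
#'
#' Places tumor lobules, then each phenotype as an independent Poisson
#' process with its compartment-specific intensity (realized by thinning a
#' field-wide proposal to the compartment, so counts are exactly Poisson
#' with rate lambda x compartment area).  Marker intensities come from the
#' phenotype-appropriate mixture component, nuclear areas from the size
#' model, and flags from the configured probabilities.  With an attraction
#' kernel, a `strength` fraction of source cells is repositioned to a
#' Gaussian offset from a randomly chosen target cell.  Deterministic under
#' `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param specimen_id Identifier, default `"synthetic_<seed>"`.
#' @return List with elements `specimen` ([specimen_table()]),
#'   `annotations` ([annotation_set()]: lobule polygons as tumor, the field
#'   rectangle as stroma) and `truth` (ground truth: per-cell true
#'   phenotype/compartment/flags, true lambdas, lobule geometry, attraction
#'   settings).
#' @export
generate_specimen <- function(config, seed,
                              specimen_id = paste0("synthetic_", seed)) {
  .with_seed(seed, {
    W <- config$field_width_um; H <- config$field_height_um
    field_mm2 <- W * H * 1e-6
    expected <- sum((config$phenotypes$lambda_tumor +
                       config$phenotypes$lambda_stroma)) * field_mm2
    if (expected > 1e6) abort("configuration implies > 1e6 cells")

    lobules <- list()
    if (config$n_lobules > 0) {
      r <- runif(config$n_lobules, config$lobule_radius_um[1],
                 config$lobule_radius_um[2])
      cx <- runif(config$n_lobules, r, W - r)
      cy <- runif(config$n_lobules, r, H - r)
      lobules <- lapply(seq_len(config$n_lobules), function(k) {
        .disc_polygon(cx[k], cy[k], r[k])
      })
    }

    het <- config$heterogeneity_sdlog
    ph <- config$phenotypes
    mult <- if (het > 0) {
      rlnorm(nrow(ph), meanlog = -het^2 / 2, sdlog = het)
    } else rep(1, nrow(ph))

    place <- function(lambda_mm2, in_tumor) {
      n_prop <- rpois(1, lambda_mm2 * field_mm2)
      if (n_prop == 0) return(cbind(numeric(0), numeric(0)))
      x <- runif(n_prop, 0, W); y <- runif(n_prop, 0, H)
      keep <- .in_lobules(x, y, lobules)
      if (!in_tumor) keep <- !keep
      cbind(x[keep], y[keep])
    }

    rows <- list()
    for (k in seq_len(nrow(ph))) {
      lt <- ph$lambda_tumor[k] * mult[k]
      ls <- ph$lambda_stroma[k] * mult[k]
      pt <- place(lt, TRUE)
      ps <- place(ls, FALSE)
      n_k <- nrow(pt) + nrow(ps)
      if (n_k == 0) next
      rows[[length(rows) + 1]] <- tibble(
        x_um = c(pt[, 1], ps[, 1]), y_um = c(pt[, 2], ps[, 2]),
        true_phenotype = ph$phenotype[k],
        size_class = ph$size[k],
        pheno_row = k)
    }
    cells <- if (length(rows) > 0) bind_rows(rows) else
      tibble(x_um = numeric(0), y_um = numeric(0),
             true_phenotype = character(0), size_class = character(0),
             pheno_row = integer(0))
    n <- nrow(cells)

    # flags (needed before attraction so "nonproliferating" targets exist)
    flag_cols <- names(config$flag_probs)
    for (fl in flag_cols) {
      probs <- config$flag_probs[[fl]]
      p <- rep(0, n)
      for (lab in names(probs)) {
        pv <- probs[[lab]]
        hit <- cells$true_phenotype == lab
        if (length(pv) == 1) {
          p[hit] <- pv
        } else {
          in_t <- .in_lobules(cells$x_um, cells$y_um, lobules)
          p[hit & in_t] <- pv[["tumor"]]
          p[hit & !in_t] <- pv[["stroma"]]
        }
      }
      cells[[paste0("flag_", fl)]] <- rbinom(n, 1, p) == 1
    }

    # attraction kernel: reposition a fraction of source cells near targets
    att <- config$attraction
    if (!is.null(att) && n > 0) {
      tgt <- cells$true_phenotype == att$target
      if (!is.null(att$target_flag)) {
        fcol <- switch(att$target_flag,
                       proliferating = "flag_ki67",
                       nonproliferating = "flag_ki67",
                       paste0("flag_", att$target_flag))
        fv <- cells[[fcol]]
        tgt <- tgt & if (identical(att$target_flag, "nonproliferating"))
          !fv else fv
      }
      src <- which(cells$true_phenotype == att$source)
      if (any(tgt) && length(src) > 0) {
        move <- src[runif(length(src)) < att$strength]
        if (length(move) > 0) {
          anchor <- sample(which(tgt), length(move), replace = TRUE)
          for (m in seq_along(move)) {
            repeat {
              nx <- cells$x_um[anchor[m]] + rnorm(1, 0, att$scale_um)
              ny <- cells$y_um[anchor[m]] + rnorm(1, 0, att$scale_um)
              if (nx >= 0 && nx <= W && ny >= 0 && ny <= H) break
            }
            cells$x_um[move[m]] <- nx
            cells$y_um[move[m]] <- ny
          }
        }
      }
    }

    cells$true_compartment <- ifelse(
      .in_lobules(cells$x_um, cells$y_um, lobules), "tumor", "stroma")

    # nuclear areas
    med <- ifelse(cells$size_class == "tumor", config$tumor_area_um2,
                  config$immune_area_um2)
    cells$nuclear_area_um2 <- rlnorm(n, meanlog = log(med),
                                     sdlog = config$area_sdlog)

    # marker intensities: positive component for the phenotype's defining
    # markers and for markers tied to set flags, negative otherwise
    panel <- default_panel(config$panel)
    mu_neg <- config$neg_meanlog
    mu_pos <- mu_neg + config$separation * config$intensity_sdlog
    flag_marker <- panel$flag_markers
    intens <- matrix(0, n, length(panel$markers),
                     dimnames = list(NULL, panel$markers))
    pos_by_row <- lapply(seq_len(nrow(ph)), function(k) ph$pos_markers[[k]])
    for (m in panel$markers) {
      is_pos <- rep(FALSE, n)
      for (k in seq_len(nrow(ph))) {
        if (m %in% pos_by_row[[k]]) is_pos[cells$pheno_row == k] <- TRUE
      }
      fl <- names(flag_marker)[flag_marker == m]
      if (length(fl) == 1 && paste0("flag_", fl) %in% names(cells)) {
        is_pos <- cells[[paste0("flag_", fl)]]
      }
      intens[, m] <- rlnorm(n, meanlog = ifelse(is_pos, mu_pos, mu_neg),
                            sdlog = config$intensity_sdlog)
    }

    cell_id <- sprintf("c%06d", seq_len(n))
    sp_cells <- tibble(cell_id = cell_id, x_um = cells$x_um,
                       y_um = cells$y_um,
                       nuclear_area_um2 = cells$nuclear_area_um2)
    for (m in panel$markers) sp_cells[[m]] <- intens[, m]

    specimen <- specimen_table(sp_cells, specimen_id,
                               field_width_um = W, field_height_um = H,
                               markers = panel$markers,
                               source = "TMA-core",
                               panel_name = config$panel)
    ann <- annotation_set(specimen_id,
                          tumor = lobules,
                          stroma = list(rbind(c(0, 0), c(W, 0), c(W, H),
                                              c(0, H))))
    truth_cells <- tibble(cell_id = cell_id,
                          true_phenotype = cells$true_phenotype,
                          true_compartment = cells$true_compartment)
    for (fl in flag_cols) {
      truth_cells[[paste0("flag_", fl)]] <- cells[[paste0("flag_", fl)]]
    }
    lam <- ph |>
      mutate(lambda_tumor = .data$lambda_tumor * mult,
             lambda_stroma = .data$lambda_stroma * mult,
             true_category = classify_infiltration(.data$lambda_tumor,
                                                   .data$lambda_stroma)) |>
      select(all_of(c("phenotype", "lambda_tumor", "lambda_stroma",
                      "true_category")))
    truth <- list(specimen_id = specimen_id, cells = truth_cells,
                  lambdas = lam, lobules = lobules,
                  attraction = att, seed = seed)
    list(specimen = specimen, annotations = ann, truth = truth)
  })
}

#' Generate a synthetic cohort
#'
#' Per-specimen seeds are derived from the master seed by the fixed rule
#' `seed_i = (seed + 104729 * i) mod (2^31 - 1)`, so each specimen is
#' reproducible independently of how many others are generated.
#'
#' @param config A [synthetic_config()].
#' @param n_specimens Number of specimens (>= 1).
#' @param seed Master seed.
#' @return List of `(specimen, annotations, truth)` triples.
#' @export
generate_cohort <- function(config, n_specimens, seed) {
  if (n_specimens < 1) abort("n_specimens must be >= 1")
  lapply(seq_len(n_specimens), function(i) {
    generate_specimen(config, .split_seed(seed, i),
                      specimen_id = sprintf("synthetic_%d_%02d", seed, i))
  })
}

#' Tabulate planted ground truth for a cohort
#'
#' @param triples Output of [generate_cohort()] (or a list of
#'   `generate_specimen()` results).
#' @return A [result_table()] (`analysis = "planted_truth"`) with one row
#'   per specimen x phenotype x metric (true lambdas and category).
#' @export
planted_truth_report <- function(triples) {
  rows <- purrr::map_dfr(triples, function(tr) {
    lam <- tr$truth$lambdas
    tibble(specimen_id = tr$truth$specimen_id,
           phenotype = lam$phenotype,
           lambda_tumor = lam$lambda_tumor,
           lambda_stroma = lam$lambda_stroma,
           true_category = lam$true_category,
           attraction = if (is.null(tr$truth$attraction)) "off" else "on")
  })
  long <- rows |>
    tidyr::pivot_longer(all_of(c("lambda_tumor", "lambda_stroma")),
                        names_to = "metric", values_to = "value") |>
    mutate(compartment = sub("lambda_", "", .data$metric),
           metric = "true_lambda", units = "cells/mm^2") |>
    select(all_of(c("specimen_id", "phenotype", "compartment", "metric",
                    "value", "units")))
  cat_rows <- rows |>
    mutate(metric = "true_category", value = NA_real_,
           units = .data$true_category) |>
    select(all_of(c("specimen_id", "phenotype", "metric", "value", "units")))
  result_table("planted_truth", bind_rows(long, cat_rows))
}

#' Inject ground-truth labels into a specimen
#'
#' Bypasses gating by copying the generator's true phenotype and flags into
#' the specimen table; used to test downstream stages in isolation from
#' gating error.
#'
#' @param specimen A [specimen_table()] from [generate_specimen()].
#' @param truth The matching `truth` element.
#' @return The specimen with `phenotype`, flag and `compartment` columns
#'   set from the ground truth.
#' @export
apply_ground_truth <- function(specimen, truth) {
  stopifnot(identical(specimen$cells$cell_id, truth$cells$cell_id))
  specimen$cells$phenotype <- truth$cells$true_phenotype
  specimen$cells$compartment <- truth$cells$true_compartment
  for (col in grep("^flag_", names(truth$cells), value = TRUE)) {
    specimen$cells[[col]] <- truth$cells[[col]]
  }
  specimen
}

#' Named synthetic presets
#'
#' Fixture configurations exercising the pipeline's decision points:
#' \describe{
#'   \item{inclusion}{T-cell panel with every T phenotype planted at a 3.0
#'     tumor:stroma ratio (true category `included`).}
#'   \item{exclusion}{T phenotypes at a 10x stroma:tumor ratio (true
#'     category `excluded`).}
#'   \item{nk-confound}{NK panel with CD56+ tumor cells and a large
#'     CD56+CD16+ CK- distractor population; the size gate is load-bearing.}
#'   \item{treg-attraction}{T-cell panel with Tregs attracted (strength
#'     0.7, scale 10 um) to nonproliferating CD8 cells.}
#'   \item{null}{T-cell panel, no attraction; spatial null.}
#' }
#'
#' @param name Preset name.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("inclusion", "exclusion",
                                      "nk-confound", "treg-attraction",
                                      "null")) {
  name <- match.arg(name)
  row <- function(phenotype, lt, ls, pos, size = "immune") {
    tibble(phenotype = phenotype, lambda_tumor = lt, lambda_stroma = ls,
           pos_markers = list(pos), size = size)
  }
  tumor_row <- row("tumor", 600, 20, "CK", "tumor")
  other_row <- row("other", 100, 100, character())
  switch(name,
    inclusion = synthetic_config("tcell", phenotypes = bind_rows(
      tumor_row,
      row("cd4_helper", 30, 10, "CD4"),
      row("cd8_cytotoxic", 30, 10, "CD8"),
      row("treg", 30, 10, c("CD4", "FOXP3")),
      other_row)),
    exclusion = synthetic_config("tcell", phenotypes = bind_rows(
      tumor_row,
      row("cd4_helper", 4, 40, "CD4"),
      row("cd8_cytotoxic", 4, 40, "CD8"),
      row("treg", 4, 40, c("CD4", "FOXP3")),
      other_row)),
    "nk-confound" = synthetic_config("nk", phenotypes = bind_rows(
      row("tumor", 600, 20, c("CK", "CD56"), "tumor"),
      row("nk", 8, 12, c("CD16", "CD56")),
      row("other", 10, 10, c("CD16", "CD56"), "tumor"),  # large distractor
      row("other", 40, 80, "CD3"),
      other_row)),
    "treg-attraction" = synthetic_config("tcell",
      attraction = list(source = "treg", target = "cd8_cytotoxic",
                        target_flag = "nonproliferating", scale_um = 10,
                        strength = 0.7)),
    null = synthetic_config("tcell"))
}
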