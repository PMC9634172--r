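#' Per-specimen gating thresholds
#'
#' Positivity cutoffs are calibrated for each specimen independently to
#' absorb stain-uptake variability between slides.  A threshold object
#' carries one positive cutoff per marker, optional distinct "low" cutoffs
#' (HLA-DR low/- semantics), a "highly positive" cutoff for CD68
#' pan-macrophage calls, and the nuclear-size cutoff used by the NK gate.
#'
#' @param specimen_id Specimen the thresholds were calibrated on.
#' @param pos_threshold Named numeric vector, marker -> positivity cutoff.
#' @param low_threshold Named numeric vector for markers with low/-
#'   semantics; must not exceed the positive cutoff.
#' @param high_threshold Named numeric vector of "highly positive" cutoffs.
#' @param size_threshold_um2 Nuclear-area cutoff for the NK size gate, or
#'   `NA`.
#' @return A `gating_thresholds` object.
#' @export
gating_thresholds <- function(specimen_id, pos_threshold,
                              low_threshold = numeric(),
                              high_threshold = numeric(),
                              size_threshold_um2 = NA_real_) {
  if (any(pos_threshold < 0) || any(low_threshold < 0) ||
      any(high_threshold < 0)) {
    abort("gating cutoffs must be nonnegative")
  }
  shared <- intersect(names(low_threshold), names(pos_threshold))
  if (any(low_threshold[shared] > pos_threshold[shared])) {
    abort("low_threshold must not exceed pos_threshold")
  }
  structure(list(specimen_id = specimen_id,
                 pos_threshold = pos_threshold,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 size_threshold_um2 = size_threshold_um2),
            class = "gating_thresholds")
}

# Minimum-error split of a bimodal intensity sample: fit a two-component
# Gaussian mixture on log1p intensities and cut where the weighted component
# densities cross, between the component means.
.two_component_cutoff <- function(x) {
  lx <- log1p(x)
  fit <- tryCatch(
    Mclust(lx, G = 2, modelNames = c("V", "E"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  p <- fit$parameters
  mu <- p$mean
  sig <- sqrt(if (length(p$variance$sigmasq) == 2) p$variance$sigmasq
              else rep(p$variance$sigmasq, 2))
  w <- p$pro
  lo <- which.min(mu); hi <- which.max(mu)
  if (mu[lo] == mu[hi]) return(NA_real_)
  grid <- seq(mu[lo], mu[hi], length.out = 512)
  diff <- w[lo] * dnorm(grid, mu[lo], sig[lo]) -
    w[hi] * dnorm(grid, mu[hi], sig[hi])
  cross <- which(diff[-length(diff)] > 0 & diff[-1] <= 0)
  cut_l <- if (length(cross) > 0) grid[cross[1]] else mean(mu)
  expm1(cut_l)
}

#' Calibrate positivity thresholds for one specimen
#'
#' @param specimen A [specimen_table()] carrying intensities for every panel
#'   marker.
#' @param panel A [panel_definition()].
#' @param method `"quantile"` (default) puts the positive cutoff at a fixed
#'   intensity quantile per marker; `"two_component"` fits a two-component
#'   mixture to each marker's log intensities and cuts at the minimum-error
#'   boundary between the components; `"manual"` uses `overrides` only.
#' @param overrides List with optional entries `pos_threshold`,
#'   `low_threshold`, `high_threshold` (named numeric vectors) and
#'   `size_threshold_um2`; manual overrides always win, in every method.
#' @param pos_quantile,high_quantile,size_quantile Calibration conventions
#'   (not values from any study): positive cutoff at the 0.90 intensity
#'   quantile, CD68 "highly positive" at 0.98, and the NK size gate at the
#'   0.25 quantile of nuclear area among CD56+ cells.  In `two_component`
#'   mode the positive and CD68-high cutoffs come from the mixture split
#'   instead.
#' @return A [gating_thresholds()] object.
#' @export
calibrate_thresholds <- function(specimen, panel,
                                 method = c("quantile", "two_component",
                                            "manual"),
                                 overrides = list(),
                                 pos_quantile = 0.90, high_quantile = 0.98,
                                 size_quantile = 0.25) {
  method <- match.arg(method)
  cells <- specimen$cells
  missing <- setdiff(panel$markers, names(cells))
  if (length(missing) > 0) {
    abort(paste0("specimen lacks intensities for panel marker(s): ",
                 paste(missing, collapse = ", ")))
  }
  ov_pos <- overrides$pos_threshold %||% numeric()
  ov_low <- overrides$low_threshold %||% numeric()
  ov_high <- overrides$high_threshold %||% numeric()

  pos <- setNames(rep(NA_real_, length(panel$markers)), panel$markers)
  for (m in panel$markers) {
    if (m %in% names(ov_pos)) { pos[m] <- ov_pos[[m]]; next }
    if (method == "manual") {
      abort(sprintf(
        "method = 'manual' but no override for marker '%s'", m))
    }
    x <- cells[[m]]
    if (length(x) == 0 || sd(x) == 0) {
      abort(sprintf(
        "marker '%s' has zero intensity variance; supply a manual threshold",
        m))
    }
    pos[m] <- if (method == "quantile") {
      unname(quantile(x, pos_quantile, names = FALSE))
    } else {
      ct <- .two_component_cutoff(x)
      if (is.na(ct)) unname(quantile(x, pos_quantile, names = FALSE)) else ct
    }
  }

  # Distinct low cutoffs only where overridden; by default low == positive
  # cutoff, i.e. "low/-" means "not positive".
  low_markers <- unique(unlist(lapply(panel$rules, `[[`, "required_low")))
  low <- pos[intersect(low_markers, names(pos))]
  low[names(ov_low)[names(ov_low) %in% names(low)]] <-
    ov_low[names(ov_low) %in% names(low)]

  high_markers <- unique(unlist(lapply(panel$rules, `[[`, "required_high")))
  high <- setNames(rep(NA_real_, length(high_markers)), high_markers)
  for (m in high_markers) {
    high[m] <- if (m %in% names(ov_high)) {
      ov_high[[m]]
    } else if (method == "two_component") {
      # the mixture boundary already separates bright cells from dim ones
      pos[m]
    } else {
      unname(quantile(cells[[m]], high_quantile, names = FALSE))
    }
  }

  size_thr <- NA_real_
  uses_size <- any(!vapply(panel$rules, function(r) is.null(r$size_gate),
                           logical(1)))
  if (uses_size) {
    if (!is.null(overrides$size_threshold_um2)) {
      size_thr <- overrides$size_threshold_um2
    } else if ("CD56" %in% names(pos)) {
      cd56_pos <- cells$nuclear_area_um2[cells$CD56 > pos["CD56"]]
      if (length(cd56_pos) > 0) {
        size_thr <- if (method == "two_component") {
          # small NK nuclei vs large chordoma-like nuclei are bimodal among
          # CD56+ cells; split them the same way as intensities
          ct <- .two_component_cutoff(cd56_pos)
          if (is.na(ct)) unname(quantile(cd56_pos, size_quantile,
                                         names = FALSE)) else ct
        } else {
          unname(quantile(cd56_pos, size_quantile, names = FALSE))
        }
      }
    }
  }

  gating_thresholds(specimen$specimen_id, pos_threshold = pos,
                    low_threshold = low, high_threshold = high,
                    size_threshold_um2 = size_thr)
}

#' Apply positivity calls to a specimen
#'
#' Fills `pos_<marker>` logical columns.  The boundary convention is strict:
#' a cell whose intensity equals the cutoff is negative.  For markers with
#' low/- semantics, `low_<marker>` is `TRUE` when intensity is at or below
#' the low cutoff (with the default low == positive cutoff, low is exactly
#' "not positive").
#'
#' @param specimen A [specimen_table()].
#' @param thresholds A [gating_thresholds()] covering all panel markers.
#' @return The specimen with positivity columns filled.
#' @export
apply_positivity <- function(specimen, thresholds) {
  cells <- specimen$cells
  missing <- setdiff(names(thresholds$pos_threshold), names(cells))
  if (length(missing) > 0) {
    abort(paste0("thresholds cover marker(s) absent from specimen: ",
                 paste(missing, collapse = ", ")))
  }
  for (m in names(thresholds$pos_threshold)) {
    cells[[paste0("pos_", m)]] <- cells[[m]] > thresholds$pos_threshold[[m]]
  }
  for (m in names(thresholds$low_threshold)) {
    cells[[paste0("low_", m)]] <- cells[[m]] <= thresholds$low_threshold[[m]]
  }
  for (m in names(thresholds$high_threshold)) {
    cells[[paste0("high_", m)]] <- cells[[m]] > thresholds$high_threshold[[m]]
  }
  specimen$cells <- cells
  specimen$thresholds <- thresholds
  specimen
}

#' Assign phenotype labels and subset flags
#'
#' Evaluates the panel's gating rules in priority order; the first rule a
#' cell satisfies gives its label.  CK+ cells are labeled `tumor` ahead of
#' any immune rule, NK calls additionally require nuclear area below the
#' specimen size threshold (large CD56+ cells are chordoma-like), and cells
#' matching no rule become `other`.  Ki67+/PD1+ flags are set on T-cell
#' labels (Ki67+ cells are the proliferating subset) and GzmB+ on NK cells.
#'
#' @param specimen A [specimen_table()] with positivity filled (see
#'   [apply_positivity()]); if not, positivity is applied first from
#'   `thresholds`.
#' @param panel A [panel_definition()].
#' @param thresholds A [gating_thresholds()].
#' @return The specimen with `phenotype` and `flag_*` columns filled; the
#'   number of cells matching more than one rule (before priority
#'   resolution, tumor excluded) is recorded in the `ambiguity_count`
#'   attribute.
#' @export
assign_phenotypes <- function(specimen, panel, thresholds) {
  if (!any(grepl("^pos_", names(specimen$cells)))) {
    specimen <- apply_positivity(specimen, thresholds)
  }
  cells <- specimen$cells
  nc <- nrow(cells)
  label <- rep("other", nc)
  assigned <- rep(FALSE, nc)
  match_count <- rep(0L, nc)

  size_ok <- function(gate) {
    if (is.null(gate)) return(rep(TRUE, nc))
    thr <- thresholds$size_threshold_um2
    if (is.na(thr)) {
      abort("panel rule uses a size gate but size_threshold_um2 is NA")
    }
    if (gate == "below") cells$nuclear_area_um2 < thr
    else cells$nuclear_area_um2 >= thr
  }

  for (rule in panel$rules) {
    ok <- rep(TRUE, nc)
    for (m in rule$required_positive) ok <- ok & cells[[paste0("pos_", m)]]
    for (m in rule$required_negative) ok <- ok & !cells[[paste0("pos_", m)]]
    for (m in rule$required_low) {
      col <- paste0("low_", m)
      ok <- ok & if (col %in% names(cells)) cells[[col]]
        else !cells[[paste0("pos_", m)]]
    }
    for (m in rule$required_high) ok <- ok & cells[[paste0("high_", m)]]
    ok <- ok & size_ok(rule$size_gate)
    if (rule$label != "tumor") match_count <- match_count + ok
    label[ok & !assigned] <- rule$label
    assigned <- assigned | ok
  }
  cells$phenotype <- label
  ambiguity <- sum(match_count > 1 & label != "tumor")

  for (flag in names(panel$flag_markers)) {
    m <- panel$flag_markers[[flag]]
    on_labels <- panel$flag_labels[[flag]]
    cells[[paste0("flag_", flag)]] <-
      cells[[paste0("pos_", m)]] & label %in% on_labels
  }

  specimen$cells <- cells
  attr(specimen, "ambiguity_count") <- ambiguity
  specimen
}

#' Run calibration, positivity and phenotyping in one call
#'
#' @inheritParams calibrate_thresholds
#' @param ... Passed to [calibrate_thresholds()].
#' @return The gated specimen (see [assign_phenotypes()]).
#' @export
gate_specimen <- function(specimen, panel, method = "quantile",
                          overrides = list(), ...) {
  thr <- calibrate_thresholds(specimen, panel, method = method,
                              overrides = overrides, ...)
  assign_phenotypes(apply_positivity(specimen, thr), panel, thr)
}
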