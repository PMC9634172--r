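#' Phenotype gating rule
#'
#' A declarative rule mapping marker positivity calls to a phenotype label.
#' Rules are evaluated in `priority` order (lower first); the first rule a
#' cell satisfies wins.
#'
#' @param label Phenotype label assigned when the rule matches.
#' @param required_positive Markers that must be called positive.
#' @param required_negative Markers that must be called negative.
#' @param required_low Markers that must be at or below their "low" cutoff
#'   (distinct low/- semantics, used for HLA-DR; by default low means
#'   "not positive").
#' @param required_high Markers that must exceed their "highly positive"
#'   cutoff (used for CD68 pan-macrophage identification).
#' @param size_gate `"below"` or `"above"` to additionally gate on nuclear
#'   area against the specimen's calibrated size threshold, or `NULL`.
#' @param priority Integer; lower priorities are evaluated first.
#' @return A `phenotype_rule` object.
#' @export
phenotype_rule <- function(label, required_positive = character(),
                           required_negative = character(),
                           required_low = character(),
                           required_high = character(),
                           size_gate = NULL, priority = 10L) {
  if (length(intersect(required_positive, required_negative)) > 0) {
    abort("a marker cannot be both required positive and required negative")
  }
  if (!is.null(size_gate)) size_gate <- match.arg(size_gate, c("below", "above"))
  structure(list(label = label,
                 required_positive = required_positive,
                 required_negative = required_negative,
                 required_low = required_low,
                 required_high = required_high,
                 size_gate = size_gate,
                 priority = as.integer(priority)),
            class = "phenotype_rule")
}

#' Panel definition
#'
#' A panel names its markers and carries the ordered gating rules that turn
#' positivity calls into phenotype labels.  Cytokeratin (CK) identifies tumor
#' cells in every panel and always takes priority over immune labels.
#'
#' @param panel_name One of `"myeloid"`, `"tcell"`, `"nk"` or a custom name.
#' @param markers Ordered marker names the panel stains for.
#' @param rules List of [phenotype_rule()] objects with unique labels.
#' @param flag_markers Named character vector mapping flag names (e.g.
#'   `ki67`) to marker names whose positivity sets the flag.
#' @param flag_labels Named list mapping flag names to the phenotype labels
#'   the flag may be set on.
#' @return A `panel_definition` object.
#' @export
panel_definition <- function(panel_name, markers, rules,
                             flag_markers = character(),
                             flag_labels = list()) {
  labels <- vapply(rules, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("rule labels must be unique within a panel")
  rule_markers <- unique(unlist(lapply(rules, function(r) {
    c(r$required_positive, r$required_negative, r$required_low, r$required_high)
  })))
  bad <- setdiff(rule_markers, markers)
  if (length(bad) > 0) {
    abort(paste0("rules reference markers outside the panel: ",
                 paste(bad, collapse = ", ")))
  }
  ord <- order(vapply(rules, `[[`, integer(1), "priority"))
  structure(list(panel_name = panel_name, markers = markers,
                 rules = rules[ord], flag_markers = flag_markers,
                 flag_labels = flag_labels),
            class = "panel_definition")
}

#' Built-in chordoma MIF panels
#'
#' The three validated panels: myeloid (CD11b, CD14, CD15, CD68, HLA-DR, CK),
#' T cell (CD4, CD8, FOXP3, Ki67, PD1, CK) and NK (CD3, CD56, CD16, GzmB,
#' CK).  Phenotype definitions follow the established MDSC-style
#' co-localization criteria: monocytes are CD11b+/CD14+/CD15-/HLA-DR-low,
#' PMN-like cells CD11b+/CD15+/CD14-/HLA-DR-low, pan macrophages are the
#' highly CD68-positive cells; helper T cells CD4+/CD8-/FOXP3-, cytotoxic
#' T cells CD8+/CD4-/FOXP3-, Tregs CD4+/FOXP3+/CD8-; NK cells
#' CD16+/CD56+/CD3- with nuclear area below the specimen size threshold
#' (large CD56+ cells are chordoma-like, not NK).  Ki67 and PD1 positivity
#' are flags on T-cell labels; Granzyme B marks activated NK cells.
#'
#' @param panel_name `"myeloid"`, `"tcell"` or `"nk"`.
#' @return A [panel_definition()].
#' @export
default_panel <- function(panel_name = c("myeloid", "tcell", "nk")) {
  panel_name <- match.arg(panel_name)
  tumor_rule <- phenotype_rule("tumor", required_positive = "CK", priority = 0L)
  switch(panel_name,
    myeloid = panel_definition(
      "myeloid",
      markers = c("CD11b", "CD14", "CD15", "CD68", "HLA-DR", "CK"),
      rules = list(
        tumor_rule,
        phenotype_rule("pan_macrophage", required_high = "CD68", priority = 1L),
        phenotype_rule("monocyte",
                       required_positive = c("CD11b", "CD14"),
                       required_negative = "CD15",
                       required_low = "HLA-DR", priority = 2L),
        phenotype_rule("pmn_like",
                       required_positive = c("CD11b", "CD15"),
                       required_negative = "CD14",
                       required_low = "HLA-DR", priority = 3L))),
    tcell = panel_definition(
      "tcell",
      markers = c("CD4", "CD8", "FOXP3", "Ki67", "PD1", "CK"),
      rules = list(
        tumor_rule,
        phenotype_rule("treg",
                       required_positive = c("CD4", "FOXP3"),
                       required_negative = "CD8", priority = 1L),
        phenotype_rule("cd4_helper",
                       required_positive = "CD4",
                       required_negative = c("CD8", "FOXP3"), priority = 2L),
        phenotype_rule("cd8_cytotoxic",
                       required_positive = "CD8",
                       required_negative = c("CD4", "FOXP3"), priority = 3L)),
      flag_markers = c(ki67 = "Ki67", pd1 = "PD1"),
      flag_labels = list(ki67 = c("cd4_helper", "cd8_cytotoxic", "treg"),
                         pd1 = c("cd4_helper", "cd8_cytotoxic", "treg"))),
    nk = panel_definition(
      "nk",
      markers = c("CD3", "CD56", "CD16", "GzmB", "CK"),
      rules = list(
        tumor_rule,
        phenotype_rule("nk",
                       required_positive = c("CD16", "CD56"),
                       required_negative = "CD3",
                       size_gate = "below", priority = 1L)),
      flag_markers = c(gzmb = "GzmB"),
      flag_labels = list(gzmb = "nk")))
}

#' Phenotype labels a panel can assign (excluding tumor/other)
#' @param panel A [panel_definition()].
#' @return Character vector of immune phenotype labels.
#' @export
panel_phenotypes <- function(panel) {
  setdiff(vapply(panel$rules, `[[`, character(1), "label"), "tumor")
}
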