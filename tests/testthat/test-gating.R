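# Threshold calibration and phenotype assignment.

test_that("two-component calibration splits well-separated populations", {
  set.seed(21)
  # half low, half clearly separated high; planted labels known
  n <- 400
  lab <- rep(c(FALSE, TRUE), each = n / 2)
  x <- ifelse(lab, rlnorm(n, 3.4, 0.4), rlnorm(n, 1.0, 0.4))
  cells <- make_cells(runif(n, 0, 100), runif(n, 0, 100), CD4 = 0)
  cells$CD4 <- x
  sp <- make_specimen(cells, width = 100, height = 100, markers = "CD4")
  panel <- panel_definition("custom", "CD4",
                           list(phenotype_rule("cd4_helper", "CD4")))
  thr <- calibrate_thresholds(sp, panel, method = "two_component")
  cut <- thr$pos_threshold[["CD4"]]
  expect_gt(cut, exp(1.0))
  expect_lt(cut, exp(3.4))

  # oracle: exhaustive scan of candidate cutoffs minimizing misclassification
  cand <- sort(x)
  err <- vapply(cand, function(c0) sum((x > c0) != lab), numeric(1))
  best <- cand[which.min(err)]
  expect_lt(sum((x > cut) != lab), n * 0.01 + min(err) + 3)
  expect_lt(abs(log(cut) - log(best)), 0.5)
})

test_that("manual overrides always win and degenerate markers error", {
  cells <- make_cells(1:4, 1:4, CD4 = c(0, 1, 5, 20), CK = c(0, 1, 2, 30))
  sp <- make_specimen(cells, width = 10, height = 10,
                      markers = c("CD4", "CK"))
  panel <- panel_definition("custom", c("CD4", "CK"),
                           list(phenotype_rule("cd4_helper", "CD4")))
  thr <- calibrate_thresholds(sp, panel, method = "quantile",
                              overrides = list(pos_threshold = c(CD4 = 10)))
  expect_identical(thr$pos_threshold[["CD4"]], 10)
  expect_error(calibrate_thresholds(sp, panel, method = "manual"),
               "override")

  # a constant-intensity marker errors, instructing a manual threshold...
  cells$CK <- 1
  sp_const <- make_specimen(cells, width = 10, height = 10,
                            markers = c("CD4", "CK"))
  expect_error(calibrate_thresholds(sp_const, panel, method = "quantile"),
               "manual")
  # ...and an override resolves it
  thr2 <- calibrate_thresholds(sp_const, panel, method = "quantile",
                               overrides = list(pos_threshold = c(CK = 5)))
  expect_identical(thr2$pos_threshold[["CK"]], 5)
})

test_that("positivity is strict at the cutoff and matches a per-cell oracle", {
  set.seed(22)
  n <- 1000
  cells <- make_cells(runif(n), runif(n),
                      CD4 = 0, CD8 = 0)
  cells$CD4 <- sample(c(0, 5, 10, 20), n, replace = TRUE)
  cells$CD8 <- rlnorm(n)
  sp <- make_specimen(cells, width = 1, height = 1,
                      markers = c("CD4", "CD8"))
  thr <- gating_thresholds("sp1", c(CD4 = 10, CD8 = 1))
  sp <- apply_positivity(sp, thr)
  # boundary value is negative (strict inequality)
  expect_false(any(sp$cells$pos_CD4[sp$cells$CD4 == 10]))
  # brute-force per-cell re-check
  for (m in c("CD4", "CD8")) {
    expect_identical(sp$cells[[paste0("pos_", m)]],
                     vapply(sp$cells[[m]],
                            function(v) v > thr$pos_threshold[[m]],
                            logical(1)))
  }
  # all-zero intensities are all negative
  sp0 <- make_specimen(make_cells(1, 1, CD4 = 0, CD8 = 0),
                       width = 10, height = 10, markers = c("CD4", "CD8"))
  expect_false(any(apply_positivity(sp0, thr)$cells$pos_CD4))
})

make_tcell_specimen <- function(cd4, cd8, foxp3, ck = 0, area = 30) {
  n <- length(cd4)
  cells <- make_cells(seq_len(n), seq_len(n), area = area,
                      CD4 = 0, CD8 = 0, FOXP3 = 0, Ki67 = 0, PD1 = 0, CK = 0)
  cells$CD4 <- cd4; cells$CD8 <- cd8; cells$FOXP3 <- foxp3
  cells$CK <- rep_len(ck, n)
  make_specimen(cells, width = n + 1, height = n + 1,
                markers = c("CD4", "CD8", "FOXP3", "Ki67", "PD1", "CK"))
}

tcell_thresholds <- gating_thresholds(
  "sp1", c(CD4 = 5, CD8 = 5, FOXP3 = 5, Ki67 = 5, PD1 = 5, CK = 5))

test_that("phenotype rules implement the panel co-localization definitions", {
  panel <- default_panel("tcell")
  # CD4+, FOXP3+, CD8- is a Treg
  sp <- make_tcell_specimen(cd4 = 10, cd8 = 0, foxp3 = 10)
  sp <- assign_phenotypes(sp, panel, tcell_thresholds)
  expect_equal(sp$cells$phenotype, "treg")
  # all markers negative falls to other
  sp <- assign_phenotypes(make_tcell_specimen(0, 0, 0), panel,
                          tcell_thresholds)
  expect_equal(sp$cells$phenotype, "other")
  # conflicting lineage markers (CD4+CD8+) fall to other, not either class
  sp <- assign_phenotypes(make_tcell_specimen(10, 10, 0), panel,
                          tcell_thresholds)
  expect_equal(sp$cells$phenotype, "other")
  # CK+ wins over immune labels
  sp <- assign_phenotypes(make_tcell_specimen(10, 0, 10, ck = 10), panel,
                          tcell_thresholds)
  expect_equal(sp$cells$phenotype, "tumor")
})

test_that("NK size gate rejects large CD56+ chordoma-like cells", {
  panel <- default_panel("nk")
  nk_thr <- gating_thresholds("sp1",
                              c(CD3 = 5, CD56 = 5, CD16 = 5, GzmB = 5,
                                CK = 5),
                              size_threshold_um2 = 50)
  mk <- function(area) {
    cells <- make_cells(1, 1, area = area,
                        CD3 = 0, CD56 = 10, CD16 = 10, GzmB = 0, CK = 0)
    make_specimen(cells, width = 10, height = 10,
                  markers = c("CD3", "CD56", "CD16", "GzmB", "CK"))
  }
  small <- assign_phenotypes(mk(30), panel, nk_thr)
  large <- assign_phenotypes(mk(80), panel, nk_thr)
  expect_equal(small$cells$phenotype, "nk")
  expect_equal(large$cells$phenotype, "other")
})

test_that("gating recovers planted labels, partitions cells, is monotone", {
  tr <- generate_specimen(synthetic_preset("inclusion"), 31)
  panel <- default_panel("tcell")
  sp <- gate_specimen(tr$specimen, panel, method = "two_component")
  acc <- mean(sp$cells$phenotype == tr$truth$cells$true_phenotype)
  expect_gte(acc, 0.99)

  # partition: label counts sum to the cell count
  expect_equal(sum(table(sp$cells$phenotype)), n_cells(sp))

  # determinism: identical inputs give identical calls
  sp2 <- gate_specimen(tr$specimen, panel, method = "two_component")
  expect_identical(sp$cells$phenotype, sp2$cells$phenotype)

  # monotonicity: raising a required-positive marker's cutoff never
  # increases the count of phenotypes requiring it
  thr <- sp$thresholds
  n_cd8 <- sum(sp$cells$phenotype == "cd8_cytotoxic")
  for (bump in c(1.5, 3, 10)) {
    thr_up <- thr
    thr_up$pos_threshold["CD8"] <- thr$pos_threshold["CD8"] * bump
    sp_up <- assign_phenotypes(apply_positivity(tr$specimen, thr_up), panel,
                               thr_up)
    expect_lte(sum(sp_up$cells$phenotype == "cd8_cytotoxic"), n_cd8)
    n_cd8 <- sum(sp_up$cells$phenotype == "cd8_cytotoxic")
  }
})

test_that("flags are set only on compatible labels", {
  panel <- default_panel("tcell")
  cells <- make_cells(1:3, 1:3,
                      CD4 = c(10, 0, 0), CD8 = c(0, 10, 0),
                      FOXP3 = 0, Ki67 = c(10, 10, 10), PD1 = 0, CK = c(0, 0, 10))
  sp <- make_specimen(cells, width = 10, height = 10,
                      markers = c("CD4", "CD8", "FOXP3", "Ki67", "PD1", "CK"))
  sp <- assign_phenotypes(sp, panel, tcell_thresholds)
  expect_equal(sp$cells$phenotype, c("cd4_helper", "cd8_cytotoxic", "tumor"))
  # Ki67+ flag on the T cells but never on tumor cells
  expect_identical(sp$cells$flag_ki67, c(TRUE, TRUE, FALSE))
})
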