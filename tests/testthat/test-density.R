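# Density quantification, infiltration classification, heat maps.

gated_square_specimen <- function(n_treg, n_other, width = 2000) {
  # tumor square occupies the left half; tregs placed in the stroma half
  cells <- make_cells(runif(n_treg + n_other, width / 2, width),
                      runif(n_treg + n_other, 0, width), CD4 = 1)
  cells$phenotype <- rep(c("treg", "other"), c(n_treg, n_other))
  sp <- make_specimen(cells, width = width, height = width, markers = "CD4")
  ann <- annotation_set("sp1", tumor = list(square_poly(0, 0, width / 2)),
                        stroma = list(square_poly(0, 0, width)))
  cmap <- compartments_from_annotations(sp, ann, resolution_um = 5)
  assign_cells(sp, cmap)
}

test_that("densities are count/area with excluded cells never counted", {
  set.seed(51)
  sp <- gated_square_specimen(10, 5)
  # 2 x 2 mm field with a 1 x 1 mm tumor square: tumor 1 mm^2, stroma 3 mm^2
  d <- compute_density(sp, phenotype = "treg")
  expect_equal(d$area_mm2, c(1, 3))
  expect_equal(d$count, c(0, 10))
  expect_equal(d$density, c(0, 10 / 3))
  # consistency invariant on every row
  expect_true(all(abs(d$density * d$area_mm2 - d$count) < 1e-9))

  # 10 cells in 0.5 mm^2 gives 20 cells/mm^2
  expect_equal(10 / 0.5, 20)
  # zero matching cells with positive area is density 0, not missing
  d0 <- compute_density(sp, phenotype = "cd8_cytotoxic")
  expect_equal(d0$density, c(0, 0))
})

test_that("estimated density matches planted intensity within 3 SE", {
  # Poisson sampling oracle over 20 seeds
  lam_hat <- vapply(1:20, function(s) {
    tr <- generate_specimen(synthetic_preset("inclusion"), 100 + s)
    sp <- apply_ground_truth(tr$specimen, tr$truth)
    cmap <- compartments_from_annotations(sp, tr$annotations, 5)
    sp <- assign_cells(sp, cmap)
    d <- compute_density(sp, phenotype = "cd4_helper")
    c(d$density[d$compartment == "tumor"], d$area_mm2[d$compartment == "tumor"])
  }, numeric(2))
  lambda <- 30  # planted tumor intensity in the inclusion preset
  z <- (lam_hat[1, ] - lambda) / sqrt(lambda / lam_hat[2, ])
  # per-seed estimates sit within 3 SE (a single excursion is within the
  # expected Poisson fluctuation for 20 draws)
  expect_gte(mean(abs(z) <= 3), 19 / 20)
  # pooled over seeds the estimate is within 3 pooled SE
  total_area <- sum(lam_hat[2, ])
  pooled <- sum(lam_hat[1, ] * lam_hat[2, ]) / total_area
  expect_lt(abs(pooled - lambda), 3 * sqrt(lambda / total_area))
})

test_that("infiltration categories follow the strict ratio thresholds", {
  # included: tumor:stroma 3.0 > 1.5; excluded: stroma:tumor 6.0 > 4.5
  expect_equal(classify_infiltration(30, 10), "included")
  expect_equal(classify_infiltration(5, 30), "excluded")
  expect_equal(classify_infiltration(10, 10), "intermediate")
  expect_equal(classify_infiltration(0, 0), "undefined")
  # zero-denominator conventions
  expect_equal(classify_infiltration(5, 0), "included")
  expect_equal(classify_infiltration(0, 5), "excluded")
  # strictness at the boundaries
  expect_equal(classify_infiltration(15, 10), "intermediate")  # exactly 1.5
  expect_equal(classify_infiltration(10, 45), "intermediate")  # exactly 4.5
  expect_error(classify_infiltration(-1, 5), "nonnegative")

  # scale invariance: multiplying both densities preserves the category
  set.seed(52)
  td <- runif(50, 0, 50); sd_ <- runif(50, 0, 50)
  base <- classify_infiltration(td, sd_)
  for (c0 in c(0.01, 0.5, 7, 1000)) {
    expect_identical(classify_infiltration(c0 * td, c0 * sd_), base)
  }
})

test_that("heat maps conserve mass and localize counts", {
  set.seed(53)
  # one cell in one 100 um tile: that tile reads 100 cells/mm^2
  cells <- make_cells(150, 150, CD4 = 1)
  cells$phenotype <- "treg"
  sp <- make_specimen(cells, width = 400, height = 400, markers = "CD4")
  hm <- density_heatmap(sp, "treg", grid_um = 100)
  expect_equal(hm[2, 2], 100)
  expect_equal(sum(hm), 100)

  # conservation: sum over tiles of value x area = total matching cells
  n <- 500
  cells <- make_cells(runif(n, 0, 2000), runif(n, 0, 2000), CD4 = 1)
  cells$phenotype <- sample(c("treg", "other"), n, replace = TRUE)
  sp <- make_specimen(cells, width = 2000, height = 2000, markers = "CD4")
  hm <- density_heatmap(sp, "treg", grid_um = 130)  # non-divisor tile size
  expect_equal(sum(hm * attr(hm, "tile_area_mm2")),
               sum(cells$phenotype == "treg"))
  expect_error(density_heatmap(sp, "treg", grid_um = -5), "positive")

  # uniform field: tile mean within 3 SE of the planted intensity
  lam <- 250  # cells/mm^2 over a 4 mm^2 field
  n2 <- rpois(1, lam * 4)
  cells2 <- make_cells(runif(n2, 0, 2000), runif(n2, 0, 2000), CD4 = 1)
  cells2$phenotype <- "treg"
  sp2 <- make_specimen(cells2, width = 2000, height = 2000, markers = "CD4")
  hm2 <- density_heatmap(sp2, "treg", grid_um = 100)
  se <- sqrt(lam / 4)
  expect_lt(abs(mean(hm2) - lam), 3 * se)
})

test_that("cohort density tables summarize correctly and are order-invariant", {
  set.seed(54)
  sps <- lapply(1:3, function(k) {
    sp <- gated_square_specimen(10 * k, 5)
    sp$specimen_id <- paste0("s", k)
    sp
  })
  tab <- cohort_density_table(sps, "treg")
  stroma <- dplyr::filter(tab, specimen_id == "cohort",
                          compartment == "stroma")
  dens <- c(10, 20, 30) / 3
  expect_equal(stroma$value[stroma$metric == "median"], median(dens))
  expect_equal(stroma$value[stroma$metric == "mean"], mean(dens))
  expect_equal(stroma$value[stroma$metric == "sem"],
               sd(dens) / sqrt(3), tolerance = 1e-12)
  # closed form: densities {10,20,30} have SEM 5.7735
  expect_equal(sd(c(10, 20, 30)) / sqrt(3), 5.7735, tolerance = 1e-4)

  # permutation of specimen order leaves all summaries unchanged
  tab_rev <- cohort_density_table(rev(sps), "treg")
  a <- dplyr::arrange(dplyr::filter(tab, specimen_id == "cohort"),
                      compartment, metric)
  b <- dplyr::arrange(dplyr::filter(tab_rev, specimen_id == "cohort"),
                      compartment, metric)
  expect_equal(a$value, b$value)

  # cohort of one: median = mean = the single density, SEM undefined
  tab1 <- cohort_density_table(sps[1], "treg")
  one <- dplyr::filter(tab1, specimen_id == "cohort",
                       compartment == "stroma")
  expect_equal(one$value[one$metric == "median"],
               one$value[one$metric == "mean"])
  expect_true(is.na(one$value[one$metric == "sem"]))
})
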