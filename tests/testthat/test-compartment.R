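# Compartment rasterization, CK-density classification, cell assignment.

test_that("aligned squares rasterize to exact areas with precedence", {
  sp <- make_specimen(make_cells(500, 500, CD4 = 1), width = 2000,
                      height = 2000, markers = "CD4")
  ann <- annotation_set("sp1", tumor = list(square_poly(0, 0, 1000)))
  cmap <- compartments_from_annotations(sp, ann, resolution_um = 5)
  expect_equal(cmap$areas_mm2[["tumor"]], 1.0)
  expect_equal(sum(cmap$grid == 1), 200 * 200)

  # exclusion covering half the tumor square takes precedence
  ann2 <- annotation_set("sp1", tumor = list(square_poly(0, 0, 1000)),
                         exclude = list(square_poly(0, 0, 500)))
  cmap2 <- compartments_from_annotations(sp, ann2, resolution_um = 5)
  expect_equal(cmap2$areas_mm2[["tumor"]], 0.75)
  expect_equal(cmap2$areas_mm2[["excluded"]], 0.25)

  # area conservation: all labels partition the raster
  counts <- table(factor(cmap2$grid, levels = 0:3))
  expect_equal(sum(counts), length(cmap2$grid))
})

test_that("rasterized polygon areas match the analytic shoelace area", {
  set.seed(41)
  sp <- make_specimen(make_cells(10, 10, CD4 = 1), width = 2000,
                      height = 2000, markers = "CD4")
  for (k in 1:5) {
    # random convex polygon (convex hull of random points)
    pts <- cbind(runif(12, 200, 1800), runif(12, 200, 1800))
    hull <- pts[grDevices::chull(pts), ]
    ann <- annotation_set("sp1", tumor = list(hull))
    res <- 5
    cmap <- compartments_from_annotations(sp, ann, resolution_um = res)
    exact <- chordomaTIME:::.polygon_area(hull)
    n <- nrow(hull)
    per <- sum(sqrt(rowSums((hull - hull[c(2:n, 1), ])^2)))
    expect_lt(abs(cmap$areas_mm2[["tumor"]] * 1e6 - exact), 2 * res * per)
  }
})

test_that("CK-density compartments contain the tumor disc and recover labels", {
  set.seed(42)
  # CK+ cells inside a central disc, other cells everywhere
  n_ck <- 400
  th <- runif(n_ck, 0, 2 * pi); rr <- 400 * sqrt(runif(n_ck))
  ck_x <- 1000 + rr * cos(th); ck_y <- 1000 + rr * sin(th)
  n_other <- 300
  ox <- runif(n_other, 0, 2000); oy <- runif(n_other, 0, 2000)
  cells <- make_cells(c(ck_x, ox), c(ck_y, oy), CK = 0)
  cells$CK <- c(rep(50, n_ck), rep(0.5, n_other))
  cells$phenotype <- rep(c("tumor", "other"), c(n_ck, n_other))
  sp <- make_specimen(cells, width = 2000, height = 2000, markers = "CK")
  cmap <- compartments_from_ck(sp, bandwidth_um = 50, resolution_um = 10)
  sp <- assign_cells(sp, cmap)
  in_disc <- sqrt((cells$x_um - 1000)^2 + (cells$y_um - 1000)^2) < 350
  # tumor region covers the disc interior (cells well inside the disc)
  expect_gte(mean(sp$cells$compartment[in_disc] == "tumor"), 0.95)
  far <- sqrt((cells$x_um - 1000)^2 + (cells$y_um - 1000)^2) > 550
  expect_gte(mean(sp$cells$compartment[far] != "tumor"), 0.95)

  # zero cells is an error; no CK+ cells falls back to all-stroma + warning
  sp0 <- make_specimen(make_cells(numeric(0), numeric(0), CK = numeric(0)),
                       width = 100, height = 100, markers = "CK")
  sp0$cells$phenotype <- character(0)
  expect_error(compartments_from_ck(sp0), "no cells")
  sp1 <- make_specimen(make_cells(50, 50, CK = 0), width = 100, height = 100,
                       markers = "CK")
  sp1$cells$phenotype <- "other"
  expect_warning(cm1 <- compartments_from_ck(sp1, bandwidth_um = 10,
                                             resolution_um = 5),
                 "all-stroma")
  expect_equal(cm1$areas_mm2[["tumor"]], 0)
  expect_gt(cm1$areas_mm2[["stroma"]], 0)
})

test_that("CK compartments recover planted tumor/stroma on synthetic tissue", {
  tr <- generate_specimen(synthetic_preset("inclusion"), 43)
  sp <- gate_specimen(tr$specimen, default_panel("tcell"),
                      method = "two_component")
  cmap <- compartments_from_ck(sp)
  sp <- assign_cells(sp, cmap)
  agree <- mean(sp$cells$compartment == tr$truth$cells$true_compartment)
  expect_gte(agree, 0.95)
})

test_that("CK compartments are invariant under rigid translation", {
  tr <- generate_specimen(synthetic_preset("inclusion"), 44)
  sp <- gate_specimen(tr$specimen, default_panel("tcell"),
                      method = "two_component")
  res <- 5
  cmap <- compartments_from_ck(sp, resolution_um = res)
  sp_sh <- sp
  # translate by an exact multiple of the raster resolution
  sp_sh$cells$x_um <- sp$cells$x_um + 4 * res
  sp_sh$cells$y_um <- sp$cells$y_um + 4 * res
  sp_sh$field_width_um <- sp$field_width_um + 4 * res
  sp_sh$field_height_um <- sp$field_height_um + 4 * res
  cmap_sh <- compartments_from_ck(sp_sh, resolution_um = res)
  lab <- assign_cells(sp, cmap)$cells$compartment
  lab_sh <- assign_cells(sp_sh, cmap_sh)$cells$compartment
  expect_gte(mean(lab == lab_sh), 0.999)
})

test_that("assign_cells matches direct point-in-polygon away from borders", {
  set.seed(45)
  sp_empty <- make_specimen(make_cells(1, 1, CD4 = 1), width = 2000,
                            height = 2000, markers = "CD4")
  tumor_poly <- square_poly(300, 300, 800)
  ann <- annotation_set("sp1", tumor = list(tumor_poly),
                        stroma = list(square_poly(0, 0, 2000)),
                        exclude = list(square_poly(1500, 1500, 400)))
  res <- 5
  cmap <- compartments_from_annotations(sp_empty, ann, resolution_um = res)

  n <- 1000
  cells <- make_cells(runif(n, 0, 2000), runif(n, 0, 2000), CD4 = 1)
  sp <- make_specimen(cells, width = 2000, height = 2000, markers = "CD4")
  sp <- assign_cells(sp, cmap)
  in_rect <- function(x, y, x0, y0, s) {
    x > x0 & x < x0 + s & y > y0 & y < y0 + s
  }
  expected <- ifelse(in_rect(cells$x_um, cells$y_um, 1500, 1500, 400),
                     "excluded",
                     ifelse(in_rect(cells$x_um, cells$y_um, 300, 300, 800),
                            "tumor", "stroma"))
  # compare only cells farther than one pixel from any boundary
  d_edge <- pmin(
    abs(cells$x_um - 300), abs(cells$x_um - 1100),
    abs(cells$y_um - 300), abs(cells$y_um - 1100),
    abs(cells$x_um - 1500), abs(cells$x_um - 1900),
    abs(cells$y_um - 1500), abs(cells$y_um - 1900))
  keep <- d_edge > res
  expect_identical(sp$cells$compartment[keep], expected[keep])

  # point examples: center of the tumor square; inside the exclusion
  sp_pt <- make_specimen(make_cells(c(700, 1700), c(700, 1700), CD4 = 1),
                         width = 2000, height = 2000, markers = "CD4")
  sp_pt <- assign_cells(sp_pt, cmap)
  expect_identical(sp_pt$cells$compartment, c("tumor", "excluded"))
})
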