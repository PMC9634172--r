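# Nearest-neighbor and proximity statistics against brute-force oracles.

test_that("nearest neighbor handles the elementary geometric cases", {
  src <- make_cells(0, 0)
  tgt <- make_cells(3, 4)
  tgt$cell_id <- "t001"
  nn <- nearest_neighbor(src, tgt)
  expect_equal(nn$mean_nn_distance_um, 5)   # 3-4-5 triangle
  expect_equal(nn$unique_neighbors, 1)

  # same population of two cells at distance d: self excluded, mean = d
  pair <- make_cells(c(0, 7), c(0, 0))
  nn2 <- nearest_neighbor(pair, pair)
  expect_equal(nn2$mean_nn_distance_um, 7)
  expect_equal(nn2$unique_neighbors, 2)

  # empty target is undefined, not zero
  empty <- make_cells(numeric(0), numeric(0))
  expect_true(nearest_neighbor(src, empty)$undefined)
  expect_true(nearest_neighbor(empty, tgt)$undefined)
  expect_equal(nearest_neighbor(empty, tgt)$n_source, 0)
})

test_that("nearest neighbor equals the exhaustive all-pairs scan", {
  set.seed(61)
  src <- random_cells(500, prefix = "s")
  tgt <- random_cells(500, prefix = "t")
  nn <- nearest_neighbor(src, tgt)
  oracle <- nn_oracle(src, tgt)
  expect_identical(nn$mean_nn_distance_um, oracle$mean)
  expect_identical(nn$sd_nn_distance_um, oracle$sd)
  expect_identical(nn$unique_neighbors, oracle$unique_neighbors)

  # same-population case with self-exclusion
  nn_s <- nearest_neighbor(src, src)
  oracle_s <- nn_oracle(src, src, same = TRUE)
  expect_identical(nn_s$mean_nn_distance_um, oracle_s$mean)
  expect_identical(nn_s$unique_neighbors, oracle_s$unique_neighbors)
})

test_that("proximity boundary convention is a closed upper bound", {
  src <- make_cells(0, 0)
  tgt <- make_cells(20, 0)
  pr <- proximity(src, tgt, radius_um = 20, band_width_um = 20)
  # d = 20.0 counts as within, landing in the single (final) band
  expect_equal(pr$fraction_within, 1)
  expect_equal(pr$bands[[1]]$count, 1L)

  # with 1 um bands the boundary case still lands in the last band
  pr2 <- proximity(src, tgt, radius_um = 20, band_width_um = 1)
  expect_equal(pr2$bands[[1]]$count[20], 1L)
  expect_equal(sum(pr2$bands[[1]]$count), pr2$n_within)

  # nothing within range: fraction 0, empty histogram
  far <- make_cells(500, 500)
  pr3 <- proximity(src, far, radius_um = 100, band_width_um = 20)
  expect_equal(pr3$fraction_within, 0)
  expect_equal(sum(pr3$bands[[1]]$count), 0L)

  expect_error(proximity(src, tgt, radius_um = -5), "positive")
  expect_error(proximity(src, tgt, radius_um = 20, band_width_um = 7),
               "evenly")
  expect_true(proximity(src, make_cells(numeric(0), numeric(0)),
                        radius_um = 20)$undefined)
})

test_that("proximity equals the brute-force oracle across radii and bands", {
  set.seed(62)
  src <- random_cells(500, prefix = "s")
  tgt <- random_cells(500, prefix = "t")
  for (radius in c(20, 100)) {
    for (w in c(1, 20)) {
      pr <- proximity(src, tgt, radius_um = radius, band_width_um = w)
      orc <- proximity_oracle(src, tgt, radius, w)
      expect_identical(pr$fraction_within, orc$fraction_within)
      expect_identical(pr$n_within, as.integer(orc$n_within))
      expect_identical(pr$bands[[1]]$count, orc$counts)
      expect_identical(pr$mean_targets_within, orc$mean_targets_within)
    }
  }
})

test_that("spatial statistics are invariant under rigid motions", {
  set.seed(63)
  src <- random_cells(200, prefix = "s")
  tgt <- random_cells(200, prefix = "t")
  rotate <- function(cells, theta, dx, dy) {
    x <- cells$x_um; y <- cells$y_um
    cells$x_um <- cos(theta) * x - sin(theta) * y + dx
    cells$y_um <- sin(theta) * x + cos(theta) * y + dy
    cells
  }
  nn0 <- nearest_neighbor(src, tgt)
  pr0 <- proximity(src, tgt, 100, 20)
  for (theta in c(pi / 7, pi / 2)) {
    nn1 <- nearest_neighbor(rotate(src, theta, 500, 300),
                            rotate(tgt, theta, 500, 300))
    expect_equal(nn1$mean_nn_distance_um, nn0$mean_nn_distance_um,
                 tolerance = 1e-9)
    pr1 <- proximity(rotate(src, theta, 500, 300),
                     rotate(tgt, theta, 500, 300), 100, 20)
    expect_equal(pr1$fraction_within, pr0$fraction_within)
    expect_equal(pr1$bands[[1]]$count, pr0$bands[[1]]$count)
  }
})

test_that("fraction_within is nondecreasing in the radius", {
  set.seed(64)
  src <- random_cells(150, prefix = "s")
  tgt <- random_cells(40, prefix = "t")
  radii <- c(10, 20, 50, 100, 200)
  fr <- vapply(radii, function(r) proximity(src, tgt, r)$fraction_within,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("treg_cd8_contrast pairs percentages and drops unusable specimens", {
  # every treg within 20 um of a nonproliferating CD8, none near
  # proliferating: pair (100, 0)
  cells <- make_cells(c(0, 5, 300), c(0, 0, 0),
                      CD4 = 0, CD8 = 0, FOXP3 = 0, Ki67 = 0, PD1 = 0, CK = 0)
  cells$phenotype <- c("treg", "cd8_cytotoxic", "cd8_cytotoxic")
  cells$flag_ki67 <- c(FALSE, FALSE, TRUE)
  cells$flag_pd1 <- FALSE
  sp <- make_specimen(cells, width = 400, height = 400,
                      markers = c("CD4", "CD8", "FOXP3", "Ki67", "PD1", "CK"))
  sp2 <- sp; sp2$specimen_id <- "sp2"
  ct <- treg_cd8_contrast(list(sp, sp2))
  expect_equal(ct$pairs$pct_near_nonproliferating, c(100, 100))
  expect_equal(ct$pairs$pct_near_proliferating, c(0, 0))
  expect_equal(ct$n_dropped, 0)
  expect_s3_class(ct$test, "test_result")

  # specimens without tregs are dropped and the analysis degrades gracefully
  sp3 <- sp
  sp3$cells$phenotype <- c("other", "cd8_cytotoxic", "cd8_cytotoxic")
  ct2 <- treg_cd8_contrast(list(sp, sp3))
  expect_equal(ct2$n_dropped, 1)
  expect_null(ct2$test)  # fewer than 2 usable pairs
  ct3 <- treg_cd8_contrast(list(sp3))
  expect_equal(nrow(ct3$pairs), 0)
})

test_that("spatial_summary scales with coordinates as expected", {
  set.seed(65)
  cells <- random_cells(120)
  cells$phenotype <- sample(c("treg", "tumor"), 120, replace = TRUE)
  cells$CD4 <- 1
  sp <- make_specimen(cells, width = 1000, height = 1000, markers = "CD4")
  pairs <- tibble::tibble(source = "treg", target = "tumor")
  tab <- spatial_summary(list(sp), pairs, radius_um = 100)
  row <- dplyr::filter(tab, specimen_id == "sp1",
                       metric == "mean_nn_distance_um")
  # matches nearest_neighbor directly
  nn <- nearest_neighbor(phenotype_cells(sp, "treg"),
                         phenotype_cells(sp, "tumor"))
  expect_equal(row$value, nn$mean_nn_distance_um)

  # doubling coordinates doubles mean distance and cannot raise fractions
  sp2 <- sp
  sp2$cells$x_um <- sp$cells$x_um * 2
  sp2$cells$y_um <- sp$cells$y_um * 2
  sp2$field_width_um <- 2000; sp2$field_height_um <- 2000
  tab2 <- spatial_summary(list(sp2), pairs, radius_um = 100)
  row2 <- dplyr::filter(tab2, specimen_id == "sp1",
                        metric == "mean_nn_distance_um")
  expect_equal(row2$value, 2 * row$value, tolerance = 1e-12)
  f1 <- dplyr::filter(tab, specimen_id == "sp1", metric == "pct_within")$value
  f2 <- dplyr::filter(tab2, specimen_id == "sp1", metric == "pct_within")$value
  expect_lte(f2, f1)
})
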