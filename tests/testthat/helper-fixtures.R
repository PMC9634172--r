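# Shared fixtures and independent brute-force oracles for the test suite.

# Minimal cell tibble; marker columns appended from `...` (name = vector).
make_cells <- function(x, y, area = 30, ...) {
  n <- length(x)
  cells <- tibble::tibble(cell_id = sprintf("c%03d", seq_len(n)),
                          x_um = x, y_um = y,
                          nuclear_area_um2 = rep_len(area, n))
  extra <- list(...)
  for (nm in names(extra)) cells[[nm]] <- rep_len(extra[[nm]], n)
  cells
}

make_specimen <- function(cells, id = "sp1", width = NULL, height = NULL,
                          markers = NULL) {
  specimen_table(cells, id, field_width_um = width, field_height_um = height,
                 markers = markers)
}

square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# ---- spatial oracles: exhaustive all-pairs scans -------------------------

# Full distance matrix between two point sets.
pairwise_dist <- function(sx, sy, tx, ty) {
  sqrt(outer(sx, tx, `-`)^2 + outer(sy, ty, `-`)^2)
}

# Nearest-neighbor oracle; ties toward the lowest target cell_id.
nn_oracle <- function(src, tgt, same = FALSE) {
  D <- pairwise_dist(src$x_um, src$y_um, tgt$x_um, tgt$y_um)
  if (same) D[cbind(seq_len(nrow(src)), match(src$cell_id, tgt$cell_id))] <- Inf
  dists <- numeric(nrow(src))
  nn_id <- character(nrow(src))
  for (i in seq_len(nrow(src))) {
    d <- min(D[i, ])
    cand <- tgt$cell_id[which(D[i, ] == d)]
    dists[i] <- d
    nn_id[i] <- sort(cand)[1]
  }
  list(dist = dists, nn_id = nn_id,
       mean = mean(dists), sd = stats::sd(dists),
       unique_neighbors = length(unique(nn_id)))
}

# Proximity oracle: nearest-target distances, closed upper bound at radius,
# half-open bands with the boundary case in the final band.
proximity_oracle <- function(src, tgt, radius, width, same = FALSE) {
  d <- nn_oracle(src, tgt, same)$dist
  nb <- as.integer(round(radius / width))
  within <- d <= radius
  k <- pmin(floor(d / width), nb - 1)
  counts <- tabulate(k[within] + 1, nbins = nb)
  D <- pairwise_dist(src$x_um, src$y_um, tgt$x_um, tgt$y_um)
  if (same) D[cbind(seq_len(nrow(src)), match(src$cell_id, tgt$cell_id))] <- Inf
  list(fraction_within = mean(within), n_within = sum(within),
       counts = counts, mean_targets_within = mean(rowSums(D <= radius)))
}

random_cells <- function(n, width = 1000, height = 1000, prefix = "r") {
  make_cells(stats::runif(n, 0, width), stats::runif(n, 0, height)) |>
    dplyr::mutate(cell_id = sprintf("%s%04d", prefix, sample(seq_len(n))))
}

# ---- statistics oracles ---------------------------------------------------

# Wilcoxon signed-rank: full 2^n enumeration of sign assignments.
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_le <- mean(Ws <= W + 1e-12)
  p_ge <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Mann-Whitney: enumeration of all C(n, na) rank splits.
mw_enum_oracle <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  Wa <- sum(r[seq_len(na)])
  splits <- utils::combn(length(r), na)
  Ws <- apply(splits, 2, function(idx) sum(r[idx]))
  p_le <- mean(Ws <= Wa + 1e-12)
  p_ge <- mean(Ws >= Wa - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Two-way ANOVA oracle for balanced designs: explicit projection onto the
# factor-effect subspaces (Type II == Type I == Type III when balanced).
anova_projection_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  n <- length(y)
  gm <- mean(y)
  mA <- tapply(y, A, mean)[A]
  mB <- tapply(y, B, mean)[B]
  mAB <- tapply(y, interaction(A, B), mean)[interaction(A, B)]
  ss_a <- sum((mA - gm)^2)
  ss_b <- sum((mB - gm)^2)
  ss_ab <- sum((mAB - mA - mB + gm)^2)
  ss_res <- sum((y - mAB)^2)
  df_a <- nlevels(A) - 1
  df_b <- nlevels(B) - 1
  df_ab <- df_a * df_b
  df_res <- n - nlevels(A) * nlevels(B)
  list(F_a = (ss_a / df_a) / (ss_res / df_res),
       F_b = (ss_b / df_b) / (ss_res / df_res),
       F_ab = (ss_ab / df_ab) / (ss_res / df_res))
}

# Lean spatial-null configuration: only CD8 and Treg populations on a 1x1 mm
# field, used with ground-truth labels for spatial calibration runs.  The
# Ki67 rate on CD8 cells is 0.5 so the proliferating and nonproliferating
# classes are exchangeable: with the attraction kernel off, the paired
# percentages then share a distribution and the signed-rank null holds.
lean_treg_config <- function(attraction = NULL) {
  row <- function(phenotype, lt, ls, pos, size = "immune") {
    tibble::tibble(phenotype = phenotype, lambda_tumor = lt,
                   lambda_stroma = ls, pos_markers = list(pos), size = size)
  }
  synthetic_config(
    "tcell", field_width_um = 1000, field_height_um = 1000, n_lobules = 2,
    lobule_radius_um = c(100, 200),
    phenotypes = dplyr::bind_rows(
      row("cd8_cytotoxic", 25, 40, "CD8"),
      row("treg", 15, 25, c("CD4", "FOXP3"))),
    flag_probs = list(ki67 = c(cd8_cytotoxic = 0.5, treg = 0.02)),
    attraction = attraction)
}
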