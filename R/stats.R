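#' Hypothesis-test result container
#'
#' @param test_name Short method name.
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value in \[0, 1\], or `NA` when undefined.
#' @param n_effective Observations actually used.
#' @param method_detail `"exact"` or `"normal_approximation"`.
#' @param comparison Label of the comparison.
#' @return A one-row `test_result` tibble.
#' @export
test_result <- function(test_name, statistic, p_value, n_effective,
                        method_detail, comparison = "") {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    abort("p_value outside [0, 1]")
  }
  structure(tibble(test_name = test_name, statistic = statistic,
                   p_value = p_value, n_effective = n_effective,
                   method_detail = method_detail, comparison = comparison),
            class = c("test_result", class(tibble())))
}

# Distribution of the positive-rank sum W+ under the signed-rank null, as a
# probability vector over 2*W+ = 0 .. sum(2r).  Ranks may be half-integers
# under ties, so everything is done on doubled ranks (integers).
.signed_rank_null <- function(ranks2) {
  f <- 1
  for (r in ranks2) {
    g <- c(f, numeric(r))
    g[(r + 1):(r + length(f))] <- g[(r + 1):(r + length(f))] + f
    f <- g
  }
  f / sum(f)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided.  Zero differences are dropped (standard practice), so
#' `n_effective` is the number of nonzero differences.  For
#' `n_effective <= exact_cutoff` the null distribution of the positive-rank
#' sum is enumerated exactly by dynamic programming over the 2^n sign
#' assignments (valid under ties, where the distribution conditions on the
#' observed ranks); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exact_cutoff Largest `n_effective` for exact enumeration.
#' @param comparison Label carried into the result.
#' @return A [test_result()]; `p_value = NA` with `method_detail`
#'   `"undefined"` when every difference is zero.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_cutoff = 25, comparison = "") {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  if (length(a) < 1) abort("need at least one pair")
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(test_result("wilcoxon_signed_rank", NA_real_, NA_real_, 0L,
                       "undefined", comparison))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_cutoff) {
    r2 <- as.integer(round(2 * r))
    null <- .signed_rank_null(r2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(test_result("wilcoxon_signed_rank", W, p, n, "exact", comparison))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  test_result("wilcoxon_signed_rank", W, p, n, "normal_approximation",
              comparison)
}

# Null distribution of the doubled rank sum of group A under the
# Mann-Whitney permutation null: choose na of the N observed (doubled)
# ranks.  Returns a probability vector over 2*Wa = 0 .. sum(ranks2).
.rank_sum_null <- function(ranks2, na) {
  total <- sum(ranks2)
  g <- matrix(0, na + 1L, total + 1L)
  g[1L, 1L] <- 1
  for (r in ranks2) {
    for (k in na:1) {
      # shift row k-1 by r and add into row k
      src <- g[k, ]
      if (!any(src != 0)) next
      g[k + 1L, (r + 1L):(total + 1L)] <-
        g[k + 1L, (r + 1L):(total + 1L)] + src[1L:(total + 1L - r)]
    }
  }
  g[na + 1L, ] / sum(g[na + 1L, ])
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided.  Exact permutation enumeration (dynamic programming over rank
#' splits, valid under ties) when `length(a) * length(b) <= exact_product`;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric samples.
#' @param exact_product Switch to the approximation above this product.
#' @param comparison Label carried into the result.
#' @return A [test_result()] whose statistic is U for sample `a` (ties
#'   counted 1/2).
#' @export
mann_whitney_u <- function(a, b, exact_product = 400, comparison = "") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) abort("both samples must be nonempty")
  r <- rank(c(a, b))
  Wa <- sum(r[seq_len(na)])
  U <- Wa - na * (na + 1) / 2
  if (na * nb <= exact_product) {
    r2 <- as.integer(round(2 * r))
    null <- .rank_sum_null(r2, na)
    w2 <- as.integer(round(2 * Wa))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(test_result("mann_whitney_u", U, p, na + nb, "exact", comparison))
  }
  N <- na + nb
  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  test_result("mann_whitney_u", U, p, N, "normal_approximation", comparison)
}

#' Two-way fixed-effects ANOVA
#'
#' Standard decomposition for densities against two crossed factors (e.g.
#' anatomic site and cell type).  Unbalanced designs use Type II sums of
#' squares, which answer main-effect questions robustly when group sizes
#' differ.  Degenerate fits with zero residual variance report `F = 0`,
#' `p = 1` for effects with zero sum of squares.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (>= 2 levels each after dropping
#'   missing values).
#' @param labels Names for the two factors in the output.
#' @return Tibble of [test_result()] rows for both main effects and the
#'   interaction, with columns `df` and `sum_sq` added.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          labels = c("factor_a", "factor_b")) {
  keep <- complete.cases(values, factor_a, factor_b)
  df <- data.frame(y = values[keep],
                   A = droplevels(factor(factor_a[keep])),
                   B = droplevels(factor(factor_b[keep])))
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    abort("both factors need at least two levels")
  }
  fit <- lm(y ~ A * B, data = df)
  tab <- tryCatch(car::Anova(fit, type = 2, singular.ok = TRUE),
                  error = function(e) {
                    # zero residual variance (e.g. constant response):
                    # fall back to the sequential table, whose zero sums of
                    # squares are mapped to F = 0, p = 1 below
                    suppressWarnings(stats::anova(fit))
                  })
  total_ss <- sum((df$y - mean(df$y))^2)
  effects <- c("A", "B", "A:B")
  eff_labels <- c(labels[1], labels[2],
                  paste(labels[1], labels[2], sep = ":"))
  out <- purrr::map_dfr(seq_along(effects), function(k) {
    row <- tab[effects[k], ]
    ss <- row[["Sum Sq"]]
    Fv <- row[["F value"]]
    p <- row[["Pr(>F)"]]
    if (!is.na(ss) && ss <= 1e-12 * max(1, total_ss)) { Fv <- 0; p <- 1 }
    res <- test_result("two_way_anova", Fv, p, nrow(df), "F_test",
                       eff_labels[k])
    res$df <- row[["Df"]]
    res$sum_sq <- ss
    res
  })
  out
}

#' Significance markers at the conventional thresholds
#'
#' @param p Numeric p-values.
#' @return `"****"` for p <= 1e-4, `"***"` <= 1e-3, `"**"` <= 0.01,
#'   `"*"` <= 0.05, else `"ns"`.
#' @export
significance_marker <- function(p) {
  cut_points <- c(1e-4, 1e-3, 1e-2, 0.05)
  marks <- c("****", "***", "**", "*")
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    i <- which(pp <= cut_points)
    if (length(i) > 0) marks[i[1]] else "ns"
  }, character(1))
}

#' Cohort-level comparisons of immune densities
#'
#' Dispatches the standard TIME-study battery of tests on a cohort density
#' table:
#' \describe{
#'   \item{compartment-paired}{per phenotype, paired Wilcoxon signed-rank of
#'     tumor vs stroma densities across specimens.}
#'   \item{site}{two-way ANOVA of density against anatomic site x cell type.}
#'   \item{stage (or any 2-group metadata)}{per phenotype, Mann-Whitney
#'     between the groups (tumor-compartment densities).}
#' }
#' All p-values are reported raw; `correct = "BH"` optionally adds a
#' Benjamini-Hochberg adjusted column (off by default to mirror per-test
#' reporting).
#'
#' @param density_table A [cohort_density_table()] result (per-specimen rows
#'   are used).
#' @param grouping `"compartment-paired"`, `"site"` or `"stage"`.
#' @param metadata Tibble with `specimen_id` plus a `site` or `stage`
#'   column, required for those groupings; specimens without metadata are
#'   dropped with a `n_dropped` attribute.
#' @param correct `"none"` (default) or `"BH"`.
#' @return Tibble of test rows; attribute `n_dropped` counts specimens
#'   without metadata.
#' @export
cohort_compare <- function(density_table,
                           grouping = c("compartment-paired", "site",
                                        "stage"),
                           metadata = NULL, correct = c("none", "BH")) {
  grouping <- match.arg(grouping)
  correct <- match.arg(correct)
  df <- as_tibble(density_table) |>
    filter(.data$metric == "density", .data$specimen_id != "cohort",
           .data$flag_filter == "none")
  n_dropped <- 0L
  out <- if (grouping == "compartment-paired") {
    wide <- df |>
      tidyr::pivot_wider(id_cols = all_of(c("specimen_id", "phenotype")),
                         names_from = "compartment",
                         values_from = "value")
    purrr::map_dfr(unique(wide$phenotype), function(ph) {
      sub <- wide[wide$phenotype == ph &
                    complete.cases(wide$tumor, wide$stroma), ]
      res <- wilcoxon_signed_rank(sub$tumor, sub$stroma,
                                  comparison = paste0(ph, ": tumor vs stroma"))
      res$phenotype <- ph
      res
    })
  } else {
    if (is.null(metadata)) abort("metadata required for this grouping")
    col <- if (grouping == "site") "site" else "stage"
    if (!col %in% names(metadata)) {
      abort(sprintf("metadata lacks a '%s' column", col))
    }
    dft <- df |> filter(.data$compartment == "tumor")
    merged <- left_join(dft, metadata, by = "specimen_id")
    n_dropped <- length(unique(merged$specimen_id[is.na(merged[[col]])]))
    merged <- merged[!is.na(merged[[col]]) & !is.na(merged$value), ]
    if (grouping == "site") {
      two_way_anova(merged$value, merged[[col]], merged$phenotype,
                    labels = c("site", "cell_type"))
    } else {
      lv <- unique(merged[[col]])
      if (length(lv) != 2) abort("stage grouping needs exactly two groups")
      purrr::map_dfr(unique(merged$phenotype), function(ph) {
        sub <- merged[merged$phenotype == ph, ]
        res <- mann_whitney_u(sub$value[sub[[col]] == lv[1]],
                              sub$value[sub[[col]] == lv[2]],
                              comparison = paste0(ph, ": ", lv[1], " vs ",
                                                  lv[2]))
        res$phenotype <- ph
        res
      })
    }
  }
  if (correct == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out$significance <- significance_marker(out$p_value)
  attr(out, "n_dropped") <- n_dropped
  out
}
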