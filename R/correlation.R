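# Diversity vs ecosystem-service correlation per realm: simple linear
# correlation of per-cell TD/FD/PD against a gridded nutrient-retention
# surface, reported with both Pearson and Spearman statistics and
# Shapiro-Wilk normality gates, regions ranked by r-squared.

#' Correlate diversity with a nutrient surface per region
#'
#' For every (region, metric) pair: Pearson r, r-squared and two-sided p,
#' Spearman's rho, and Shapiro-Wilk p for both variables. Cells with missing
#' nutrient values are dropped pairwise; a constant metric or nutrient in a
#' region yields `NA` statistics. The result is ordered by r-squared within
#' metric (strongest region first).
#'
#' @param cell_table a `croc_diversity` table.
#' @param nutrient_values named per-cell nutrient values (names = cell ids).
#' @param region_assignment named character vector mapping cell ids to
#'   regions.
#' @param metrics which diversity columns to use.
#' @return data.frame `region, metric, n_cells, pearson_r, r_squared,
#'   p_value, spearman_rho, shapiro_p_x, shapiro_p_y`.
#' @export
region_correlation <- function(cell_table, nutrient_values, region_assignment,
                               metrics = c("TD", "FD", "PD")) {
  ids <- as.character(cell_table$cell_id)
  regions <- region_assignment[ids]
  rows <- list()
  for (rg in sort(unique(stats::na.omit(regions)))) {
    sel <- !is.na(regions) & regions == rg
    for (met in metrics) {
      x <- cell_table[[met]][sel]
      y <- nutrient_values[ids[sel]]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3L) stop("region '", rg, "' has fewer than 3 usable cells")
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, metric = met, n_cells = length(x),
          pearson_r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
          spearman_rho = NA_real_, shapiro_p_x = shapiro_p(x),
          shapiro_p_y = shapiro_p(y), stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      r <- unname(ct$estimate)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, metric = met, n_cells = length(x),
        pearson_r = r, r_squared = r^2, p_value = ct$p.value,
        spearman_rho = stats::cor(x, y, method = "spearman"),
        shapiro_p_x = shapiro_p(x), shapiro_p_y = shapiro_p(y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$metric, -ifelse(is.na(out$r_squared), -Inf, out$r_squared)), ]
}
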