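# Threshold-based conservation prioritization. Three nested models combine
# per-cell diversity cutoffs with the presence of threatened species:
#   Model 1 (very high priority): FD, PD, TD each above the 90%-of-mean
#     threshold and at least one Critically Endangered species present;
#   Model 2 (high): 70% thresholds and an Endangered species, minus Model 1;
#   Model 3 (medium): 50% thresholds and a Vulnerable species, minus the
#     cells already assigned.
# In the published equations each threshold f*mean(X) is additionally divided
# by a per-level divisor (0.5 almost everywhere; 0.7 for the FD term of
# Model 2; 1.0 at level 3), which makes the level-1 cutoff 1.8x the mean —
# `mode = "as_printed"` reproduces those equations literally, while
# `mode = "normalized"` reads the thresholds as f-quantiles of the nonzero
# per-cell distribution instead.

#' Prioritization configuration
#'
#' @param levels ordered list of `(f, status)` pairs, highest priority first.
#' @param divisors 3 x 3 numeric matrix (levels x metrics FD, PD, TD) of
#'   published per-term divisors.
#' @param mode `"as_printed"` (literal equations, default) or `"normalized"`
#'   (quantile thresholds).
#' @param cumulative_exclusion subtract all higher levels from each level
#'   (default `TRUE`); `FALSE` subtracts only the immediately higher level,
#'   the literal set-difference reading.
#' @return a `croc_priority_config` list.
#' @export
priority_config <- function(levels = list(list(f = 0.9, status = "CR"),
                                          list(f = 0.7, status = "EN"),
                                          list(f = 0.5, status = "VU")),
                            divisors = rbind(c(0.5, 0.5, 0.5),
                                             c(0.7, 0.5, 0.5),
                                             c(1.0, 1.0, 1.0)),
                            mode = c("as_printed", "normalized"),
                            cumulative_exclusion = TRUE) {
  mode <- match.arg(mode)
  f <- vapply(levels, function(l) l$f, 0)
  if (is.unsorted(rev(f), strictly = TRUE)) stop("level fractions must descend")
  if (any(divisors <= 0)) stop("divisors must be positive")
  colnames(divisors) <- c("FD", "PD", "TD")
  structure(list(levels = levels, divisors = divisors, mode = mode,
                 cumulative_exclusion = cumulative_exclusion),
            class = "croc_priority_config")
}

#' Per-metric thresholds for one priority level
#'
#' `as_printed`: `thr_X = f * (sum(X) / N) / divisor(level, X)` with N the
#' number of cells in the table. `normalized`: the f-quantile of the nonzero
#' per-cell values of X.
#'
#' @param cell_table a `croc_diversity` table.
#' @param config a [priority_config()].
#' @param level level index (1, 2 or 3).
#' @return named vector `c(FD =, PD =, TD =)`.
#' @export
thresholds <- function(cell_table, config, level) {
  if (nrow(cell_table) == 0L) stop("empty diversity table")
  f <- config$levels[[level]]$f
  vapply(c("FD", "PD", "TD"), function(met) {
    x <- cell_table[[met]]
    if (config$mode == "as_printed") {
      f * mean(x) / config$divisors[level, met]
    } else {
      stats::quantile(x[x > 0], probs = f, names = FALSE, type = 7)
    }
  }, 0)
}

#' Per-cell threatened-status presence flags
#'
#' @param presence binary cells x species matrix.
#' @param status data.frame `species_id, iucn_category`.
#' @return logical matrix (cells x `has_CR, has_EN, has_VU`).
#' @export
status_presence <- function(presence, status) {
  status_of <- stats::setNames(status$iucn_category, status$species_id)
  out <- sapply(c("CR", "EN", "VU"), function(cat) {
    sp <- names(status_of)[status_of == cat]
    sp <- intersect(sp, colnames(presence))
    if (length(sp) == 0L) rep(FALSE, nrow(presence))
    else rowSums(presence[, sp, drop = FALSE]) > 0
  })
  rownames(out) <- rownames(presence)
  colnames(out) <- c("has_CR", "has_EN", "has_VU")
  out
}

#' Assign cells to priority levels
#'
#' A cell enters level k when its FD, PD and TD all reach the level-k
#' thresholds and a species of the level's gating category (CR, EN or VU) is
#' present; cells already assigned to a higher level are excluded (see
#' [priority_config()] for the literal-subtraction variant).
#'
#' @param cell_table a `croc_diversity` table.
#' @param presence binary cells x species matrix (same cells).
#' @param status data.frame `species_id, iucn_category`.
#' @param config a [priority_config()].
#' @return data.frame of class `croc_priority`: `cell_id,
#'   level` with level in `"1", "2", "3", "none"`.
#' @export
prioritize <- function(cell_table, presence, status,
                       config = priority_config()) {
  stopifnot(nrow(cell_table) == nrow(presence))
  sp_flags <- status_presence(presence, status)
  gate_col <- c(CR = "has_CR", EN = "has_EN", VU = "has_VU")
  level <- rep("none", nrow(cell_table))
  assigned <- rep(FALSE, nrow(cell_table))
  prev <- rep(FALSE, nrow(cell_table))
  for (k in seq_along(config$levels)) {
    thr <- thresholds(cell_table, config, k)
    gate <- sp_flags[, gate_col[[config$levels[[k]]$status]]]
    cand <- cell_table$FD >= thr[["FD"]] & cell_table$PD >= thr[["PD"]] &
      cell_table$TD >= thr[["TD"]] & gate
    excl <- if (config$cumulative_exclusion) assigned else prev
    sel <- cand & !excl
    # the map keeps the highest (first-assigned) level even under the
    # literal subtraction rule, where level sets may overlap
    level[sel & !assigned] <- as.character(k)
    prev <- sel
    assigned <- assigned | sel
  }
  out <- data.frame(cell_id = cell_table$cell_id, level = level,
                    stringsAsFactors = FALSE)
  class(out) <- c("croc_priority", "data.frame")
  out
}

#' Priority area per region
#'
#' Sums the spherical area of priority cells of the requested levels within
#' each region polygon (e.g. countries), with the relative percentage of the
#' region occupied. A region's total area is measured as the part of the
#' masked grid it covers, so a fully prioritized region scores exactly 100.
#'
#' @param priority_map a `croc_priority` table.
#' @param grid the `croc_grid` the cells belong to.
#' @param region_polygons named list of `croc_geom` regions.
#' @param levels which priority levels to count (default `"1"`).
#' @return data.frame `region, area_km2, relative_pct`, regions without
#'   priority area omitted; zero-area regions dropped with a warning.
#' @export
area_by_region <- function(priority_map, grid, region_polygons,
                           levels = "1") {
  pr_cells <- priority_map$cell_id[priority_map$level %in% levels]
  rows <- lapply(names(region_polygons), function(rg) {
    geom <- region_polygons[[rg]]
    ids <- intersect(cells_touched(grid, geom), grid$mask)
    if (length(ids) == 0L) {
      warning("region '", rg, "' covers no grid area; dropped")
      return(NULL)
    }
    cell_region_area <- function(cid) {
      rect <- cell_bounds(grid, cid)[1L, ]
      rings <- clip_geom_rect_rings(geom, rect)
      if (length(rings) == 0L) 0 else units_union_area_km2(list(rings))
    }
    total <- sum(vapply(ids, cell_region_area, 0))
    pid <- intersect(ids, pr_cells)
    if (length(pid) == 0L) return(NULL)
    a <- sum(vapply(pid, cell_region_area, 0))
    data.frame(region = rg, area_km2 = a,
               relative_pct = 100 * a / total, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(region = character(0), area_km2 = numeric(0),
                      relative_pct = numeric(0)))
  do.call(rbind, rows)
}
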