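# Analysis grid: regular lon/lat lattice with half-open cells
# [west, east) x [south, north), row-major 0-based cell ids with row 0 the
# southernmost band. A grid carries an optional region mask (the retained
# cell ids); every downstream statistic runs over the masked cells only.

#' Build a regular geographic analysis grid
#'
#' Constructs a lon/lat grid at the requested resolution (default 0.5
#' degrees), snapping the extent outward to whole cells. If mask polygons are
#' supplied, the region mask keeps only cells whose interior intersects their
#' union; otherwise all cells are retained.
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in degrees.
#' @param resolution cell edge in degrees (> 0).
#' @param mask_polygons optional list of [croc_geom] objects.
#' @return an object of class `croc_grid` with fields `origin`, `resolution`,
#'   `n_cols`, `n_rows`, `mask` (sorted 0-based cell ids).
#' @export
build_grid <- function(extent, resolution = 0.5, mask_polygons = NULL) {
  stopifnot(length(extent) == 4L, resolution > 0)
  xmin <- extent[1L]; ymin <- extent[2L]; xmax <- extent[3L]; ymax <- extent[4L]
  stopifnot(xmax > xmin, ymax > ymin)
  snap <- function(v, up) {
    k <- v / resolution
    r <- if (up) ceiling(k - 1e-9) else floor(k + 1e-9)
    r * resolution
  }
  x0 <- snap(xmin, FALSE); y0 <- snap(ymin, FALSE)
  x1 <- snap(xmax, TRUE);  y1 <- snap(ymax, TRUE)
  n_cols <- as.integer(round((x1 - x0) / resolution))
  n_rows <- as.integer(round((y1 - y0) / resolution))
  g <- structure(list(origin = c(x0, y0), resolution = resolution,
                      n_cols = n_cols, n_rows = n_rows,
                      mask = seq_len(n_cols * n_rows) - 1L),
                 class = "croc_grid")
  if (!is.null(mask_polygons)) {
    if (inherits(mask_polygons, "croc_geom")) mask_polygons <- list(mask_polygons)
    ids <- integer(0)
    for (mp in mask_polygons) ids <- c(ids, cells_touched(g, mp))
    ids <- sort(unique(ids))
    if (length(ids) == 0L) stop("mask polygons intersect no grid cell")
    g$mask <- ids
  }
  g
}

#' @export
print.croc_grid <- function(x, ...) {
  cat(sprintf("<croc_grid: %d x %d cells at %g deg, origin (%g, %g), %d masked>\n",
              x$n_cols, x$n_rows, x$resolution, x$origin[1L], x$origin[2L],
              length(x$mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Bounds of grid cells
#'
#' @param grid a `croc_grid`.
#' @param cell_id integer vector of 0-based cell ids.
#' @return matrix with columns `xmin, ymin, xmax, ymax` (degrees).
#' @export
cell_bounds <- function(grid, cell_id) {
  row <- cell_id %/% grid$n_cols
  col <- cell_id %% grid$n_cols
  xmin <- grid$origin[1L] + col * grid$resolution
  ymin <- grid$origin[2L] + row * grid$resolution
  cbind(xmin = xmin, ymin = ymin,
        xmax = xmin + grid$resolution, ymax = ymin + grid$resolution)
}

#' Centers of grid cells
#' @inheritParams cell_bounds
#' @return matrix with columns `lon, lat`.
#' @export
cell_centers <- function(grid, cell_id = grid$mask) {
  b <- cell_bounds(grid, cell_id)
  cbind(lon = (b[, 1L] + b[, 3L]) / 2, lat = (b[, 2L] + b[, 4L]) / 2)
}

#' Locate points on the grid
#'
#' Half-open cell intervals `[west, east) x [south, north)` mean a boundary
#' point belongs to exactly one cell.
#'
#' @param grid a `croc_grid`.
#' @param x,y coordinates in degrees.
#' @return 0-based cell ids (`NA` outside the grid extent).
#' @export
cell_from_point <- function(grid, x, y) {
  col <- floor((x - grid$origin[1L]) / grid$resolution)
  row <- floor((y - grid$origin[2L]) / grid$resolution)
  id <- as.integer(row * grid$n_cols + col)
  id[col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows] <- NA_integer_
  id
}

# candidate cell ids whose rectangle intersects bbox (open interior test later)
cells_in_bbox <- function(grid, bbox) {
  # open-interval logic: a bbox edge lying exactly on a cell boundary does
  # not pull in the neighboring cell it merely touches
  c0 <- max(0L, floor((bbox[1L] - grid$origin[1L]) / grid$resolution + 1e-9))
  c1 <- min(grid$n_cols - 1L, floor((bbox[3L] - grid$origin[1L]) / grid$resolution - 1e-9))
  r0 <- max(0L, floor((bbox[2L] - grid$origin[2L]) / grid$resolution + 1e-9))
  r1 <- min(grid$n_rows - 1L, floor((bbox[4L] - grid$origin[2L]) / grid$resolution - 1e-9))
  if (c1 < c0 || r1 < r0) return(integer(0))
  as.integer(outer(seq.int(r0, r1) * grid$n_cols, seq.int(c0, c1), "+"))
}

# cells whose interior intersects geometry g (positive clipped area)
cells_touched <- function(grid, g, min_frac = 0) {
  cand <- integer(0)
  for (ring in geom_rings(g)) {
    bb <- c(min(ring[, 1L]), min(ring[, 2L]), max(ring[, 1L]), max(ring[, 2L]))
    cand <- c(cand, cells_in_bbox(grid, bb))
  }
  cand <- sort(unique(cand))
  if (length(cand) == 0L) return(integer(0))
  keep <- logical(length(cand))
  areas <- cell_area_km2(grid, cand)
  for (i in seq_along(cand)) {
    rect <- cell_bounds(grid, cand[i])[1L, ]
    rings <- clip_geom_rect_rings(g, rect)
    if (length(rings) == 0L) next
    a <- units_union_area_km2(list(rings))
    keep[i] <- if (min_frac > 0) (a / areas[i] >= min_frac - 1e-12) else (a / areas[i] > 1e-12)
  }
  cand[keep]
}

#' Spherical area of grid cells
#'
#' Exact spherical-zone formula `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))`
#' with the authalic radius R = 6371.0088 km.
#'
#' @inheritParams cell_bounds
#' @return areas in km^2.
#' @export
cell_area_km2 <- function(grid, cell_id = grid$mask) {
  b <- cell_bounds(grid, cell_id)
  dlam <- (b[, 3L] - b[, 1L]) * pi / 180
  unname(EARTH_RADIUS_KM^2 * dlam *
           (sin(b[, 4L] * pi / 180) - sin(b[, 2L] * pi / 180)))
}

## ---- presence matrix -----------------------------------------------------

#' Rasterize species ranges into a presence/absence matrix
#'
#' Superimposes range polygons on the analysis grid. A cell scores 1 for a
#' species under the chosen membership rule:
#' `any_intersection` (default; any positive overlap of cell and range),
#' `centroid_within` (the range centroid's cell only), or `min_fraction`
#' (overlap of at least `min_fraction` of the cell's spherical area).
#'
#' @param ranges a list of range objects as returned by [read_ranges()] or
#'   [generate_ranges()] (each has `species_id` and `geom`).
#' @param grid a `croc_grid`.
#' @param rule cell membership rule.
#' @param min_fraction threshold for `rule = "min_fraction"`.
#' @return binary matrix (masked cells x species); rownames are cell ids,
#'   colnames species ids; attribute `grid` carries the grid. Species whose
#'   range touches no masked cell are dropped with a warning.
#' @export
rasterize_ranges <- function(ranges, grid,
                             rule = c("any_intersection", "centroid_within",
                                      "min_fraction"),
                             min_fraction = 0.5) {
  rule <- match.arg(rule)
  sp <- vapply(ranges, function(r) r$species_id, "")
  if (anyDuplicated(sp)) stop("duplicate species_id in range collection")
  m <- matrix(0L, nrow = length(grid$mask), ncol = length(sp),
              dimnames = list(as.character(grid$mask), sp))
  mask_set <- grid$mask
  for (k in seq_along(ranges)) {
    g <- ranges[[k]]$geom
    ids <- switch(rule,
      any_intersection = cells_touched(grid, g),
      min_fraction = cells_touched(grid, g, min_frac = min_fraction),
      centroid_within = {
        ct <- geom_centroid(g)
        id <- cell_from_point(grid, ct[1L], ct[2L])
        if (is.na(id)) integer(0) else id
      })
    ids <- ids[ids %in% mask_set]
    if (length(ids) == 0L) next
    m[as.character(ids), k] <- 1L
  }
  empty <- colSums(m) == 0L
  if (any(empty)) {
    warning("dropping species with no rasterized cell: ",
            paste(sp[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  attr(m, "grid") <- grid
  m
}

## ---- protected-area coverage --------------------------------------------

#' Per-cell protected-area coverage fraction
#'
#' Fraction of each masked cell's spherical area covered by the union of the
#' protected-area polygons. Overlapping polygons are dissolved (counted once).
#'
#' @param pa_polygons list of `croc_geom` (or objects with a `$geom` field).
#' @param grid a `croc_grid`.
#' @return named numeric vector over masked cells (names = cell ids),
#'   values in `[0, 1]`.
#' @export
pa_coverage <- function(pa_polygons, grid) {
  geoms <- lapply(pa_polygons, function(p) if (inherits(p, "croc_geom")) p else p$geom)
  cov <- stats::setNames(numeric(length(grid$mask)), as.character(grid$mask))
  if (length(geoms) == 0L) return(cov)
  bboxes <- lapply(geoms, geom_bbox)
  # cells possibly touched by any PA
  cand <- integer(0)
  for (bb in bboxes) cand <- c(cand, cells_in_bbox(grid, bb))
  cand <- intersect(sort(unique(cand)), grid$mask)
  if (length(cand) == 0L) return(cov)
  areas <- cell_area_km2(grid, cand)
  b <- cell_bounds(grid, cand)
  for (i in seq_along(cand)) {
    rect <- b[i, ]
    units <- list()
    for (k in seq_along(geoms)) {
      bb <- bboxes[[k]]
      if (bb[3L] <= rect[1L] || bb[1L] >= rect[3L] ||
          bb[4L] <= rect[2L] || bb[2L] >= rect[4L]) next
      rings <- clip_geom_rect_rings(geoms[[k]], rect)
      if (length(rings)) units[[length(units) + 1L]] <- rings
    }
    if (length(units) == 0L) next
    cov[as.character(cand[i])] <- min(1, units_union_area_km2(units) / areas[i])
  }
  cov
}

## ---- raster aggregation --------------------------------------------------

#' Aggregate a finer raster to the analysis grid
#'
#' Assigns each raster pixel to the grid cell containing its center and
#' summarizes per cell. Cells receiving no pixel are `NA`.
#'
#' @param raster a `croc_raster` (see [read_asc_raster()]).
#' @param grid a `croc_grid`.
#' @param stat one of `"mean"`, `"sum"`, `"max"`.
#' @return named numeric vector over masked cells.
#' @export
aggregate_raster_to_grid <- function(raster, grid,
                                     stat = c("mean", "sum", "max")) {
  stat <- match.arg(stat)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  px <- raster$xll + (rep(seq_len(nc), each = nr) - 0.5) * raster$cellsize
  py <- raster$yll + (nr - rep(seq_len(nr), times = nc) + 0.5) * raster$cellsize
  val <- as.vector(v)
  keep <- !is.na(val)
  id <- cell_from_point(grid, px[keep], py[keep])
  val <- val[keep]
  ok <- !is.na(id) & id %in% grid$mask
  out <- stats::setNames(rep(NA_real_, length(grid$mask)), as.character(grid$mask))
  if (!any(ok)) return(out)
  f <- factor(as.character(id[ok]), levels = as.character(grid$mask))
  agg <- switch(stat,
    mean = tapply(val[ok], f, mean),
    sum  = tapply(val[ok], f, sum),
    max  = tapply(val[ok], f, max))
  out[names(agg)] <- as.numeric(agg)
  out
}
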