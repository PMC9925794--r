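# Lightweight rectilinear-friendly geometry layer in longitude/latitude degrees
# (WGS84 convention). Geometries are multipolygons: a list of polygons, each a
# list of rings (first outer, rest holes); a ring is an n x 2 matrix of
# (lon, lat) vertices, stored open (last vertex != first). All areas are
# spherical, on the authalic sphere R = 6371.0088 km; interior membership uses
# the even-odd rule, so holes need no special casing.

EARTH_RADIUS_KM <- 6371.0088

#' Construct a polygon geometry
#'
#' Builds a `croc_geom` multipolygon from a list of rings or polygons. Used by
#' the readers and the synthetic generators; most users will obtain geometries
#' from [read_ranges()] or [wkt_to_geom()].
#'
#' @param polys a list of polygons; each polygon is a list of rings (first
#'   outer, subsequent rings holes); each ring an n x 2 matrix of lon/lat
#'   vertices. A single ring or single polygon is promoted.
#' @param validate check invariants (coordinate bounds, ring size)?
#' @return an object of class `croc_geom`.
#' @export
croc_geom <- function(polys, validate = TRUE) {
  if (is.matrix(polys)) polys <- list(list(polys))
  if (length(polys) > 0L && is.matrix(polys[[1L]])) polys <- list(polys)
  polys <- lapply(polys, function(p) lapply(p, close_open_ring))
  g <- structure(list(polys = polys), class = "croc_geom")
  if (validate) validate_geom(g)
  g
}

# drop a repeated closing vertex and exact consecutive duplicates
close_open_ring <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n >= 2L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring[keep, , drop = FALSE]
}

validate_geom <- function(g) {
  for (p in g$polys) {
    for (ring in p) {
      if (nrow(ring) < 3L) stop("geometry ring with fewer than 3 distinct vertices")
      if (!all(is.finite(ring))) stop("non-finite coordinate in geometry")
      if (any(ring[, 1L] < -180 - 1e-9 | ring[, 1L] > 180 + 1e-9))
        stop("longitude outside [-180, 180]")
      if (any(ring[, 2L] < -90 - 1e-9 | ring[, 2L] > 90 + 1e-9))
        stop("latitude outside [-90, 90]")
    }
  }
  invisible(g)
}

#' @export
print.croc_geom <- function(x, ...) {
  nr <- sum(vapply(x$polys, length, 1L))
  cat(sprintf("<croc_geom: %d polygon(s), %d ring(s), area %.2f km^2>\n",
              length(x$polys), nr, geom_area_km2(x)))
  invisible(x)
}

#' Axis-aligned rectangle geometry
#'
#' @param xmin,ymin,xmax,ymax bounds in degrees.
#' @return a `croc_geom` with one rectangular polygon.
#' @export
geom_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  croc_geom(rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax)))
}

geom_bbox <- function(g) {
  xs <- unlist(lapply(g$polys, function(p) lapply(p, function(r) r[, 1L])))
  ys <- unlist(lapply(g$polys, function(p) lapply(p, function(r) r[, 2L])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# all rings of a geometry, flat
geom_rings <- function(g) unlist(g$polys, recursive = FALSE)

## ---- WKT ----------------------------------------------------------------

#' Parse WKT POLYGON / MULTIPOLYGON text
#'
#' A minimal well-known-text reader for the two polygonal types; sufficient
#' for the delimited-text geometry interchange this package uses.
#'
#' @param wkt a single WKT string.
#' @return a `croc_geom`.
#' @export
wkt_to_geom <- function(wkt) {
  s <- trimws(wkt)
  if (grepl("^MULTIPOLYGON", s, ignore.case = TRUE)) {
    body <- sub("^MULTIPOLYGON\\s*", "", s, ignore.case = TRUE)
    polys <- lapply(split_paren_group(strip_outer_parens(body)),
                    function(ptxt) lapply(split_paren_group(strip_outer_parens(ptxt)),
                                          parse_ring_text))
  } else if (grepl("^POLYGON", s, ignore.case = TRUE)) {
    body <- sub("^POLYGON\\s*", "", s, ignore.case = TRUE)
    polys <- list(lapply(split_paren_group(strip_outer_parens(body)), parse_ring_text))
  } else {
    stop("unsupported WKT type (POLYGON and MULTIPOLYGON only): ",
         substr(s, 1L, 30L))
  }
  croc_geom(polys)
}

strip_outer_parens <- function(s) {
  s <- trimws(s)
  if (!startsWith(s, "(") || !endsWith(s, ")"))
    stop("malformed WKT near: ", substr(s, 1L, 30L))
  substr(s, 2L, nchar(s) - 1L)
}

# split "(...),(...)" at top-level commas
split_paren_group <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  trimws(substring(s, starts, ends))
}

parse_ring_text <- function(s) {
  s <- strip_outer_parens(s)
  pts <- strsplit(split_paren_group(s), "\\s+")
  m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[p != ""])))
  if (ncol(m) != 2L || anyNA(m)) stop("malformed WKT coordinate list")
  m
}

#' Serialize a geometry to WKT
#'
#' @param g a `croc_geom`.
#' @return a WKT `MULTIPOLYGON` (or `POLYGON` for a single part) string.
#' @export
geom_to_wkt <- function(g) {
  fmt_ring <- function(r) {
    r <- rbind(r, r[1L, ])
    paste0("(", paste(sprintf("%.10g %.10g", r[, 1L], r[, 2L]), collapse = ", "), ")")
  }
  fmt_poly <- function(p) paste0("(", paste(vapply(p, fmt_ring, ""), collapse = ", "), ")")
  if (length(g$polys) == 1L) {
    paste0("POLYGON ", fmt_poly(g$polys[[1L]]))
  } else {
    paste0("MULTIPOLYGON (", paste(vapply(g$polys, fmt_poly, ""), collapse = ", "), ")")
  }
}

## ---- clipping -----------------------------------------------------------

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle
# rect = c(xmin, ymin, xmax, ymax). Returns a ring matrix (possibly 0 rows).
clip_ring_rect <- function(ring, rect) {
  pts <- ring
  for (side in 1:4) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    inside <- switch(side,
      pts[, 1L] >= rect[1L], pts[, 2L] >= rect[2L],
      pts[, 1L] <= rect[3L], pts[, 2L] <= rect[4L])
    prev <- c(n, seq_len(n - 1L))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      p <- pts[prev[i], ]; c_ <- pts[i, ]
      pin <- inside[prev[i]]; cin <- inside[i]
      if (cin) {
        if (!pin) out[[i]] <- rbind(edge_rect_intersect(p, c_, side, rect), c_)
        else out[[i]] <- matrix(c_, 1L)
      } else if (pin) {
        out[[i]] <- matrix(edge_rect_intersect(p, c_, side, rect), 1L)
      }
    }
    pts <- do.call(rbind, out)
    if (is.null(pts)) return(matrix(numeric(0), 0L, 2L))
  }
  close_open_ring(pts)
}

edge_rect_intersect <- function(p, q, side, rect) {
  if (side %in% c(1L, 3L)) {
    x <- rect[if (side == 1L) 1L else 3L]
    t <- (x - p[1L]) / (q[1L] - p[1L])
    c(x, p[2L] + t * (q[2L] - p[2L]))
  } else {
    y <- rect[if (side == 2L) 2L else 4L]
    t <- (y - p[2L]) / (q[2L] - p[2L])
    c(p[1L] + t * (q[1L] - p[1L]), y)
  }
}

# clip a whole geometry to a rectangle; returns list of ring matrices
# (flattened; even-odd semantics preserved because holes clip alongside outers)
clip_geom_rect_rings <- function(g, rect) {
  out <- list()
  for (p in g$polys) {
    for (ring in p) {
      rb <- range(ring[, 1L]); cb <- range(ring[, 2L])
      if (rb[2L] <= rect[1L] || rb[1L] >= rect[3L] ||
          cb[2L] <= rect[2L] || cb[1L] >= rect[4L]) next
      cl <- clip_ring_rect(ring, rect)
      if (nrow(cl) >= 3L) out[[length(out) + 1L]] <- cl
    }
  }
  out
}

## ---- areas --------------------------------------------------------------

# signed planar (degree^2) area of a ring; shoelace
ring_area_planar <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

# Spherical area (km^2) of the union of "units". Each unit is a list of ring
# matrices interpreted with the even-odd rule (so one geometry's outer+hole
# rings form one unit). Vertical-slab decomposition at all vertex longitudes
# plus pairwise inter-unit edge crossings; within a slab the union's
# latitude-interval structure is fixed, and the integrand
# sum(sin(lat_hi) - sin(lat_lo)) is evaluated by 3-point Gauss-Legendre,
# which is exact to ~1e-13 relative for sub-degree slabs.
units_union_area_km2 <- function(units) {
  units <- Filter(function(u) length(u) > 0L, units)
  if (length(units) == 0L) return(0)
  edges <- vector("list", length(units))   # per unit: x1,y1,x2,y2 matrix
  for (k in seq_along(units)) {
    e <- lapply(units[[k]], function(r) {
      n <- nrow(r)
      cbind(r[, 1L], r[, 2L], r[c(2:n, 1L), 1L], r[c(2:n, 1L), 2L])
    })
    edges[[k]] <- do.call(rbind, e)
  }
  xs <- sort(unique(unlist(lapply(edges, function(e) c(e[, 1L], e[, 3L])))))
  if (length(units) > 1L) {
    cross_x <- inter_unit_crossings(edges)
    if (length(cross_x)) xs <- sort(unique(c(xs, cross_x)))
  }
  # Gauss-Legendre 3-point nodes/weights on [0,1]
  gn <- c(0.5 - sqrt(0.15), 0.5, 0.5 + sqrt(0.15))
  gw <- c(5, 8, 5) / 18
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x1 <- xs[i]; x2 <- xs[i + 1L]
    w <- x2 - x1
    if (w <= 0) next
    acc <- 0
    for (j in 1:3) {
      x <- x1 + gn[j] * w
      iv <- union_intervals_at(edges, x)
      if (length(iv)) {
        lo <- iv[c(TRUE, FALSE)]; hi <- iv[c(FALSE, TRUE)]
        acc <- acc + gw[j] * sum(sin(hi * pi / 180) - sin(lo * pi / 180))
      }
    }
    total <- total + acc * w * pi / 180
  }
  total * EARTH_RADIUS_KM^2
}

# latitudes where the vertical line at x crosses unit k's edges -> intervals
unit_intervals_at <- function(e, x) {
  sel <- (e[, 1L] <= x & e[, 3L] > x) | (e[, 3L] <= x & e[, 1L] > x)
  if (!any(sel)) return(numeric(0))
  e <- e[sel, , drop = FALSE]
  t <- (x - e[, 1L]) / (e[, 3L] - e[, 1L])
  sort(e[, 2L] + t * (e[, 4L] - e[, 2L]))
}

union_intervals_at <- function(edges, x) {
  ivs <- lapply(edges, unit_intervals_at, x = x)
  ivs <- Filter(length, ivs)
  if (length(ivs) == 0L) return(numeric(0))
  if (length(ivs) == 1L) return(ivs[[1L]])
  # merge even-odd interval lists across units
  lo <- unlist(lapply(ivs, function(v) v[c(TRUE, FALSE)]))
  hi <- unlist(lapply(ivs, function(v) v[c(FALSE, TRUE)]))
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1L]; mhi <- hi[1L]; out <- numeric(0)
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= mhi) mhi <- max(mhi, hi[i])
    else { out <- c(out, mlo, mhi); mlo <- lo[i]; mhi <- hi[i] }
  }
  c(out, mlo, mhi)
}

inter_unit_crossings <- function(edges) {
  out <- numeric(0)
  nk <- length(edges)
  for (a in seq_len(nk - 1L)) for (b in (a + 1L):nk) {
    ea <- edges[[a]]; eb <- edges[[b]]
    for (i in seq_len(nrow(ea))) {
      p1 <- ea[i, 1:2]; p2 <- ea[i, 3:4]
      d1 <- p2 - p1
      denom_all <- d1[1L] * (eb[, 4L] - eb[, 2L]) - d1[2L] * (eb[, 3L] - eb[, 1L])
      for (j in seq_len(nrow(eb))) {
        denom <- denom_all[j]
        if (abs(denom) < 1e-15) next
        q1 <- eb[j, 1:2]; d2 <- eb[j, 3:4] - q1
        t <- ((q1[1L] - p1[1L]) * d2[2L] - (q1[2L] - p1[2L]) * d2[1L]) / -denom
        u <- ((p1[1L] - q1[1L]) * d1[2L] - (p1[2L] - q1[2L]) * d1[1L]) / denom
        if (t > 0 && t < 1 && u > 0 && u < 1) out <- c(out, p1[1L] + t * d1[1L])
      }
    }
  }
  out
}

#' Spherical area of a geometry
#'
#' Area on the authalic sphere (radius 6371.0088 km) of a lon/lat polygon
#' whose edges are straight in coordinate space. Holes are subtracted.
#'
#' @param g a `croc_geom`.
#' @return area in km^2.
#' @export
geom_area_km2 <- function(g) units_union_area_km2(list(geom_rings(g)))

#' Spherical area of the union of several geometries
#'
#' Overlaps are counted once (dissolve semantics), as required when measuring
#' protected-area coverage from overlapping reserve polygons.
#'
#' @param geoms a list of `croc_geom` objects.
#' @return area in km^2.
#' @export
geoms_union_area_km2 <- function(geoms)
  units_union_area_km2(lapply(geoms, geom_rings))

# fast exact union area for axis-aligned rectangles, rect rows (xmin,ymin,xmax,ymax)
rect_union_area_km2 <- function(rects) {
  if (is.null(rects) || nrow(rects) == 0L) return(0)
  xs <- sort(unique(c(rects[, 1L], rects[, 3L])))
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x1 <- xs[i]; x2 <- xs[i + 1L]
    sel <- rects[, 1L] <= x1 & rects[, 3L] >= x2
    if (!any(sel)) next
    lo <- rects[sel, 2L]; hi <- rects[sel, 4L]
    o <- order(lo); lo <- lo[o]; hi <- hi[o]
    mlo <- lo[1L]; mhi <- hi[1L]; zone <- 0
    for (k in seq_along(lo)[-1L]) {
      if (lo[k] <= mhi) mhi <- max(mhi, hi[k])
      else { zone <- zone + sin(mhi * pi / 180) - sin(mlo * pi / 180)
             mlo <- lo[k]; mhi <- hi[k] }
    }
    zone <- zone + sin(mhi * pi / 180) - sin(mlo * pi / 180)
    total <- total + zone * (x2 - x1) * pi / 180
  }
  total * EARTH_RADIUS_KM^2
}

## ---- point location & centroid ------------------------------------------

#' Point-in-geometry test (even-odd rule)
#'
#' @param x,y point coordinates in degrees.
#' @param g a `croc_geom`.
#' @return logical.
#' @export
point_in_geom <- function(x, y, g) {
  inside <- FALSE
  for (ring in geom_rings(g)) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2L]; yj <- ring[j, 2L]
      if ((yi > y) != (yj > y)) {
        xint <- ring[i, 1L] + (y - yi) / (yj - yi) * (ring[j, 1L] - ring[i, 1L])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# planar area-weighted centroid (degrees); adequate for cell assignment.
# Ring orientation is normalized via the signed shoelace area; holes subtract.
geom_centroid <- function(g) {
  cx <- 0; cy <- 0; atot <- 0
  for (p in g$polys) {
    for (k in seq_along(p)) {
      ring <- p[[k]]
      a <- ring_area_planar(ring)          # signed
      if (abs(a) < 1e-15) next
      x <- ring[, 1L]; y <- ring[, 2L]
      xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
      cr <- x * ys - xs * y
      orient <- sign(a)                    # make contribution positive
      sgn <- if (k == 1L) 1 else -1        # outer adds, holes subtract
      cx <- cx + sgn * orient * sum((x + xs) * cr) / 6
      cy <- cy + sgn * orient * sum((y + ys) * cr) / 6
      atot <- atot + sgn * abs(a)
    }
  }
  if (atot <= 0) stop("zero-area geometry has no centroid")
  c(cx / atot, cy / atot)
}
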