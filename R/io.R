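# Readers and writers for every external artifact: range and protected-area
# polygons (CSV with WKT geometry), traits (CSV + YAML schema), Newick trees,
# IUCN status tables, gridded values (long CSV and ESRI ASCII raster). All
# readers validate hard rather than coerce silently.

IUCN_CATEGORIES <- c("CR", "EN", "VU", "NT", "LC", "DD")

#' Construct a species range object
#'
#' @param species_id species identifier.
#' @param geom a [croc_geom] polygon/multipolygon.
#' @param source_tag free-text provenance tag.
#' @return an object of class `croc_range`.
#' @export
croc_range <- function(species_id, geom, source_tag = "") {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            inherits(geom, "croc_geom"))
  structure(list(species_id = species_id, geom = geom, source_tag = source_tag),
            class = "croc_range")
}

#' @export
print.croc_range <- function(x, ...) {
  cat(sprintf("<croc_range %s: %d polygon(s), %.2f km^2>\n", x$species_id,
              length(x$geom$polys), geom_area_km2(x$geom)))
  invisible(x)
}

#' Read species range polygons
#'
#' Reads a delimited-text vector file with one feature per row: a species
#' identifier column and a WKT `POLYGON`/`MULTIPOLYGON` column. Multiple
#' features of the same species are merged into one multipolygon.
#'
#' @param path CSV file with columns `species_id`, `wkt` and optionally
#'   `source_tag`.
#' @param on_invalid `"repair"` drops degenerate rings (fewer than 3 distinct
#'   vertices); `"reject"` raises an error instead.
#' @return named list of [croc_range] objects (possibly empty, with warning).
#' @export
read_ranges <- function(path, on_invalid = c("repair", "reject")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("range file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"species_id" %in% names(df))
    stop("range file ", path, " lacks a 'species_id' attribute column")
  if (!"wkt" %in% names(df))
    stop("range file ", path, " lacks a 'wkt' geometry column")
  if (nrow(df) == 0L) {
    warning("range file ", path, " contains zero features")
    return(structure(list(), names = character(0)))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    g <- tryCatch(wkt_to_geom(df$wkt[i]), error = function(e) {
      if (on_invalid == "reject")
        stop("invalid geometry in ", path, " row ", i, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(g)) next
    bad <- vapply(g$polys, function(p) any(vapply(p, nrow, 1L) < 3L), TRUE)
    if (any(bad)) {
      if (on_invalid == "reject")
        stop("degenerate ring in ", path, " row ", i)
      g$polys <- g$polys[!bad]
      if (length(g$polys) == 0L) next
    }
    sp <- as.character(df$species_id[i])
    tag <- if ("source_tag" %in% names(df)) df$source_tag[i] else ""
    if (is.null(out[[sp]])) {
      out[[sp]] <- croc_range(sp, g, tag)
    } else {
      out[[sp]]$geom$polys <- c(out[[sp]]$geom$polys, g$polys)
    }
  }
  out
}

#' Write range polygons as WKT CSV
#' @param ranges list of [croc_range].
#' @param path output file.
#' @export
write_ranges <- function(ranges, path) {
  df <- data.frame(
    species_id = vapply(ranges, function(r) r$species_id, ""),
    wkt = vapply(ranges, function(r) geom_to_wkt(r$geom), ""),
    source_tag = vapply(ranges, function(r) as.character(r$source_tag %||% ""), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- trees ---------------------------------------------------------------

#' Read a Newick phylogeny with mandatory branch lengths
#'
#' Parses a (possibly lenient) Newick string into an `ape` `phylo` object and
#' enforces the invariants the diversity metrics need: balanced parentheses,
#' a branch length on every edge, non-negative lengths, unique leaf labels.
#' A missing trailing semicolon is accepted with a warning.
#'
#' @param path path to a Newick file, or a literal Newick string.
#' @return a `phylo` tree; the number of leaves is reported via `message()`.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "") else path
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("empty Newick input")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses in Newick at offset ", i)
  }
  if (depth != 0L)
    stop("unbalanced parentheses in Newick: ", depth, " unclosed at end of input")
  if (!grepl(";\\s*$", txt)) {
    warning("Newick string lacks a trailing semicolon; accepting lenient dialect")
    txt <- paste0(txt, ";")
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("Newick edge without branch length; branch lengths are required")
  if (any(tr$edge.length < 0)) stop("negative branch length in Newick input")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in Newick input")
  message(sprintf("read tree with %d leaves, total branch length %g",
                  ape::Ntip(tr), sum(tr$edge.length)))
  tr
}

## ---- traits --------------------------------------------------------------

#' Read a species-by-trait table with a sidecar schema
#'
#' The schema (YAML) declares each trait's kind — `continuous`, `ordinal`,
#' `categorical` or `binary` — and, optionally, allowed category levels and a
#' category label. Values are validated against the declared kind; missing
#' values must be empty cells / `NA`, never silent zeros.
#'
#' @param path CSV with a `species_id` column plus one column per trait.
#' @param schema either a path to a YAML schema file or an equivalent named
#'   list `list(trait = list(kind = ..., levels = ..., category = ...))`.
#' @return a data.frame (rownames = species ids) with attribute `schema`,
#'   of class `croc_traits`.
#' @export
read_traits <- function(path, schema) {
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  if (!is.null(schema$traits)) schema <- schema$traits
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  if (!"species_id" %in% names(df)) stop("trait file lacks 'species_id' column")
  if (anyDuplicated(df$species_id)) stop("duplicate species_id in trait file")
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop("trait columns declared in schema but absent from file: ",
         paste(missing_cols, collapse = ", "))
  rownames(df) <- df$species_id
  df <- df[setdiff(names(df), "species_id")]
  df <- df[names(schema)]
  validate_traits(df, schema)
  structure(df, schema = schema, class = c("croc_traits", "data.frame"))
}

validate_traits <- function(df, schema) {
  for (tr in names(schema)) {
    kind <- schema[[tr]]$kind
    v <- df[[tr]]
    if (kind %in% c("continuous", "ordinal")) {
      if (!is.numeric(v))
        stop("trait '", tr, "' declared ", kind, " but contains non-numeric values")
    } else if (kind == "binary") {
      bad <- which(!is.na(v) & !(v %in% c(0, 1)))
      if (length(bad))
        stop("trait '", tr, "' declared binary but row ", bad[1L],
             " has value ", v[bad[1L]])
    } else if (kind == "categorical") {
      lev <- schema[[tr]]$levels
      if (!is.null(lev)) {
        bad <- which(!is.na(v) & !(v %in% lev))
        if (length(bad))
          stop("trait '", tr, "' row ", bad[1L], " value '", v[bad[1L]],
               "' not among declared levels: ", paste(lev, collapse = ", "))
      }
    } else stop("unknown trait kind '", kind, "' for trait '", tr, "'")
  }
  invisible(df)
}

#' Write a trait table and its schema
#' @param traits a `croc_traits` object.
#' @param path CSV output path.
#' @param schema_path YAML schema output path.
#' @export
write_traits <- function(traits, path, schema_path) {
  df <- cbind(species_id = rownames(traits), as.data.frame(traits))
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(traits = attr(traits, "schema")), schema_path)
  invisible(path)
}

## ---- status --------------------------------------------------------------

#' Read an IUCN status table
#'
#' @param path CSV with columns `species_id`, `iucn_category`.
#' @return data.frame with validated categories (CR, EN, VU, NT, LC, DD).
#' @export
read_status <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("species_id", "iucn_category") %in% names(df)))
    stop("status file needs 'species_id' and 'iucn_category' columns")
  bad <- which(!(df$iucn_category %in% IUCN_CATEGORIES))
  if (length(bad))
    stop("invalid IUCN category '", df$iucn_category[bad[1L]], "' at row ",
         bad[1L], "; allowed: ", paste(IUCN_CATEGORIES, collapse = ", "))
  if (anyDuplicated(df$species_id)) stop("duplicate species_id in status file")
  df
}

## ---- result tables and gridded values ------------------------------------

#' Write a result table as CSV (lossless round-trip)
#' @param rows a data.frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

#' Write per-cell values as a long-format CSV
#'
#' Columns `cell_id, lon, lat, value`, one row per masked grid cell.
#'
#' @param values named numeric vector over masked cells (names = cell ids).
#' @param grid a `croc_grid`.
#' @param path output path.
#' @export
write_grid_csv <- function(values, grid, path) {
  ids <- as.integer(names(values))
  ct <- cell_centers(grid, ids)
  utils::write.csv(data.frame(cell_id = ids, lon = ct[, 1L], lat = ct[, 2L],
                              value = as.numeric(values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Convert per-cell values to a raster
#'
#' @param values named numeric vector over cells (names = 0-based cell ids).
#' @param grid a `croc_grid`.
#' @return a `croc_raster` (values matrix row 1 = northernmost band).
#' @export
grid_values_to_raster <- function(values, grid) {
  m <- matrix(NA_real_, nrow = grid$n_rows, ncol = grid$n_cols)
  ids <- as.integer(names(values))
  row <- ids %/% grid$n_cols         # 0 = south
  col <- ids %% grid$n_cols
  m[cbind(grid$n_rows - row, col + 1L)] <- as.numeric(values)
  structure(list(values = m, xll = grid$origin[1L], yll = grid$origin[2L],
                 cellsize = grid$resolution, nodata = -9999),
            class = "croc_raster")
}

#' Write a georeferenced raster as ESRI ASCII grid
#' @param raster a `croc_raster`.
#' @param path output `.asc` path.
#' @export
write_asc_raster <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", raster$xll),
           sprintf("yllcorner %.10g", raster$yll),
           sprintf("cellsize %.10g", raster$cellsize),
           sprintf("NODATA_value %.10g", raster$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#' @param path `.asc` path.
#' @return a `croc_raster`.
#' @export
read_asc_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  v <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  nodata <- hdr[["nodata_value"]] %||% -9999
  v[v == nodata] <- NA_real_
  if (nrow(v) != hdr$nrows || ncol(v) != hdr$ncols)
    stop("ASCII raster body does not match header dimensions")
  structure(list(values = v, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = nodata),
            class = "croc_raster")
}
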