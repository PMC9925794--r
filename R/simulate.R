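# Synthetic study-input generator. Produces a complete, deterministic test
# bed — ranges, traits + schema, phylogeny, protected-area mosaic, nutrient
# surface, IUCN statuses, realm polygons — with controlled statistical
# structure: spatially cohesive ranges following a latitudinal richness
# gradient, log-normal range sizes, a pure-birth tree, a PA mosaic of
# controllable total coverage, and a nutrient surface with a tunable
# correlation to richness. One global seed fans out to per-component child
# seeds so each component can be regenerated independently.

#' Synthetic-study configuration
#'
#' Defaults describe the package's reference synthetic study: 28 species on
#' a 0.5-degree grid over a 140 x 80 degree tropical-to-subtropical window
#' (44,800 cells), log-normal range sizes (median 300 cells, sigma 1), a
#' richness peak at 5 deg latitude with a 15-degree Gaussian decay, a
#' protected-area mosaic covering 15% of the region in ~150 patches, a
#' nutrient surface coupled to richness at r = 0.5, and status quantile cuts
#' (0.25, 0.32, 0.54) giving a 7 CR / 2 EN / 6 VU / 13 LC composition.
#'
#' @param n_species number of species.
#' @param extent `c(xmin, ymin, xmax, ymax)` degrees; edges must be whole
#'   multiples of `resolution_deg`.
#' @param resolution_deg grid resolution (default 0.5).
#' @param range_size_median_cells,range_size_sigma log-normal range-size law.
#' @param richness_peak_lat,richness_decay_deg latitudinal gradient: seeding
#'   and growth weight `exp(-(lat - peak)^2 / (2 * decay^2))`.
#' @param pa_target_coverage target PA union coverage fraction in `[0, 1]`.
#' @param pa_patch_count approximate number of PA patches.
#' @param nutrient_coupling target Pearson correlation of the nutrient
#'   surface with cell richness, in `[-1, 1]`.
#' @param noise_sd standard deviation of the nutrient noise term (with the
#'   default 1 the realized correlation approximates the coupling).
#' @param birth_rate pure-birth speciation rate for the tree.
#' @param status_quantiles named fractions `c(CR=, EN=, VU=)`, cumulative
#'   cut points on the range-size order (smallest ranges most threatened).
#' @param seed global seed; all components derive child seeds from it.
#' @return a `croc_synth_config` list.
#' @export
synth_config <- function(n_species = 28L,
                         extent = c(-80, -40, 60, 40),
                         resolution_deg = 0.5,
                         range_size_median_cells = 300,
                         range_size_sigma = 1,
                         richness_peak_lat = 5,
                         richness_decay_deg = 15,
                         pa_target_coverage = 0.15,
                         pa_patch_count = 150L,
                         nutrient_coupling = 0.5,
                         noise_sd = 1,
                         birth_rate = 1,
                         status_quantiles = c(CR = 0.25, EN = 0.32, VU = 0.54),
                         seed = 42L) {
  stopifnot(n_species >= 0, resolution_deg > 0,
            pa_target_coverage >= 0, pa_target_coverage <= 1,
            nutrient_coupling >= -1, nutrient_coupling <= 1,
            noise_sd >= 0, all(diff(status_quantiles) >= 0),
            all(status_quantiles >= 0 & status_quantiles <= 1))
  for (edge in c(extent[3L] - extent[1L], extent[4L] - extent[2L])) {
    k <- edge / resolution_deg
    if (abs(k - round(k)) > 1e-9)
      stop("extent edges must be whole multiples of the resolution")
  }
  structure(as.list(environment()), class = "croc_synth_config")
}

species_ids <- function(n) sprintf("sp%02d", seq_len(n))

lat_weight <- function(lat, config)
  exp(-(lat - config$richness_peak_lat)^2 / (2 * config$richness_decay_deg^2))

#' Generate spatially cohesive species ranges
#'
#' Each species' range is a connected blob of grid cells grown from a seed
#' cell: seeding and growth probabilities decay with distance from the
#' configured latitudinal richness peak, and the realized number of cells is
#' drawn from the configured log-normal law (clipped to the grid). Blobs are
#' polygonized into rectilinear multipolygons, so range size in cells is
#' controlled exactly.
#'
#' @param config a [synth_config()].
#' @return named list of [croc_range] objects.
#' @export
generate_ranges <- function(config) {
  grid <- build_grid(config$extent, config$resolution_deg)
  ids <- species_ids(config$n_species)
  ncell <- n_cells(grid)
  ctr_lat <- cell_centers(grid, seq_len(ncell) - 1L)[, 2L]
  w <- lat_weight(ctr_lat, config)
  out <- list()
  for (i in seq_along(ids)) {
    out[[ids[i]]] <- with_seed(child_seed(config$seed, paste0("range", i)), {
      n_target <- round(stats::rlnorm(1, log(config$range_size_median_cells),
                                      config$range_size_sigma))
      n_target <- max(1L, min(ncell, as.integer(n_target)))
      blob <- grow_blob(grid, n_target, w)
      croc_range(ids[i], blob_to_geom(grid, blob), "synthetic")
    })
  }
  out
}

# grow a connected 4-neighborhood blob of n cells; frontier sampled with the
# latitudinal weight
grow_blob <- function(grid, n, w) {
  ncell <- length(w)
  seed_cell <- sample.int(ncell, 1L, prob = w)
  in_blob <- logical(ncell)
  in_blob[seed_cell] <- TRUE
  frontier <- cell_neighbors(grid, seed_cell)
  while (sum(in_blob) < n && length(frontier) > 0L) {
    pick <- if (length(frontier) == 1L) frontier
            else frontier[sample.int(length(frontier), 1L, prob = w[frontier])]
    in_blob[pick] <- TRUE
    frontier <- frontier[frontier != pick]
    nb <- cell_neighbors(grid, pick)
    nb <- nb[!in_blob[nb]]
    frontier <- unique(c(frontier, nb))
  }
  which(in_blob) - 1L   # 0-based cell ids
}

# 4-neighbors of a 1-based linear cell index; returns 1-based indices
cell_neighbors <- function(grid, idx1) {
  id <- idx1 - 1L
  row <- id %/% grid$n_cols
  col <- id %% grid$n_cols
  nb <- c(if (col > 0L) id - 1L,
          if (col < grid$n_cols - 1L) id + 1L,
          if (row > 0L) id - grid$n_cols,
          if (row < grid$n_rows - 1L) id + grid$n_cols)
  nb + 1L
}

# merge a cell set into per-row horizontal run rectangles -> multipolygon
blob_to_geom <- function(grid, cells0) {
  row <- cells0 %/% grid$n_cols
  col <- cells0 %% grid$n_cols
  o <- order(row, col)
  row <- row[o]; col <- col[o]
  polys <- list()
  for (r in unique(row)) {
    cc <- col[row == r]
    breaks <- c(0L, which(diff(cc) > 1L), length(cc))
    for (b in seq_len(length(breaks) - 1L)) {
      c0 <- cc[breaks[b] + 1L]; c1 <- cc[breaks[b + 1L]]
      xmin <- grid$origin[1L] + c0 * grid$resolution
      xmax <- grid$origin[1L] + (c1 + 1L) * grid$resolution
      ymin <- grid$origin[2L] + r * grid$resolution
      ymax <- ymin + grid$resolution
      polys[[length(polys) + 1L]] <-
        list(rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax)))
    }
  }
  croc_geom(polys)
}

#' Generate a mixed-type trait table
#'
#' Emulates a crocodilian-style trait schema: two continuous body sizes,
#' three habitat traits, two binary climate-tolerance traits, a binary
#' burrowing trait, a three-level activity trait, diet generality, skull
#' shape, bite force, nest type, and relative clutch mass. Values are drawn
#' independently per declared kind.
#'
#' @param config a [synth_config()].
#' @param species_ids species identifiers (default from the config).
#' @return a `croc_traits` table with its schema attribute.
#' @export
generate_traits <- function(config, species_ids = NULL) {
  if (is.null(species_ids)) species_ids <- species_ids(config$n_species)
  n <- length(species_ids)
  schema <- default_trait_schema()
  df <- with_seed(child_seed(config$seed, "traits"), data.frame(
    max_male_size_cm = round(stats::rlnorm(n, log(300), 0.4), 1),
    female_maturity_size_cm = round(stats::rlnorm(n, log(150), 0.35), 1),
    habitat_generality = sample(1:5, n, replace = TRUE),
    salt_tolerance = stats::rbinom(n, 1L, 0.3),
    terrestriality = stats::rbinom(n, 1L, 0.4),
    aestivation = stats::rbinom(n, 1L, 0.25),
    brumation = stats::rbinom(n, 1L, 0.2),
    burrowing = stats::rbinom(n, 1L, 0.35),
    activity = sample(c("diurnal", "nocturnal", "both"), n, replace = TRUE),
    diet_generality = sample(1:5, n, replace = TRUE),
    skull_shape = sample(c("slender", "moderate", "broad"), n, replace = TRUE),
    bite_force_n = round(stats::rlnorm(n, log(5000), 0.5), 0),
    nest_type = sample(c("mound", "hole"), n, replace = TRUE),
    relative_clutch_mass = round(stats::runif(n, 0.05, 0.35), 3),
    row.names = species_ids, stringsAsFactors = FALSE))
  structure(df, schema = schema, class = c("croc_traits", "data.frame"))
}

default_trait_schema <- function() {
  list(
    max_male_size_cm = list(kind = "continuous", category = "body size"),
    female_maturity_size_cm = list(kind = "continuous", category = "body size"),
    habitat_generality = list(kind = "ordinal", category = "habitat"),
    salt_tolerance = list(kind = "binary", category = "habitat"),
    terrestriality = list(kind = "binary", category = "habitat"),
    aestivation = list(kind = "binary", category = "climate tolerance"),
    brumation = list(kind = "binary", category = "climate tolerance"),
    burrowing = list(kind = "binary", category = "ecosystem engineering"),
    activity = list(kind = "categorical", category = "activity",
                    levels = c("diurnal", "nocturnal", "both")),
    diet_generality = list(kind = "ordinal", category = "diet"),
    skull_shape = list(kind = "categorical", category = "diet",
                       levels = c("slender", "moderate", "broad")),
    bite_force_n = list(kind = "continuous", category = "diet"),
    nest_type = list(kind = "categorical", category = "reproduction",
                     levels = c("mound", "hole")),
    relative_clutch_mass = list(kind = "continuous", category = "reproduction"))
}

#' Generate a pure-birth phylogeny
#'
#' @param config a [synth_config()].
#' @param species_ids tip labels (default from the config).
#' @param drop_tips number of species to exclude from the tree, emulating a
#'   phylogeny that covers only part of the species pool.
#' @return a `phylo` tree with strictly positive branch lengths.
#' @export
generate_tree <- function(config, species_ids = NULL, drop_tips = 0L) {
  if (is.null(species_ids)) species_ids <- species_ids(config$n_species)
  n <- length(species_ids)
  if (n < 2L) stop("a tree needs at least two species")
  with_seed(child_seed(config$seed, "tree"), {
    tr <- ape::rphylo(n, birth = config$birth_rate, death = 0)
    tr$tip.label <- species_ids
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    if (drop_tips > 0L)
      tr <- ape::drop.tip(tr, sample(species_ids, drop_tips))
    tr
  })
}

#' Generate a protected-area mosaic
#'
#' Places axis-aligned rectangular patches uniformly over the grid extent
#' until their union covers `pa_target_coverage` (within 0.02) of the
#' region's spherical area; the final patch is shrunk to avoid overshooting.
#'
#' @param config a [synth_config()].
#' @param grid the analysis grid (default built from the config extent).
#' @return list of [croc_range] objects tagged `pa_001, pa_002, ...`
#'   (areas, not species); empty when the target coverage is 0.
#' @export
generate_pa <- function(config, grid = NULL) {
  if (is.null(grid)) grid <- build_grid(config$extent, config$resolution_deg)
  target <- config$pa_target_coverage
  if (target <= 0) return(list())
  ext <- c(grid$origin,
           grid$origin + c(grid$n_cols, grid$n_rows) * grid$resolution)
  region_area <- rect_union_area_km2(matrix(ext, 1L))
  nominal_deg2 <- target * (ext[3L] - ext[1L]) * (ext[4L] - ext[2L]) /
    config$pa_patch_count
  with_seed(child_seed(config$seed, "pa"), {
    rects <- matrix(numeric(0), 0L, 4L)
    cov <- 0
    iter <- 0L
    while (cov < target - 0.001 && iter < 20L * config$pa_patch_count) {
      iter <- iter + 1L
      a <- nominal_deg2 * stats::rlnorm(1, 0, 0.4)
      # shrink when close to the target so the union cannot overshoot
      remaining <- (target + 0.015 - cov) * (ext[3L] - ext[1L]) * (ext[4L] - ext[2L])
      a <- min(a, max(remaining, 1e-6))
      aspect <- stats::rlnorm(1, 0, 0.3)
      wdeg <- sqrt(a * aspect); hdeg <- sqrt(a / aspect)
      cx <- stats::runif(1, ext[1L], ext[3L])
      cy <- stats::runif(1, ext[2L], ext[4L])
      r <- c(max(ext[1L], cx - wdeg / 2), max(ext[2L], cy - hdeg / 2),
             min(ext[3L], cx + wdeg / 2), min(ext[4L], cy + hdeg / 2))
      if (r[3L] - r[1L] < 1e-6 || r[4L] - r[2L] < 1e-6) next
      rects <- rbind(rects, r)
      cov <- rect_union_area_km2(rects) / region_area
    }
    lapply(seq_len(nrow(rects)), function(i)
      croc_range(sprintf("pa_%03d", i),
                 geom_rect(rects[i, 1L], rects[i, 2L], rects[i, 3L], rects[i, 4L]),
                 "synthetic"))
  })
}

#' Generate a nutrient-retention surface coupled to richness
#'
#' Per masked cell: `nutrient = c * z(TD) + sqrt(1 - c^2) * noise_sd * eps`
#' with `c` the configured coupling, `z` the richness z-score and `eps`
#' standard normal. With `noise_sd = 1` the expected Pearson correlation
#' with per-cell richness is approximately `c` (exactly 1 when `c = 1`).
#'
#' @param config a [synth_config()].
#' @param grid the analysis grid.
#' @param presence binary cells x species matrix on that grid.
#' @return named numeric vector of nutrient values over the masked cells.
#' @export
generate_nutrient <- function(config, grid, presence) {
  td <- rowSums(presence)
  z <- if (stats::sd(td) > 0) as.numeric(scale(td)) else rep(0, length(td))
  cc <- config$nutrient_coupling
  eps <- with_seed(child_seed(config$seed, "nutrient"),
                   stats::rnorm(length(td)))
  stats::setNames(cc * z + sqrt(1 - cc^2) * config$noise_sd * eps,
                  rownames(presence))
}

#' Assign IUCN statuses from range sizes
#'
#' The smallest-range quantile of species becomes CR, the next EN, the next
#' VU, the rest LC; cut points come from `config$status_quantiles`. Ties in
#' range size break by species id order.
#'
#' @param config a [synth_config()].
#' @param species_ids species identifiers.
#' @param range_sizes range sizes (cells) aligned with `species_ids`.
#' @return data.frame `species_id, iucn_category` (empty for zero species).
#' @export
assign_status <- function(config, species_ids, range_sizes) {
  n <- length(species_ids)
  if (n == 0L)
    return(data.frame(species_id = character(0), iucn_category = character(0)))
  stopifnot(length(range_sizes) == n)
  q <- config$status_quantiles
  counts <- diff(c(0, round(q * n)))
  counts <- c(counts, n - sum(counts))           # remainder -> LC
  o <- order(range_sizes, species_ids)
  cat_by_rank <- rep(c("CR", "EN", "VU", "LC"), times = pmax(0L, counts))
  catv <- character(n)
  catv[o] <- cat_by_rank
  data.frame(species_id = species_ids, iucn_category = catv,
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic input bundle
#'
#' Generates every pipeline input from one configuration and writes it to a
#' directory: `ranges.csv` (WKT), `traits.csv` + `traits_schema.yml`,
#' `tree.nwk`, `pa.csv` (WKT), `nutrient.asc`, `status.csv`, `realms.csv`
#' (three longitudinal realm bands) and `config.yml`.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @param drop_tips species to leave off the tree (default 1, emulating a
#'   phylogeny that misses one species).
#' @return invisibly, a named list of the written paths.
#' @export
simulate_bundle <- function(config, dir, drop_tips = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  grid <- build_grid(config$extent, config$resolution_deg)
  ranges <- generate_ranges(config)
  write_ranges(ranges, p("ranges.csv"))
  traits <- generate_traits(config)
  write_traits(traits, p("traits.csv"), p("traits_schema.yml"))
  tree <- generate_tree(config, drop_tips = min(drop_tips, config$n_species - 2L))
  ape::write.tree(tree, p("tree.nwk"))
  pa <- generate_pa(config, grid)
  write_ranges(pa, p("pa.csv"))
  presence <- rasterize_ranges(ranges, grid)
  nutrient <- generate_nutrient(config, grid, presence)
  write_asc_raster(grid_values_to_raster(nutrient, grid), p("nutrient.asc"))
  sizes <- vapply(names(ranges), function(sp)
    if (sp %in% colnames(presence)) sum(presence[, sp]) else 0L, 0)
  status <- assign_status(config, names(ranges), sizes)
  write_table(status, p("status.csv"))
  write_table(realm_bands_table(config$extent), p("realms.csv"))
  cfg <- unclass(config)
  cfg$status_quantiles <- as.list(cfg$status_quantiles)
  yaml::write_yaml(cfg, p("config.yml"))
  invisible(list(dir = dir, ranges = p("ranges.csv"), traits = p("traits.csv"),
                 traits_schema = p("traits_schema.yml"), tree = p("tree.nwk"),
                 pa = p("pa.csv"), nutrient = p("nutrient.asc"),
                 status = p("status.csv"), realms = p("realms.csv"),
                 config = p("config.yml")))
}

# three equal longitudinal bands used as synthetic realms
realm_bands_table <- function(extent) {
  xs <- seq(extent[1L], extent[3L], length.out = 4L)
  nm <- c("realm_west", "realm_center", "realm_east")
  data.frame(
    name = nm,
    wkt = vapply(1:3, function(i)
      geom_to_wkt(geom_rect(xs[i], extent[2L], xs[i + 1L], extent[4L])), ""),
    stringsAsFactors = FALSE)
}
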