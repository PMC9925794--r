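# End-to-end orchestration: read a (possibly synthetic) input bundle, build
# the grid and presence matrix, compute diversity, run the null models, the
# MPO gap analysis, the prioritization models and the realm correlations,
# writing every stage's output as a plain inspectable file plus a manifest.

#' Assign grid cells to named regions
#'
#' Locates each masked cell's center in the region polygons (even-odd rule);
#' a center falling in no polygon (e.g. exactly on a shared boundary) is
#' assigned to the region with the nearest bounding-box center.
#'
#' @param grid a `croc_grid`.
#' @param region_polygons named list of `croc_geom`.
#' @return named character vector (names = cell ids).
#' @export
assign_cells_to_regions <- function(grid, region_polygons) {
  ct <- cell_centers(grid)
  out <- rep(NA_character_, nrow(ct))
  for (rg in names(region_polygons)) {
    g <- region_polygons[[rg]]
    hit <- is.na(out) &
      vapply(seq_len(nrow(ct)),
             function(i) point_in_geom(ct[i, 1L], ct[i, 2L], g), TRUE)
    out[hit] <- rg
  }
  if (anyNA(out)) {
    centers <- vapply(region_polygons, function(g) {
      bb <- geom_bbox(g)
      c((bb[1L] + bb[3L]) / 2, (bb[2L] + bb[4L]) / 2)
    }, numeric(2))
    for (i in which(is.na(out))) {
      d2 <- (centers[1L, ] - ct[i, 1L])^2 + (centers[2L, ] - ct[i, 2L])^2
      out[i] <- names(region_polygons)[which.min(d2)]
    }
  }
  stats::setNames(out, as.character(grid$mask))
}

read_region_polygons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(lapply(df$wkt, wkt_to_geom), df$name)
}

#' Run the full diversity / gap-analysis / prioritization pipeline
#'
#' Sequences every stage on an input bundle (see [simulate_bundle()] for the
#' expected files): grid construction, rasterization, PA coverage, TD/FD/PD,
#' diversity correlations, FD/PD null models, species MPO representation,
#' priority mapping and realm-level nutrient correlations. Each stage writes
#' a plain CSV/raster/Newick file into `out_dir`; a `manifest.json` records
#' the configuration, seeds, input checksums and stage row counts. Reruns
#' with identical inputs and seeds are identical.
#'
#' @param bundle_dir directory containing the input bundle.
#' @param out_dir output directory (created).
#' @param fd_pd_reps replicates for the FD/PD swap null.
#' @param mpo_reps replicates for the MPO null.
#' @param seed integer seed for all stochastic stages.
#' @param null_algorithm passed to [fd_pd_null()].
#' @param priority_cfg a [priority_config()].
#' @param rule rasterization rule, see [rasterize_ranges()].
#' @return an object of class `croc_run` (stage tables + paths).
#' @export
run_pipeline <- function(bundle_dir, out_dir,
                         fd_pd_reps = 199L, mpo_reps = 1000L, seed = 1L,
                         null_algorithm = "independent_swap",
                         priority_cfg = priority_config(),
                         rule = "any_intersection") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bp <- function(f) {
    fp <- file.path(bundle_dir, f)
    if (!file.exists(fp)) stop("missing input '", f, "' in ", bundle_dir)
    fp
  }
  op <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  cfg <- stage("config", yaml::read_yaml(bp("config.yml")))
  grid <- stage("grid", build_grid(unlist(cfg$extent), cfg$resolution_deg))
  ranges <- stage("ranges", read_ranges(bp("ranges.csv")))
  presence <- stage("rasterize", rasterize_ranges(ranges, grid, rule = rule))
  message(sprintf("rasterized %d species onto %d cells",
                  ncol(presence), nrow(presence)))

  pa <- stage("coverage", read_ranges(bp("pa.csv")))
  coverage <- stage("coverage", pa_coverage(pa, grid))
  write_grid_csv(coverage, grid, op("pa_coverage.csv"))

  traits <- stage("traits", read_traits(bp("traits.csv"), bp("traits_schema.yml")))
  dendro <- stage("diversity", upgma(gower_distance(traits)))
  ape::write.tree(dendro, op("dendrogram.nwk"))
  tree <- stage("diversity", suppressMessages(read_newick(bp("tree.nwk"))))
  div <- stage("diversity", cell_diversity(presence, dendro, tree))
  write_table(div, op("cell_diversity.csv"))
  divcor <- stage("diversity", pairwise_diversity_correlation(div))
  write_table(divcor, op("diversity_correlations.csv"))

  nulls <- stage("nulls", fd_pd_null(presence, dendro, tree,
                                     n_reps = fd_pd_reps,
                                     seed = child_seed(seed, "fdpd"),
                                     algorithm = null_algorithm))
  write_table(nulls, op("fd_pd_null.csv"))

  realms <- stage("mpo", read_region_polygons(bp("realms.csv")))
  region_of <- stage("mpo", assign_cells_to_regions(grid, realms))
  status <- stage("mpo", read_status(bp("status.csv")))
  rep_tab <- stage("mpo", representation_table(
    presence, coverage, region_of, status,
    n_reps = mpo_reps, seed = child_seed(seed, "mpo")))
  write_table(rep_tab, op("representation.csv"))

  prio <- stage("prioritize", prioritize(div, presence, status, priority_cfg))
  write_table(prio, op("priority.csv"))
  prio_num <- stats::setNames(
    suppressWarnings(as.numeric(ifelse(prio$level == "none", NA, prio$level))),
    as.character(prio$cell_id))
  write_asc_raster(grid_values_to_raster(prio_num, grid), op("priority.asc"))

  nutrient <- stage("correlate", {
    ras <- read_asc_raster(bp("nutrient.asc"))
    aggregate_raster_to_grid(ras, grid)
  })
  regcor <- stage("correlate", region_correlation(div, nutrient, region_of))
  write_table(regcor, op("region_correlation.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("crocdiv")),
    seed = seed, fd_pd_reps = fd_pd_reps, mpo_reps = mpo_reps,
    null_algorithm = null_algorithm, rule = rule,
    config = cfg,
    input_md5 = as.list(tools::md5sum(list.files(bundle_dir, full.names = TRUE))),
    n_species = ncol(presence), n_cells = nrow(presence),
    n_priority = sum(prio$level != "none"))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(dir = out_dir, grid = grid, presence = presence,
                 coverage = coverage, diversity = div,
                 diversity_correlations = divcor, nulls = nulls,
                 representation = rep_tab, priority = prio,
                 region_correlation = regcor, manifest = manifest),
            class = "croc_run")
}

#' @export
print.croc_run <- function(x, ...) {
  cat(sprintf("<croc_run: %d species x %d cells, %d priority cells; outputs in %s>\n",
              x$manifest$n_species, x$manifest$n_cells,
              x$manifest$n_priority, x$dir))
  invisible(x)
}

#' @export
summary.croc_run <- function(object, ...) {
  cat(report(object), sep = "\n")
  invisible(object)
}

#' Plain-text run report
#'
#' Species counts, MPO flag percentages, priority-cell counts per model and
#' the realm ranking of richness-nutrient correlations, one species per line.
#'
#' @param run a `croc_run` object or a run directory.
#' @return character vector of report lines (also suitable for `cat()`).
#' @export
report <- function(run) {
  if (is.character(run)) {
    rd <- run
    rep_tab <- read_table(file.path(rd, "representation.csv"))
    prio <- read_table(file.path(rd, "priority.csv"))
    regcor <- read_table(file.path(rd, "region_correlation.csv"))
  } else {
    rep_tab <- run$representation
    prio <- run$priority
    regcor <- run$region_correlation
  }
  s <- summarize_representation(rep_tab)
  lines <- c(
    sprintf("species analyzed: %d", nrow(rep_tab)),
    sprintf("MPO flags: %.1f%% lower, %.1f%% higher, %.1f%% non-significant",
            s$pct_lower, s$pct_higher, s$pct_ns),
    "per-species representation:",
    sprintf("  %-10s realm=%-14s MPO=%6.3f null=%6.3f flag=%-14s %s pattern=%s",
            rep_tab$species_id, rep_tab$realm, rep_tab$mpo_observed,
            rep_tab$mpo_null_mean, rep_tab$flag, rep_tab$iucn_category,
            rep_tab$pattern))
  cnt <- table(factor(prio$level, levels = c("1", "2", "3", "none")))
  lines <- c(lines, sprintf("priority cells: model1=%d model2=%d model3=%d none=%d",
                            cnt[["1"]], cnt[["2"]], cnt[["3"]], cnt[["none"]]))
  td <- regcor[regcor$metric == "TD", , drop = FALSE]
  if (nrow(td)) {
    td <- td[order(-ifelse(is.na(td$r_squared), -Inf, td$r_squared)), ]
    lines <- c(lines, "richness vs nutrient retention by realm (r^2 ranked):",
               sprintf("  %-14s r=%6.3f r^2=%6.3f", td$region, td$pearson_r,
                       td$r_squared))
  }
  lines
}
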