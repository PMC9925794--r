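test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config(n_species = 5, extent = c(0, 0, 10, 10),
                      range_size_median_cells = 15, pa_patch_count = 10,
                      pa_target_coverage = 0.2, seed = 3)
  r1 <- generate_ranges(cfg); r2 <- generate_ranges(cfg)
  expect_identical(lapply(r1, function(r) geom_to_wkt(r$geom)),
                   lapply(r2, function(r) geom_to_wkt(r$geom)))
  expect_identical(generate_traits(cfg), generate_traits(cfg))
  expect_identical(ape::write.tree(generate_tree(cfg)),
                   ape::write.tree(generate_tree(cfg)))
  g <- build_grid(cfg$extent, cfg$resolution_deg)
  p1 <- generate_pa(cfg, g); p2 <- generate_pa(cfg, g)
  expect_identical(lapply(p1, function(r) geom_to_wkt(r$geom)),
                   lapply(p2, function(r) geom_to_wkt(r$geom)))
  # different seeds change the draw
  cfg2 <- synth_config(n_species = 5, extent = c(0, 0, 10, 10),
                       range_size_median_cells = 15, seed = 4)
  expect_false(identical(geom_to_wkt(generate_ranges(cfg2)[[1]]$geom),
                         geom_to_wkt(r1[[1]]$geom)))
})

test_that("a forced one-cell range is exactly one grid cell", {
  cfg <- synth_config(n_species = 1, extent = c(0, 0, 5, 5),
                      range_size_median_cells = 1, range_size_sigma = 0, seed = 2)
  r <- generate_ranges(cfg)[[1]]
  g <- build_grid(cfg$extent, cfg$resolution_deg)
  expect_equal(geom_area_km2(r$geom),
               cell_area_km2(g, crocdiv:::cells_touched(g, r$geom)),
               tolerance = 1e-9)
  expect_length(crocdiv:::cells_touched(g, r$geom), 1L)
})

test_that("ranges concentrate around the configured latitudinal peak", {
  cfg <- synth_config(n_species = 50, extent = c(0, -40, 40, 40),
                      resolution_deg = 1, range_size_median_cells = 30,
                      richness_peak_lat = 0, richness_decay_deg = 15, seed = 9)
  g <- build_grid(cfg$extent, cfg$resolution_deg)
  m <- rasterize_ranges(generate_ranges(cfg), g)
  lat <- cell_centers(g)[, "lat"]
  rich <- rowSums(m)
  expect_gt(mean(rich[abs(lat) <= 10]), mean(rich[abs(lat) >= 30]))
})

test_that("trait draws respect their declared kinds", {
  cfg <- synth_config(n_species = 20, extent = c(0, 0, 10, 10), seed = 5)
  tr <- generate_traits(cfg)
  sch <- attr(tr, "schema")
  for (nm in names(sch)) {
    kind <- sch[[nm]]$kind
    if (kind == "binary") expect_true(all(tr[[nm]] %in% c(0, 1)), info = nm)
    if (kind == "continuous") expect_gt(diff(range(tr[[nm]])), 0)
    if (kind == "categorical") expect_true(all(tr[[nm]] %in% sch[[nm]]$levels), info = nm)
  }
})

test_that("pure-birth trees have the requested tips and positive lengths", {
  cfg <- synth_config(n_species = 2, extent = c(0, 0, 5, 5), seed = 1)
  tr <- generate_tree(cfg)
  expect_equal(ape::Ntip(tr), 2L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  cfg10 <- synth_config(n_species = 10, extent = c(0, 0, 5, 5), seed = 1)
  tr10 <- generate_tree(cfg10, drop_tips = 1)
  expect_equal(ape::Ntip(tr10), 9L)
  expect_true(all(tr10$edge.length > 0))
  expect_true(is.finite(sum(tr10$edge.length)) && sum(tr10$edge.length) > 0)
})

test_that("PA mosaics hit the target union coverage", {
  cfg0 <- synth_config(n_species = 1, extent = c(0, 0, 20, 20),
                       pa_target_coverage = 0, seed = 6)
  expect_length(generate_pa(cfg0), 0L)
  cfg <- synth_config(n_species = 1, extent = c(0, 0, 20, 20),
                      pa_target_coverage = 0.15, pa_patch_count = 40, seed = 6)
  g <- build_grid(cfg$extent, cfg$resolution_deg)
  pa <- generate_pa(cfg, g)
  cov <- pa_coverage(pa, g)
  areas <- cell_area_km2(g)
  realized <- sum(cov * areas) / sum(areas)
  expect_gte(realized, 0.13)
  expect_lte(realized, 0.17)
})

test_that("nutrient surfaces realize the configured coupling to richness", {
  base <- function(coupling, noise_sd = 1, seed = 12)
    synth_config(n_species = 25, extent = c(0, -10, 25, 15),
                 range_size_median_cells = 120, nutrient_coupling = coupling,
                 noise_sd = noise_sd, seed = seed)
  cfg <- base(0)
  g <- build_grid(cfg$extent, cfg$resolution_deg)   # 2500 cells
  m <- rasterize_ranges(generate_ranges(cfg), g)
  td <- rowSums(m)
  expect_gte(nrow(m), 2000)
  r0 <- cor(generate_nutrient(cfg, g, m), td)
  expect_lt(abs(r0), 0.1)
  r6 <- cor(generate_nutrient(base(0.6), g, m), td)
  expect_gte(r6, 0.55); expect_lte(r6, 0.65)
  r1 <- cor(generate_nutrient(base(1, noise_sd = 0), g, m), td)
  expect_equal(r1, 1, tolerance = 1e-12)
})

test_that("status assignment follows range-size quantiles with id tie-breaks", {
  cfg <- synth_config(n_species = 10, extent = c(0, 0, 5, 5),
                      status_quantiles = c(CR = 0.1, EN = 0.2, VU = 0.3))
  ids <- sprintf("sp%02d", 1:10)
  st <- assign_status(cfg, ids, rep(5, 10))
  expect_equal(sum(st$iucn_category == "CR"), 1L)
  expect_equal(st$iucn_category[st$species_id == "sp01"], "CR")  # tie -> id order
  expect_equal(sum(st$iucn_category == "EN"), 1L)
  expect_equal(sum(st$iucn_category == "VU"), 1L)
  st2 <- assign_status(cfg, ids, 10:1)
  expect_equal(st2$iucn_category[st2$species_id == "sp10"], "CR")  # smallest range
  expect_equal(nrow(assign_status(cfg, character(0), numeric(0))), 0L)
})
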