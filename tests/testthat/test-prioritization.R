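toy_cells <- function() {
  data.frame(cell_id = 0:3, TD = c(1, 2, 3, 10), FD = c(1, 2, 3, 10),
             PD = c(1, 2, 3, 10))
}

toy_presence_status <- function() {
  # CR species only in cell 3 (the 4th cell); EN and VU species everywhere
  m <- cbind(cr = c(0L, 0L, 0L, 1L), en = 1L, vu = 1L)
  rownames(m) <- as.character(0:3)
  list(presence = m,
       status = data.frame(species_id = c("cr", "en", "vu"),
                           iucn_category = c("CR", "EN", "VU")))
}

test_that("printed-equation thresholds evaluate as written", {
  tab <- toy_cells()
  cfg <- priority_config()
  thr1 <- thresholds(tab, cfg, 1)
  expect_equal(unname(thr1), rep(0.9 * 4 / 0.5, 3))          # 7.2
  thr2 <- thresholds(tab, cfg, 2)
  expect_equal(thr2[["FD"]], 0.7 * 4 / 0.7)                  # 4.0
  expect_equal(thr2[["PD"]], 0.7 * 4 / 0.5)                  # 5.6
  thr3 <- thresholds(tab, cfg, 3)
  expect_equal(unname(thr3), rep(0.5 * 4 / 1.0, 3))          # 2.0
  # documented consequence: with equal cells no cell can reach level 1
  flat <- data.frame(cell_id = 0:3, TD = 5, FD = 5, PD = 5)
  expect_true(all(flat$TD < thresholds(flat, cfg, 1)[["TD"]]))
  expect_error(thresholds(flat[0, ], cfg, 1), "empty")
})

test_that("quantile mode reads the thresholds as f-quantiles of nonzero cells", {
  tab <- toy_cells()
  cfg <- priority_config(mode = "normalized")
  expect_equal(thresholds(tab, cfg, 1)[["TD"]],
               unname(stats::quantile(tab$TD, 0.9)))
})

test_that("status presence flags cells carrying each threat category", {
  ps <- toy_presence_status()
  f <- status_presence(ps$presence, ps$status)
  expect_equal(unname(f[, "has_CR"]), c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(f[, "has_EN"]))
  # absent category -> all false -> model empty
  st0 <- data.frame(species_id = c("cr", "en", "vu"),
                    iucn_category = c("LC", "LC", "LC"))
  expect_false(any(status_presence(ps$presence, st0)))
})

test_that("the three models assign the toy grid exactly as hand-derived", {
  ps <- toy_presence_status()
  pm <- prioritize(toy_cells(), ps$presence, ps$status)
  expect_equal(pm$level, c("none", "3", "3", "1"))
  # empty status table -> empty map
  pm0 <- prioritize(toy_cells(), ps$presence,
                    data.frame(species_id = character(0),
                               iucn_category = character(0)))
  expect_true(all(pm0$level == "none"))
  # deterministic
  expect_identical(pm, prioritize(toy_cells(), ps$presence, ps$status))
})

test_that("literal subtraction re-admits higher-level cells to the level sets", {
  ps <- toy_presence_status()
  cfg_lit <- priority_config(cumulative_exclusion = FALSE)
  pm <- prioritize(toy_cells(), ps$presence, ps$status, cfg_lit)
  # the map still reports the highest level per cell
  expect_equal(pm$level, c("none", "3", "3", "1"))
})

test_that("priority levels are disjoint and candidate sets grow as f drops", {
  set.seed(17)
  n <- 200
  tab <- data.frame(cell_id = seq_len(n) - 1L, TD = rpois(n, 3),
                    FD = rexp(n), PD = rexp(n))
  m <- cbind(a = rbinom(n, 1L, 0.3), b = rbinom(n, 1L, 0.3),
             c = rbinom(n, 1L, 0.3))
  rownames(m) <- as.character(tab$cell_id)
  st <- data.frame(species_id = c("a", "b", "c"),
                   iucn_category = c("CR", "EN", "VU"))
  pm <- prioritize(tab, m, st)
  expect_true(all(table(pm$cell_id) == 1))
  cfg <- priority_config()
  cand <- function(f, div) {
    thr <- vapply(c("FD", "PD", "TD"), function(met)
      f * mean(tab[[met]]) / div, 0)
    which(tab$FD >= thr[1] & tab$PD >= thr[2] & tab$TD >= thr[3])
  }
  expect_true(all(cand(0.9, 0.5) %in% cand(0.7, 0.5)))
  expect_true(all(cand(0.7, 0.5) %in% cand(0.5, 0.5)))
})

test_that("regional area summaries conserve area and bound percentages", {
  g <- build_grid(c(0, 0, 2, 1), 0.5)
  pm <- data.frame(cell_id = c(0L, 1L), level = c("1", "1"))
  # one region equals exactly the two priority cells -> 100%
  regions <- list(hot = geom_rect(0, 0, 1, 0.5))
  tab <- area_by_region(pm, g, regions)
  expect_equal(tab$relative_pct, 100, tolerance = 1e-9)
  expect_equal(tab$area_km2, sum(cell_area_km2(g, 0:1)), tolerance = 1e-9)
  # two regions splitting one priority cell: areas sum to the cell's area
  pm1 <- data.frame(cell_id = 0L, level = "1")
  halves <- list(w = geom_rect(0, 0, 0.25, 1), e = geom_rect(0.25, 0, 2, 1))
  t2 <- area_by_region(pm1, g, halves)
  expect_equal(sum(t2$area_km2), cell_area_km2(g, 0L), tolerance = 1e-6)
  expect_true(all(t2$relative_pct >= 0 & t2$relative_pct <= 100))
  # region without priority cells is absent
  none <- area_by_region(pm1, g, list(far = geom_rect(1.5, 0.5, 2, 1)))
  expect_equal(nrow(none), 0L)
})
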