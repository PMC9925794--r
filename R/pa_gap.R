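# Protected-area gap analysis: species-level Mean Percentage Overlap (MPO)
# with the PA network, randomization nulls per realm, significance flags, and
# the four-way representativeness classification combining the flag with the
# species' IUCN threat category.

#' Mean Percentage Overlap of a species range with protected areas
#'
#' The mean, over the cells a species occupies, of the percentage of each
#' cell covered by the PA network.
#'
#' @param occupied_cells cell ids the species occupies.
#' @param coverage named per-cell PA coverage fractions in `[0, 1]`.
#' @return MPO in percent, in `[0, 100]`.
#' @export
mpo <- function(occupied_cells, coverage) {
  occupied_cells <- as.character(occupied_cells)
  if (length(occupied_cells) == 0L) stop("species occupies zero cells")
  v <- coverage[occupied_cells]
  if (anyNA(v)) stop("coverage undefined for some occupied cells")
  100 * mean(v)
}

#' Species representation table (MPO, null flags, pattern)
#'
#' For every species in the presence matrix: observed MPO, the randomization
#' null over its realm (see [mpo_null()]), the significance flag at `alpha`,
#' the IUCN category and the four-way representativeness pattern of
#' [classify_pattern()]. Each species' realm is the region containing the
#' majority of its occupied cells (ties broken alphabetically), and its null
#' resamples cells from that realm only.
#'
#' @param presence binary cells x species matrix.
#' @param coverage named per-cell PA coverage fractions.
#' @param region_assignment named character vector mapping cell ids to realm
#'   names.
#' @param status data.frame `species_id, iucn_category`.
#' @param n_reps randomization replicates (default 1000).
#' @param seed integer seed (per-species child seeds derive from it).
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `croc_representation`: `species_id, realm,
#'   n_cells, mpo_observed, mpo_null_mean, mpo_null_sd, p_low, p_high, ses,
#'   flag, iucn_category, pattern`.
#' @export
representation_table <- function(presence, coverage, region_assignment,
                                 status, n_reps = 1000L, seed = 1L,
                                 alpha = 0.05) {
  cells <- rownames(presence)
  if (!all(cells %in% names(region_assignment)))
    stop("region_assignment must cover every cell of the presence matrix")
  regions <- region_assignment[cells]
  status_of <- stats::setNames(status$iucn_category, status$species_id)
  rows <- lapply(colnames(presence), function(sp) {
    occ <- cells[presence[, sp] == 1L]
    tab <- sort(table(regions[occ]), decreasing = TRUE)
    realm <- names(tab)[tab == max(tab)][1L]        # ties: alphabetical first
    realm_cells <- cells[regions == realm]
    obs <- mpo(occ, coverage)
    nr <- mpo_null(length(occ), coverage, realm_cells, n_reps = n_reps,
                   seed = child_seed(seed, sp), alpha = alpha, observed = obs)
    iucn <- if (sp %in% names(status_of)) status_of[[sp]] else NA_character_
    data.frame(species_id = sp, realm = realm, n_cells = length(occ),
               mpo_observed = obs, mpo_null_mean = nr$null_mean,
               mpo_null_sd = nr$null_sd, p_low = nr$p_low, p_high = nr$p_high,
               ses = nr$ses, flag = nr$flag, iucn_category = iucn,
               pattern = classify_pattern(nr$flag, iucn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("croc_representation", "data.frame")
  out
}

#' Four-way representativeness pattern
#'
#' Combines the MPO null-model flag with the IUCN category:
#' \itemize{
#'   \item i  — threatened (CR/EN/VU), not significantly over-represented
#'     (flag `lower` or non-significant): the alarming cases;
#'   \item ii — non-threatened (NT/LC/DD), not significantly over-represented;
#'   \item iii — threatened and significantly `higher` than chance;
#'   \item iv — non-threatened and significantly `higher`.
#' }
#'
#' @param flag one of `lower`, `higher`, `ns_below_mean`, `ns_above_mean`
#'   (vectorized).
#' @param iucn_category IUCN category (vectorized).
#' @return character vector of patterns `"i".."iv"`.
#' @export
classify_pattern <- function(flag, iucn_category) {
  ok_flags <- c("lower", "higher", "ns_below_mean", "ns_above_mean")
  if (any(!flag %in% ok_flags))
    stop("invalid flag; expected one of: ", paste(ok_flags, collapse = ", "))
  threatened <- iucn_category %in% c("CR", "EN", "VU")
  higher <- flag == "higher"
  ifelse(threatened & !higher, "i",
         ifelse(!threatened & !higher, "ii",
                ifelse(threatened, "iii", "iv")))
}

#' Summarize representation flags
#'
#' Percentage of species flagged significantly lower, significantly higher,
#' and non-significant (the two ns flags pooled), truncated to one decimal.
#'
#' @param table a `croc_representation` table, or any data.frame with a
#'   `flag` column (values may also be the compact `-`, `+`, `ns` codes).
#' @return named list `pct_lower, pct_higher, pct_ns`.
#' @export
summarize_representation <- function(table) {
  stopifnot(nrow(table) > 0L, "flag" %in% names(table))
  f <- table$flag
  f[f == "-"] <- "lower"
  f[f == "+"] <- "higher"
  f[f %in% c("ns", "*", "ns_below_mean", "ns_above_mean")] <- "ns"
  n <- length(f)
  trunc1 <- function(x) floor(x * 10 + 1e-9) / 10
  list(pct_lower = trunc1(100 * sum(f == "lower") / n),
       pct_higher = trunc1(100 * sum(f == "higher") / n),
       pct_ns = trunc1(100 * sum(f == "ns") / n))
}
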