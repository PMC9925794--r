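# Randomization machinery: the independent-swap matrix null (and an
# unconstrained shuffle variant) for per-cell FD/PD significance, and the
# cell-resampling null for species MPO. Rank p-values are one-tailed in both
# directions, (#{null >= obs} + 1) / (n_reps + 1), so they can never be 0.

#' @useDynLib crocdiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# deterministic child seed from a parent seed and a tag (keeps components
# independently regenerable from one global seed); stays below 2^31
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

# run expr with a temporarily seeded R RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Independent-swap randomization of a presence/absence matrix
#'
#' Repeatedly samples 2x2 submatrices and flips checkerboards
#' (`[[1,0],[0,1]] <-> [[0,1],[1,0]]`), preserving every row sum (site
#' richness) and column sum (species frequency) exactly. Deterministic given
#' `seed`.
#'
#' @param presence binary matrix.
#' @param n_swaps attempted swaps; default `max(1000, 10 * fill)` where fill
#'   is the number of 1-entries.
#' @param seed integer seed for the swap chain.
#' @return randomized matrix with identical dimnames and margins. If no swap
#'   succeeds and the matrix is verifiably checkerboard-free, it is returned
#'   unchanged with a warning.
#' @export
independent_swap <- function(presence, n_swaps = NULL, seed = 1L) {
  storage.mode(presence) <- "integer"
  if (any(presence != 0L & presence != 1L)) stop("presence matrix must be binary")
  if (is.null(n_swaps)) n_swaps <- max(1000L, 10L * sum(presence))
  if (n_swaps < 1L) stop("n_swaps must be >= 1")
  out <- cpp_independent_swap(presence, as.integer(n_swaps), as.numeric(seed))
  if (attr(out, "successes") == 0L) {
    if (length(presence) <= 10000L && !has_checkerboard(presence))
      warning("matrix contains no checkerboard (swap-inert); returned unchanged")
    else if (length(presence) > 10000L)
      warning("no successful swap in ", n_swaps, " attempts")
  }
  dimnames(out) <- dimnames(presence)
  attr(out, "grid") <- attr(presence, "grid")
  out
}

has_checkerboard <- function(m) {
  nr <- nrow(m)
  if (nr < 2L || ncol(m) < 2L) return(FALSE)
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
    di <- m[i, ] - m[j, ]
    if (any(di == 1L) && any(di == -1L)) return(TRUE)
  }
  FALSE
}

# unconstrained shuffle: each species' occurrences are redistributed
# uniformly over cells (species frequency preserved, site richness not) —
# the "every species could occupy any grid cell" reading
unconstrained_shuffle <- function(presence, seed = 1L) {
  with_seed(seed, {
    out <- presence
    n <- nrow(presence)
    for (j in seq_len(ncol(presence))) out[, j] <- presence[sample.int(n), j]
    out
  })
}

null_flag <- function(p_low, p_high, observed, null_mean, alpha) {
  ifelse(p_high < alpha, "higher",
         ifelse(p_low < alpha, "lower",
                ifelse(observed >= null_mean, "ns_above_mean", "ns_below_mean")))
}

#' FD/PD null-model test per grid cell
#'
#' Randomizes the presence matrix `n_reps` times (each replicate an
#' independent randomization of the observed matrix), recomputes FD and PD
#' per cell, and compares the observed values against the null distribution
#' with one-tailed rank p-values in both directions. Flags at `alpha`:
#' `higher` / `lower` when significant, otherwise `ns_above_mean` /
#' `ns_below_mean` relative to the null mean.
#'
#' @param presence binary cells x species matrix.
#' @param dendrogram functional dendrogram (`phylo`) or `NULL` to skip FD.
#' @param tree phylogeny (`phylo`) or `NULL` to skip PD.
#' @param n_reps number of replicates (default 1000; < 100 warns).
#' @param seed integer seed; replicate r uses a derived child seed.
#' @param algorithm `"independent_swap"` (default) or
#'   `"unconstrained_shuffle"`.
#' @param alpha significance level (default 0.05).
#' @param n_swaps attempted swaps per replicate (see [independent_swap()]).
#' @param include_root branch-sum convention, see [subtree_branch_sum()].
#' @return data.frame of class `croc_null`: `cell_id, metric, observed,
#'   null_mean, null_sd, p_low, p_high, ses, n_reps, flag`.
#' @export
fd_pd_null <- function(presence, dendrogram = NULL, tree = NULL,
                       n_reps = 1000L, seed = 1L,
                       algorithm = c("independent_swap", "unconstrained_shuffle"),
                       alpha = 0.05, n_swaps = NULL, include_root = TRUE) {
  algorithm <- match.arg(algorithm)
  if (n_reps < 100L) warning("n_reps < 100 gives unstable p-values")
  storage.mode(presence) <- "integer"
  trees <- list(FD = dendrogram, PD = tree)
  trees <- trees[!vapply(trees, is.null, TRUE)]
  if (length(trees) == 0L) stop("supply a dendrogram and/or a tree")
  obs <- lapply(trees, function(tr) branch_sums_matrix(presence, tr, include_root))
  nc <- nrow(presence)
  acc <- lapply(trees, function(tr)
    list(sum = numeric(nc), sum2 = numeric(nc),
         n_ge = integer(nc), n_le = integer(nc)))
  eps <- 1e-9
  for (r in seq_len(n_reps)) {
    rs <- child_seed(seed, paste0("rep", r))
    mnull <- if (algorithm == "independent_swap")
      independent_swap(presence, n_swaps = n_swaps, seed = rs)
    else unconstrained_shuffle(presence, seed = rs)
    for (met in names(trees)) {
      v <- branch_sums_matrix(mnull, trees[[met]], include_root)
      acc[[met]]$sum <- acc[[met]]$sum + v
      acc[[met]]$sum2 <- acc[[met]]$sum2 + v * v
      acc[[met]]$n_ge <- acc[[met]]$n_ge + (v >= obs[[met]] - eps)
      acc[[met]]$n_le <- acc[[met]]$n_le + (v <= obs[[met]] + eps)
    }
  }
  rows <- lapply(names(trees), function(met) {
    a <- acc[[met]]
    mu <- a$sum / n_reps
    var <- pmax(0, a$sum2 / n_reps - mu^2) * n_reps / max(1, n_reps - 1)
    sd <- sqrt(var)
    p_high <- (a$n_ge + 1) / (n_reps + 1)
    p_low <- (a$n_le + 1) / (n_reps + 1)
    data.frame(cell_id = as.integer(rownames(presence)), metric = met,
               observed = obs[[met]], null_mean = mu, null_sd = sd,
               p_low = p_low, p_high = p_high,
               ses = ifelse(sd > 0, (obs[[met]] - mu) / sd, NA_real_),
               n_reps = n_reps,
               flag = null_flag(p_low, p_high, obs[[met]], mu, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("croc_null", "data.frame")
  out
}

#' MPO randomization null for one species
#'
#' Null distribution of the Mean Percentage Overlap for a species occupying
#' `n_occupied_cells` cells: each replicate draws that many cells uniformly
#' without replacement from the species' region (realm) and takes the mean
#' protected-area coverage x 100.
#'
#' @param n_occupied_cells the species' range size in cells.
#' @param coverage named per-cell PA coverage fractions (names = cell ids).
#' @param region_cells cell ids forming the sampling frame (default: all
#'   cells of `coverage`).
#' @param n_reps replicates (default 1000).
#' @param seed integer seed.
#' @param alpha significance level.
#' @param observed optionally, the observed MPO (percent); p-values and flag
#'   are computed when given.
#' @return one-row data.frame: `observed, null_mean, null_sd, p_low, p_high,
#'   ses, n_reps, flag` (p/ses/flag `NA` when `observed` is missing).
#' @export
mpo_null <- function(n_occupied_cells, coverage, region_cells = NULL,
                     n_reps = 1000L, seed = 1L, alpha = 0.05,
                     observed = NA_real_) {
  if (is.null(region_cells)) region_cells <- names(coverage)
  region_cells <- as.character(region_cells)
  if (n_occupied_cells < 1L) stop("species must occupy at least one cell")
  if (n_occupied_cells > length(region_cells))
    stop("n_occupied_cells exceeds the region's cell count")
  cov <- coverage[region_cells]
  if (anyNA(cov)) stop("coverage missing for some region cells")
  draws <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r)
      100 * mean(cov[sample.int(length(cov), n_occupied_cells)]), 0)
  })
  mu <- mean(draws); sd <- stats::sd(draws)
  eps <- 1e-9
  if (is.na(observed)) {
    p_low <- p_high <- ses <- NA_real_; flag <- NA_character_
  } else {
    p_high <- (sum(draws >= observed - eps) + 1) / (n_reps + 1)
    p_low <- (sum(draws <= observed + eps) + 1) / (n_reps + 1)
    ses <- if (sd > 0) (observed - mu) / sd else NA_real_
    flag <- null_flag(p_low, p_high, observed, mu, alpha)
  }
  data.frame(observed = observed, null_mean = mu, null_sd = sd,
             p_low = p_low, p_high = p_high, ses = ses,
             n_reps = n_reps, flag = flag, stringsAsFactors = FALSE)
}
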