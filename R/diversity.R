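# Per-cell diversity in three dimensions:
#   TD — taxonomic diversity, species richness per cell;
#   FD — Petchey-Gaston functional diversity: Gower distance on the trait
#        table -> UPGMA dendrogram -> branch-length sum over the species
#        present in a cell;
#   PD — Faith's phylogenetic diversity: the same branch-length sum on the
#        phylogeny.

#' Gower distance on a mixed-type trait table
#'
#' Pairwise dissimilarity `d(i,j) = sum_k w_k d_ijk delta_ijk / sum_k w_k
#' delta_ijk` where, per trait k, `d_ijk` is the range-normalized absolute
#' difference for continuous/ordinal traits and the 0/1 mismatch for
#' categorical/binary traits; `delta_ijk = 0` whenever either species has a
#' missing value (pairwise renormalization). Ranges are taken over the full
#' species pool so that a single global dendrogram is defined.
#'
#' @param traits a `croc_traits` table (or a data.frame with a `schema`
#'   attribute / explicit `schema` argument).
#' @param schema optional schema overriding `attr(traits, "schema")`.
#' @param weights optional named per-trait weights (default 1).
#' @return symmetric distance matrix in `[0, 1]` with zero diagonal,
#'   dimnames = species ids.
#' @export
gower_distance <- function(traits, schema = attr(traits, "schema"),
                           weights = NULL) {
  if (is.null(schema)) stop("a trait schema is required")
  sp <- rownames(traits)
  n <- length(sp)
  if (n < 2L) stop("at least two species are required")
  tr_names <- names(schema)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(tr_names)), tr_names)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (k in tr_names) {
    kind <- schema[[k]]$kind
    w <- weights[[k]] %||% 1
    v <- traits[[k]]
    obs <- !is.na(v)
    delta <- outer(obs, obs, "&")
    if (kind %in% c("continuous", "ordinal")) {
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("trait '", k, "' has zero range across species; excluded")
        next
      }
      vv <- v
      vv[is.na(vv)] <- 0  # masked by delta
      d <- abs(outer(vv, vv, "-")) / rng
    } else {
      vv <- as.character(v)
      vv[is.na(vv)] <- "\r<NA>"
      d <- outer(vv, vv, "!=") * 1
    }
    num <- num + w * d * delta
    den <- den + w * delta
  }
  if (any(den[upper.tri(den)] == 0))
    stop("species pair with no shared observed trait; Gower distance undefined")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(sp, sp)
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group average-linkage agglomeration. Node height is half
#' the merge distance, so the cophenetic distance between two leaves equals
#' their merge distance and the tree is ultrametric. When several pairs are
#' tied at the minimum distance, the pair whose sorted member labels are
#' lexicographically smallest is merged, making the output platform-stable.
#'
#' @param dist symmetric distance matrix (or `dist`) with species dimnames.
#' @return an ultrametric `phylo` dendrogram over the species.
#' @export
upgma <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 2L) stop("UPGMA requires at least two species")
  if (is.null(rownames(dist))) stop("distance matrix needs species dimnames")
  if (max(abs(dist - t(dist))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix diagonal must be zero")
  labels <- rownames(dist)
  d <- dist
  # active clusters: node id (tips 1..n, internal ids assigned at merge),
  # size, height, label = lexicographically smallest member (tie-breaking)
  cl <- data.frame(node = seq_len(n), size = 1L, height = 0,
                   label = labels, stringsAsFactors = FALSE)
  merges <- matrix(0L, n - 1L, 2L)   # children node ids
  heights <- numeric(n - 1L)
  child_h <- matrix(0, n - 1L, 2L)
  next_internal <- n + 1L
  for (step in seq_len(n - 1L)) {
    m <- nrow(cl)
    dm <- d
    dm[lower.tri(dm, diag = TRUE)] <- Inf
    dmin <- min(dm)
    cand <- which(dm <= dmin + 1e-15, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(ij) {
        lab <- sort(c(cl$label[ij[1L]], cl$label[ij[2L]]))
        paste(lab, collapse = "\r")
      })
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    h <- d[i, j] / 2
    merges[step, ] <- c(cl$node[i], cl$node[j])
    heights[step] <- h
    child_h[step, ] <- c(cl$height[i], cl$height[j])
    # average-linkage update
    si <- cl$size[i]; sj <- cl$size[j]
    dnew <- (si * d[i, ] + sj * d[j, ]) / (si + sj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    newlab <- min(cl$label[c(i, j)])
    cl <- rbind(cl[keep, , drop = FALSE],
                data.frame(node = next_internal, size = si + sj, height = h,
                           label = newlab, stringsAsFactors = FALSE))
    next_internal <- next_internal + 1L
  }
  # assemble a phylo: internal node k-th merge has provisional id n+k; ape
  # wants the root numbered n+1, so renumber merge k -> 2n - k
  remap <- function(v) ifelse(v <= n, v, 2L * n - (v - n))
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  for (k in seq_len(n - 1L)) {
    parent <- remap(n + k)
    for (c2 in 1:2) {
      idx <- 2L * (k - 1L) + c2
      edge[idx, ] <- c(parent, remap(merges[k, c2]))
      elen[idx] <- heights[k] - child_h[k, c2]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = labels, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Branch-length sum of the minimal spanning subtree
#'
#' Sum of edge lengths of the smallest subtree of `tree` connecting
#' `species_set` — Faith's PD when `tree` is a phylogeny, Petchey-Gaston FD
#' when it is the functional dendrogram. With `include_root = TRUE` (default)
#' the subtree is additionally connected to the root, so a singleton set
#' scores its root-to-leaf path length; with `FALSE` the subtree spans only
#' the set's most recent common ancestor and a singleton scores 0.
#'
#' @param tree a `phylo` with branch lengths.
#' @param species_set character vector of leaf labels; members absent from
#'   the tree are dropped with a warning.
#' @param include_root span the root as well as the set?
#' @return non-negative branch-length sum (0, with a warning, for an empty
#'   effective set).
#' @export
subtree_branch_sum <- function(tree, species_set, include_root = TRUE) {
  species_set <- unique(species_set)
  missing <- setdiff(species_set, tree$tip.label)
  if (length(missing)) {
    warning(length(missing), " species not in tree dropped: ",
            paste(missing, collapse = ", "))
    species_set <- setdiff(species_set, missing)
  }
  if (length(species_set) == 0L) {
    warning("empty effective species set; branch sum is 0")
    return(0)
  }
  tips <- match(species_set, tree$tip.label)
  parent_of <- integer(max(tree$edge))
  edge_to <- integer(max(tree$edge))          # edge index arriving at node
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_to[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  count <- integer(nrow(tree$edge))
  for (tip in tips) {
    node <- tip
    while (node != root) {
      e <- edge_to[node]
      count[e] <- count[e] + 1L
      node <- parent_of[node]
    }
  }
  on_path <- count > 0L
  if (!include_root) on_path <- on_path & count < length(tips)
  sum(tree$edge.length[on_path])
}

# edge x species incidence: E[e, s] = 1 if species s sits below edge e.
# Shared by cell_diversity() and the null models; one matrix product yields
# FD/PD for every cell at once.
edge_incidence <- function(tree, species) {
  ntip <- ape::Ntip(tree)
  E <- matrix(0L, nrow(tree$edge), length(species),
              dimnames = list(NULL, species))
  present <- intersect(species, tree$tip.label)
  if (length(present) == 0L) return(E)
  parent_of <- integer(max(tree$edge))
  edge_to <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_to[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  for (sp in present) {
    node <- match(sp, tree$tip.label)
    while (node != root) {
      E[edge_to[node], sp] <- 1L
      node <- parent_of[node]
    }
  }
  E
}

# branch sums for every row of a binary presence matrix via the incidence
# matrix; include_root semantics as in subtree_branch_sum()
branch_sums_matrix <- function(presence, tree, include_root = TRUE) {
  E <- edge_incidence(tree, colnames(presence))
  len <- tree$edge.length
  counts <- presence %*% t(E)                        # cells x edges
  in_tree <- colnames(presence) %in% tree$tip.label
  ntips <- as.vector(presence[, in_tree, drop = FALSE] %*%
                       rep(1L, sum(in_tree)))
  if (include_root) {
    as.vector((counts > 0) %*% len)
  } else {
    as.vector(((counts > 0) & sweep(counts, 1L, ntips, "<")) %*% len)
  }
}

#' Per-cell taxonomic, functional and phylogenetic diversity
#'
#' For every masked grid cell: TD = number of species present; FD = branch
#' sum of the functional dendrogram over the cell's species; PD = branch sum
#' of the phylogeny over the cell's species that are in the tree. The
#' dendrogram must cover every species in the presence matrix (FD is
#' undefined otherwise); the phylogeny may cover a subset, and excluded
#' species are reported once.
#'
#' @param presence binary cells x species matrix (see [rasterize_ranges()]).
#' @param dendrogram functional `phylo` dendrogram (or `NULL` to skip FD).
#' @param tree phylogenetic `phylo` (or `NULL` to skip PD).
#' @param include_root span the root in branch sums (Faith's convention)?
#' @return data.frame `cell_id, TD, FD, PD` of class `croc_diversity`.
#' @export
cell_diversity <- function(presence, dendrogram = NULL, tree = NULL,
                           include_root = TRUE) {
  sp <- colnames(presence)
  out <- data.frame(cell_id = as.integer(rownames(presence)),
                    TD = as.integer(rowSums(presence)))
  if (!is.null(dendrogram)) {
    absent <- setdiff(sp, dendrogram$tip.label)
    if (length(absent))
      stop("species absent from the functional dendrogram (FD undefined): ",
           paste(absent, collapse = ", "))
    out$FD <- branch_sums_matrix(presence, dendrogram, include_root)
  } else out$FD <- NA_real_
  if (!is.null(tree)) {
    absent <- setdiff(sp, tree$tip.label)
    if (length(absent))
      message("species absent from the phylogeny, excluded from PD: ",
              paste(absent, collapse = ", "))
    out$PD <- branch_sums_matrix(presence, tree, include_root)
  } else out$PD <- NA_real_
  class(out) <- c("croc_diversity", "data.frame")
  out
}

#' Correlations among the diversity dimensions
#'
#' Pearson correlation (with two-sided p) for each pair among TD, FD, PD over
#' non-empty cells, plus Spearman's rho and per-variable Shapiro-Wilk
#' normality p-values; when either variable fails normality at
#' `shapiro_alpha` the Spearman statistic is marked preferred (both are
#' always reported). Constant variables yield `NA` correlations.
#'
#' @param cell_table a `croc_diversity` table.
#' @param shapiro_alpha normality gate (default 0.05).
#' @return data.frame, one row per pair: `pair, n, pearson_r, pearson_p,
#'   spearman_rho, spearman_p, shapiro_p_x, shapiro_p_y, preferred`.
#' @export
pairwise_diversity_correlation <- function(cell_table, shapiro_alpha = 0.05) {
  tab <- cell_table[cell_table$TD > 0, , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 non-empty cells")
  pairs <- list(c("TD", "FD"), c("TD", "PD"), c("FD", "PD"))
  rows <- lapply(pairs, function(pr) {
    x <- tab[[pr[1L]]]; y <- tab[[pr[2L]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    shx <- shapiro_p(x); shy <- shapiro_p(y)
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(pair = paste(pr, collapse = "-"), n = length(x),
                        pearson_r = NA_real_, pearson_p = NA_real_,
                        spearman_rho = NA_real_, spearman_p = NA_real_,
                        shapiro_p_x = shx, shapiro_p_y = shy,
                        preferred = NA_character_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    rho <- stats::cor(x, y, method = "spearman")
    sp_p <- tryCatch(
      suppressWarnings(stats::cor.test(x, y, method = "spearman")$p.value),
      error = function(e) NA_real_)
    pref <- if (!is.na(shx) && !is.na(shy) &&
                (shx < shapiro_alpha || shy < shapiro_alpha)) "spearman" else "pearson"
    data.frame(pair = paste(pr, collapse = "-"), n = length(x),
               pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
               spearman_rho = rho, spearman_p = sp_p,
               shapiro_p_x = shx, shapiro_p_y = shy, preferred = pref)
  })
  do.call(rbind, rows)
}

# Shapiro-Wilk p on at most 5000 values (evenly thinned, deterministic)
shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) > 5000L) x <- x[round(seq(1L, length(x), length.out = 5000L))]
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}
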