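# Shared fixtures, built in code.

# the hand-checkable 3-leaf tree: ((A:1,B:1):1,C:2);
toy_tree <- function()
  suppressMessages(read_newick("((A:1,B:1):1,C:2);"))

# hand-agglomerable distances: d(A,B)=2, d(A,C)=d(B,C)=6
toy_dist <- function() {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3L, 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d
}

toy_traits <- function() {
  sch <- list(x = list(kind = "continuous"), b = list(kind = "binary"))
  structure(data.frame(x = c(0, 5, 10), b = c(0, 0, 1),
                       row.names = c("s1", "s2", "s3")),
            schema = sch, class = c("croc_traits", "data.frame"))
}

# independent oracle for subtree branch sums: union of root-to-tip node
# paths via ape::nodepath, then sum the lengths of the union's edges;
# without the root, drop edges lying on every tip's path
oracle_subtree_sum <- function(tree, set, include_root = TRUE) {
  set <- intersect(set, tree$tip.label)
  if (length(set) == 0L) return(0)
  root <- ape::Ntip(tree) + 1L
  paths <- lapply(match(set, tree$tip.label),
                  function(tip) ape::nodepath(tree, root, tip))
  edge_key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  path_edges <- lapply(paths, function(p)
    paste(p[-length(p)], p[-1L]))
  u <- unique(unlist(path_edges))
  if (!include_root) {
    shared <- Reduce(intersect, path_edges)
    u <- setdiff(u, shared)
  }
  sum(tree$edge.length[match(u, edge_key)])
}

# random binary matrix with no all-zero rows/cols
random_presence <- function(nr, nc, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nr * nc, 1L, p), nr, nc,
                dimnames = list(as.character(seq_len(nr) - 1L),
                                paste0("sp", seq_len(nc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# quiet wrappers
quiet_bundle <- function(...) suppressMessages(suppressWarnings(simulate_bundle(...)))
quiet_run <- function(...) suppressMessages(suppressWarnings(run_pipeline(...)))
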