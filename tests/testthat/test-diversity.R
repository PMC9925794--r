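test_that("Gower distance matches the direct formula on mixed traits", {
  d <- gower_distance(toy_traits())
  expect_equal(d["s1", "s2"], 0.25)   # (0.5 + 0)/2
  expect_equal(d["s1", "s3"], 1.00)   # (1 + 1)/2
  expect_equal(d["s2", "s3"], 0.75)   # (0.5 + 1)/2
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(isSymmetric(d))
})

test_that("Gower handles identical rows, all-mismatch binaries and missing data", {
  sch <- list(b1 = list(kind = "binary"), b2 = list(kind = "binary"))
  tr <- structure(data.frame(b1 = c(0, 1, 0), b2 = c(0, 1, 0),
                             row.names = c("x", "y", "z")),
                  schema = sch, class = c("croc_traits", "data.frame"))
  d <- gower_distance(tr)
  expect_equal(d["x", "y"], 1)       # differ in every binary trait
  expect_equal(d["x", "z"], 0)       # identical rows
  # missing values renormalize pairwise
  sch2 <- list(a = list(kind = "continuous"), b = list(kind = "continuous"))
  tr2 <- structure(data.frame(a = c(0, 10, NA), b = c(0, 0, 5),
                              row.names = c("x", "y", "z")),
                   schema = sch2, class = c("croc_traits", "data.frame"))
  d2 <- gower_distance(tr2)
  expect_equal(d2["x", "y"], 0.5)    # both traits observed: (1 + 0)/2
  expect_equal(d2["x", "z"], 1)      # only trait b observed: |0-5|/5
  # y and z share no observed trait: undefined, not silently 0
  tr3 <- structure(data.frame(a = c(10, NA), b = c(NA, 5),
                              row.names = c("y", "z")),
                   schema = sch2, class = c("croc_traits", "data.frame"))
  expect_error(suppressWarnings(gower_distance(tr3)), "no shared")
})

test_that("a zero-range trait is excluded with a warning", {
  sch <- list(a = list(kind = "continuous"), c0 = list(kind = "continuous"))
  tr <- structure(data.frame(a = c(0, 2), c0 = c(5, 5), row.names = c("x", "y")),
                  schema = sch, class = c("croc_traits", "data.frame"))
  expect_warning(d <- gower_distance(tr), "zero range")
  expect_equal(d["x", "y"], 1)
})

test_that("Gower agrees with cluster::daisy on complete mixed data", {
  skip_if_not_installed("cluster")
  set.seed(42)
  n <- 12
  df <- data.frame(c1 = rnorm(n), c2 = runif(n, 0, 100),
                   f1 = sample(c("a", "b", "c"), n, TRUE),
                   f2 = sample(c("u", "v"), n, TRUE),
                   row.names = sprintf("s%02d", 1:n), stringsAsFactors = FALSE)
  sch <- list(c1 = list(kind = "continuous"), c2 = list(kind = "continuous"),
              f1 = list(kind = "categorical"), f2 = list(kind = "categorical"))
  tr <- structure(df, schema = sch, class = c("croc_traits", "data.frame"))
  mine <- gower_distance(tr)
  df2 <- df; df2$f1 <- factor(df2$f1); df2$f2 <- factor(df2$f2)
  ref <- as.matrix(cluster::daisy(df2, metric = "gower"))
  expect_equal(mine, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("UPGMA reproduces the hand agglomeration and its edge lengths", {
  u <- upgma(toy_dist())
  expect_equal(sum(u$edge.length), 7)
  expect_equal(subtree_branch_sum(u, c("A", "B")), 4)  # 1 + 1 + 2
  # two species at distance d -> two edges of d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  u2 <- upgma(d2)
  expect_equal(sort(u2$edge.length), c(1.5, 1.5))
  # ultrametricity: all root-to-tip depths equal
  depths <- ape::node.depth.edgelength(u)[1:3]
  expect_lt(diff(range(depths)), 1e-9)
  # cophenetic distance equals the merge distance
  cop <- ape::cophenetic.phylo(u)
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 6)
})

test_that("UPGMA matches hclust average linkage on tie-free matrices", {
  set.seed(7)
  x <- matrix(rnorm(8 * 3), 8)
  rownames(x) <- letters[1:8]
  d <- as.matrix(dist(x))
  u <- upgma(d)
  h <- hclust(as.dist(d), method = "average")
  expect_equal(as.matrix(ape::cophenetic.phylo(u))[letters[1:8], letters[1:8]],
               as.matrix(cophenetic(h))[letters[1:8], letters[1:8]],
               tolerance = 1e-9)
})

test_that("equidistant species yield the same total length under any merge order", {
  labs <- letters[1:5]
  d <- matrix(0.6, 5, 5, dimnames = list(labs, labs)); diag(d) <- 0
  base_len <- sum(upgma(d)$edge.length)
  for (perm in list(rev(labs), sample(labs), sample(labs))) {
    dp <- d[perm, perm]
    expect_equal(sum(upgma(dp)$edge.length), base_len, tolerance = 1e-12)
  }
})

test_that("subtree branch sums match the worked tree examples", {
  tr <- toy_tree()
  expect_equal(subtree_branch_sum(tr, c("A", "B")), 3)
  expect_equal(subtree_branch_sum(tr, c("A", "B", "C")), 5)
  expect_equal(subtree_branch_sum(tr, "C"), 2)
  expect_equal(subtree_branch_sum(tr, "C", include_root = FALSE), 0)
  expect_warning(s <- subtree_branch_sum(tr, c("A", "Z")), "not in tree")
  expect_equal(s, subtree_branch_sum(tr, "A"))
  expect_warning(expect_warning(s0 <- subtree_branch_sum(tr, "Z"), "empty"),
                 "not in tree")
  expect_equal(s0, 0)
})

test_that("branch sums equal brute-force edge-union sums on random trees", {
  set.seed(3)
  for (n in 3:6) {
    tr <- ape::rtree(n)
    tips <- tr$tip.label
    subsets <- unlist(lapply(1:n, function(k)
      utils::combn(tips, k, simplify = FALSE)), recursive = FALSE)
    for (s in subsets) {
      expect_equal(subtree_branch_sum(tr, s), oracle_subtree_sum(tr, s),
                   tolerance = 1e-12)
      expect_equal(subtree_branch_sum(tr, s, include_root = FALSE),
                   oracle_subtree_sum(tr, s, include_root = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("branch sums agree with picante::pd as an external oracle", {
  skip_if_not_installed("picante")
  set.seed(5)
  tr <- ape::rtree(8)
  m <- random_presence(12, 8, seed = 5)
  colnames(m) <- tr$tip.label
  ref <- picante::pd(m, tr, include.root = TRUE)
  mine <- vapply(seq_len(nrow(m)),
                 function(i) subtree_branch_sum(tr, colnames(m)[m[i, ] == 1]), 0)
  expect_equal(mine, ref$PD, tolerance = 1e-10)
})

test_that("cell_diversity computes TD/FD/PD per cell including edge cases", {
  dend <- upgma(toy_dist())
  tr <- toy_tree()
  m <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 1, 1))
  dimnames(m) <- list(c("0", "1", "2"), c("A", "B", "C"))
  cd <- cell_diversity(m, dend, tr)
  expect_equal(cd$TD, c(0, 2, 3))
  expect_equal(cd$FD, c(0, 4, 7))
  expect_equal(cd$PD, c(0, 3, 5))
  # TD always equals row sums (cross-module invariant)
  expect_equal(cd$TD, unname(rowSums(m)))
  # species missing from the dendrogram is a hard error
  dend2 <- upgma(toy_dist()[1:2, 1:2])
  expect_error(cell_diversity(m, dend2, tr), "dendrogram")
  # species missing from the tree is tolerated and reported
  m4 <- cbind(m, D = c(0, 0, 1))
  d4 <- matrix(0.4, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                          c("A", "B", "C", "D")))
  diag(d4) <- 0
  expect_message(cd4 <- cell_diversity(m4, upgma(d4), tr), "excluded from PD")
  expect_equal(cd4$PD, cd$PD)
  expect_equal(cd4$TD[3], 4L)
})

test_that("matrix-route FD/PD equals the tree-walk route on random data", {
  set.seed(11)
  tr <- ape::rtree(7)
  m <- random_presence(15, 7, seed = 11)
  colnames(m) <- tr$tip.label
  cd <- cell_diversity(m, tr, tr)
  walk <- vapply(seq_len(nrow(m)),
                 function(i) subtree_branch_sum(tr, colnames(m)[m[i, ] == 1]), 0)
  expect_equal(cd$FD, walk, tolerance = 1e-12)
  expect_equal(cd$PD, walk, tolerance = 1e-12)
})

test_that("adding a species never decreases TD, FD or PD", {
  set.seed(13)
  tr <- ape::rtree(6)
  dend <- upgma(as.matrix(dist(matrix(rnorm(12), 6,
    dimnames = list(tr$tip.label, NULL)))))
  m <- random_presence(10, 6, seed = 13)
  colnames(m) <- tr$tip.label
  base <- cell_diversity(m, dend, tr)
  for (rep in 1:20) {
    i <- sample(nrow(m), 1); j <- sample(ncol(m), 1)
    if (m[i, j] == 1) next
    m2 <- m; m2[i, j] <- 1L
    aug <- cell_diversity(m2, dend, tr)
    expect_gte(aug$TD[i], base$TD[i])
    expect_gte(aug$FD[i], base$FD[i])
    expect_gte(aug$PD[i], base$PD[i])
    # bounded by the total tree lengths
    expect_lte(aug$FD[i], sum(dend$edge.length) + 1e-12)
    expect_lte(aug$PD[i], sum(tr$edge.length) + 1e-12)
  }
})

test_that("diversity correlations report Pearson, Spearman and normality gates", {
  tab <- data.frame(cell_id = 0:49, TD = rep(1:10, 5))
  tab$FD <- 2 * tab$TD
  tab$PD <- tab$TD + 0.5
  ct <- pairwise_diversity_correlation(tab)
  expect_equal(ct$pearson_r[ct$pair == "TD-FD"], 1, tolerance = 1e-12)
  expect_equal(ct$pearson_r[ct$pair == "FD-PD"], 1, tolerance = 1e-12)
  expect_true(all(c("spearman_rho", "shapiro_p_x", "preferred") %in% names(ct)))
  # constant variable -> NA, not NaN propagation
  tab$PD <- 3
  ct2 <- pairwise_diversity_correlation(tab)
  expect_true(is.na(ct2$pearson_r[ct2$pair == "TD-PD"]))
  expect_false(any(is.nan(ct2$pearson_r)))
})

test_that("constructed correlation strength is recovered on synthetic cells", {
  set.seed(21)
  n <- 3000
  td <- 1L + rpois(n, 4)
  z <- as.numeric(scale(td))
  fd <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  tab <- data.frame(cell_id = seq_len(n) - 1L, TD = td, FD = fd, PD = z)
  ct <- pairwise_diversity_correlation(tab)
  expect_equal(ct$pearson_r[ct$pair == "TD-FD"], 0.9, tolerance = 0.05)
})
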