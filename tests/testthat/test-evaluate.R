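test_that("PCA of a rank-1 matrix explains everything on component 1", {
  u <- c(1, -2, 3, 0.5)
  v <- c(2, 1, -1)
  x <- outer(u - mean(u), v)
  p <- expr_pca(x, 1)
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-10)
  expect_equal(p$residual_fraction, 0, tolerance = 1e-10)
})

test_that("scores and loadings reconstruct the matrix at full rank", {
  set.seed(60)
  x <- matrix(rnorm(8 * 6), 8, 6)
  xc <- sweep(x, 2, colMeans(x))
  p <- expr_pca(x, 6)
  expect_lt(max(abs(xc - p$scores %*% t(p$loadings))), 1e-8)
})

test_that("explained fractions match the covariance eigendecomposition", {
  set.seed(61)
  x <- matrix(rnorm(8 * 6), 8, 6)
  xc <- sweep(x, 2, colMeans(x))
  p <- expr_pca(x, 5)
  ev <- eigen(crossprod(xc), symmetric = TRUE)$values
  expect_equal(p$explained_fraction, (ev / sum(ev))[1:5], tolerance = 1e-10)
  # non-increasing and orthogonal scores
  expect_true(all(diff(p$explained_fraction) <= 1e-12))
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[lower.tri(g)])) / max(diag(g)), 1e-8)
})

test_that("PCA sign convention and truncation are deterministic", {
  set.seed(62)
  x <- matrix(rnorm(10 * 4), 10, 4)
  p1 <- expr_pca(x, 3)
  p2 <- expr_pca(x, 3)
  expect_identical(p1$scores, p2$scores)
  for (j in 1:3) {
    l <- p1$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # rank-deficient request warns and truncates
  xr1 <- outer(rnorm(6), rnorm(5))
  expect_warning(pr <- expr_pca(xr1, 3), "rank")
  expect_equal(ncol(pr$scores), 1)
  expect_error(expr_pca(x, 9), "exceeds")
})

test_that("identical samples merge first at height zero", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  tree <- hcluster(x, "euclidean", "average")
  expect_equal(tree$height[1], 0)
  expect_setequal(abs(tree$merge[1, ]), c(1, 2))
})

test_that("merge order matches a naive agglomeration oracle per linkage", {
  set.seed(63)
  coords <- matrix(rnorm(6 * 2), 6, 2,
                   dimnames = list(paste0("s", 1:6), NULL))
  for (linkage in c("average", "complete", "ward")) {
    tree <- hcluster(coords, "euclidean", linkage)
    oracle <- naive_agglomerate_oracle(coords, linkage)
    expect_identical(hclust_merge_sets(tree), oracle$merges,
                     label = paste("merge order,", linkage))
    expect_equal(tree$height, oracle$heights, tolerance = 1e-9,
                 label = paste("heights,", linkage))
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("pearson-distance topology ignores per-sample scaling", {
  set.seed(64)
  x <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("s", 1:5), NULL))
  t1 <- hcluster(x, "pearson", "average")
  t2 <- hcluster(x * 10, "pearson", "average")
  expect_identical(t1$merge, t2$merge)
  expect_equal(t1$height, t2$height, tolerance = 1e-12)
})

test_that("zero-variance samples are rejected under pearson distance", {
  x <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1))
  expect_error(hcluster(x, "pearson", "average"), "zero-variance.*a")
})

test_that("misclassification search equals brute force over injective mappings", {
  set.seed(65)
  for (i in 1:10) {
    n <- 12
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    while (length(unique(labels)) < 3)
      labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
    tree <- hcluster(x, "euclidean", "complete")
    ev <- count_misclassified(tree, setNames(labels, rownames(x)))
    expect_equal(ev$n_misclassified,
                 brute_force_misclassification(ev$assignment, labels))
    expect_length(ev$misclassified, ev$n_misclassified)
  }
})

test_that("well-separated classes cluster without error", {
  set.seed(66)
  lab <- rep(c("A", "B", "C"), c(6, 5, 4))
  x <- matrix(rnorm(15 * 10, sd = 0.2), 15, 10,
              dimnames = list(sprintf("s%02d", 1:15), NULL))
  x[lab == "B", ] <- x[lab == "B", ] + 4
  x[lab == "C", 1:5] <- x[lab == "C", 1:5] - 4
  ev <- count_misclassified(hcluster(x, "euclidean", "ward"),
                            setNames(lab, rownames(x)))
  expect_equal(ev$n_misclassified, 0)
  # the mapping is injective: three clusters, three distinct classes
  expect_equal(anyDuplicated(ev$mapping), 0L)
})

test_that("a single displaced sample is flagged by name", {
  set.seed(67)
  lab <- rep(c("A", "B", "C"), each = 5)
  x <- matrix(rnorm(15 * 8, sd = 0.2), 15, 8,
              dimnames = list(sprintf("s%02d", 1:15), NULL))
  x[lab == "B", ] <- x[lab == "B", ] + 5
  x[lab == "C", ] <- x[lab == "C", ] - 5
  x[3, ] <- x[8, ] + rnorm(8, sd = 0.1)  # an A sample inside cluster B
  ev <- count_misclassified(hcluster(x, "euclidean", "average"),
                            setNames(lab, rownames(x)))
  expect_equal(ev$n_misclassified, 1)
  expect_identical(ev$misclassified, "s03")
})

test_that("degenerate label settings behave", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  tree <- hcluster(x, "euclidean", "average")
  ev <- count_misclassified(tree, setNames(rep("Z", 4), paste0("s", 1:4)),
                            k_clusters = 1)
  expect_equal(ev$n_misclassified, 0)
  expect_error(count_misclassified(tree, setNames(rep("Z", 4),
                                                  paste0("s", 1:4)),
                                   k_clusters = 0), "k_clusters")
})

test_that("misclassification count ignores label renaming and sample order", {
  set.seed(68)
  lab <- sample(rep(c("A", "B", "C"), c(5, 4, 6)))
  x <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(sprintf("s%02d", 1:15), NULL))
  tree <- hcluster(x, "euclidean", "average")
  ev1 <- count_misclassified(tree, setNames(lab, rownames(x)))
  renamed <- c(A = "zebra", B = "yak", C = "xerus")[lab]
  ev2 <- count_misclassified(tree, setNames(renamed, rownames(x)))
  expect_equal(ev1$n_misclassified, ev2$n_misclassified)
  shuffled <- setNames(lab, rownames(x))[sample(15)]
  ev3 <- count_misclassified(tree, shuffled)
  expect_equal(ev1$n_misclassified, ev3$n_misclassified)
})

test_that("two nested 2-cluster cuts reproduce the 3-cluster result", {
  set.seed(69)
  lab <- rep(c("B1", "B2", "OUT"), c(6, 6, 6))
  x <- matrix(rnorm(18 * 8, sd = 0.3), 18, 8,
              dimnames = list(sprintf("s%02d", 1:18), NULL))
  x[lab == "OUT", ] <- x[lab == "OUT", ] + 8
  x[lab == "B2", 1:4] <- x[lab == "B2", 1:4] + 3
  tree <- hcluster(x, "euclidean", "ward")
  three <- cutree(tree, 3)
  two <- cutree(tree, 2)
  # the super-class branch (the 2-cut cluster holding B1+B2) splits into
  # the same two groups the 3-cut finds
  super_cluster <- two[lab == "B1"][1]
  super <- names(two)[two == super_cluster]
  sub_tree <- hcluster(x[super, ], "euclidean", "ward")
  sub_two <- cutree(sub_tree, 2)
  agree <- table(sub_two, three[super])
  expect_equal(sum(agree > 0), 2)  # a one-to-one correspondence
  ev <- count_misclassified(tree, setNames(lab, rownames(x)))
  expect_equal(ev$n_misclassified, 0)
})

test_that("a marker panel separates classes better than the full matrix", {
  d <- synthetic_preprocessed(seed = 13, n_genes = 400, n_markers_up = 5,
                              n_markers_down = 5)
  sel <- parallel_ovr_select(d$pp, class_scheme("parallel",
                                                c("ALL-B", "ALL-T", "AML")),
                             n_ortho = 1, k_per_model = 10)
  panel <- em_subset(d$pp, genes = unique(sel$gene_id))
  p_panel <- expr_pca(panel, 1)
  p_full <- expr_pca(d$pp, 1)
  sep_panel <- class_separation(p_panel$scores[, 1], panel$labels)
  sep_full <- class_separation(p_full$scores[, 1], d$pp$labels)
  expect_gt(sep_panel, sep_full)
})

test_that("dendrograms export to Newick", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  tree <- hcluster(x, "euclidean", "average")
  nwk <- tree_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("s", 1:4))
  f <- tempfile(fileext = ".nwk")
  tree_newick(tree, f)
  expect_identical(readLines(f), nwk)
})
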