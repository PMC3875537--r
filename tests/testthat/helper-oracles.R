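# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (explicit loops, textbook algorithms)
# and never call into the package's own computational paths.

# Textbook NIPALS-PLS1, one latent component: iterate w <- X'u / ||X'u||,
# t <- Xw, q <- t'u / t't, u <- yq / q^2 until t stabilizes. With a single
# response the loop converges immediately, but we run it as written.
nipals_pls1_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- sweep(X, 2, colMeans(X))
  y <- y - mean(y)
  u <- y
  t_old <- rep(Inf, nrow(X))
  for (i in seq_len(max_iter)) {
    w <- drop(crossprod(X, u))
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    q <- sum(t * u) / sum(t^2)
    u <- y * q / q^2
    if (sqrt(sum((t - t_old)^2)) < tol) break
    t_old <- t
  }
  b <- sum(t * y) / sum(t^2)
  list(w = w, t = t, b = b, r2y = 1 - sum((y - b * t)^2) / sum(y^2))
}

# Direct per-gene evaluation of the S-plot formulas:
# cov_g = t' X_g / (N - 1);  corr_g = cov_g / (s_t * s_Xg)
naive_splot_oracle <- function(t, Xc) {
  n <- length(t)
  s_t <- sqrt(sum((t - mean(t))^2) / (n - 1))
  out <- data.frame(cov = numeric(ncol(Xc)), corr = numeric(ncol(Xc)))
  for (g in seq_len(ncol(Xc))) {
    xg <- Xc[, g]
    cv <- sum(t * xg) / (n - 1)
    s_x <- sqrt(sum((xg - mean(xg))^2) / (n - 1))
    out$cov[g] <- cv
    out$corr[g] <- if (s_x < 1e-12) 0 else cv / (s_t * s_x)
  }
  out
}

# Naive agglomerative clustering from the linkage definitions: clusters
# start as singletons; at each step the pair with the smallest
# cluster-to-cluster dissimilarity merges. Returns the merge order as a
# list of member-index sets plus the merge heights.
naive_agglomerate_oracle <- function(coords, linkage) {
  d <- as.matrix(dist(coords))
  clusters <- lapply(seq_len(nrow(coords)), identity)
  link <- function(a, b) {
    pairs <- d[a, b, drop = FALSE]
    switch(linkage,
           average = mean(pairs),
           complete = max(pairs),
           ward = {
             ca <- colMeans(coords[a, , drop = FALSE])
             cb <- colMeans(coords[b, , drop = FALSE])
             # ward.D2 height metric on Euclidean coordinates
             sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
                    sum((ca - cb)^2))
           })
  }
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- link(clusters[[i]], clusters[[j]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# member sets at each hclust merge step, for comparison with the oracle
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    members <- function(k) if (k < 0) -k else sets[[k]]
    sets[[i]] <- sort(c(members(tree$merge[i, 1]),
                        members(tree$merge[i, 2])))
  }
  sets
}

# Brute-force minimum misclassification over every injective
# cluster -> class mapping (independent of the package's search).
brute_force_misclassification <- function(assignment, labels) {
  classes <- sort(unique(labels))
  clusters <- sort(unique(assignment))
  grid <- expand.grid(rep(list(classes), length(clusters)),
                      stringsAsFactors = FALSE)
  grid <- grid[apply(grid, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    mapped <- unlist(grid[i, ])[match(assignment, clusters)]
    best <- min(best, sum(mapped != labels))
  }
  best
}
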