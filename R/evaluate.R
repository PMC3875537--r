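#' Principal component analysis of a centered expression matrix
#'
#' Computed by singular value decomposition of the centered samples x
#' genes matrix: \eqn{X = T P^T + E} with scores \eqn{T = U D}, loadings
#' \eqn{P = V}, and residual E beyond the requested components. The sign
#' of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param x samples x genes matrix, or an \code{expr_matrix} in state
#'   \code{"centered"} (or \code{"log10"}, centered internally).
#' @param n_components number of components; truncated to the matrix rank
#'   with a warning when it exceeds it.
#' @return An object of class \code{"expr_pca"}: \code{scores} (samples x
#'   components), \code{loadings} (genes x components),
#'   \code{explained_fraction}, \code{residual_fraction},
#'   \code{singular_values}.
#' @export
expr_pca <- function(x, n_components = 2) {
  xm <- .as_sample_gene_matrix(x)
  xm <- sweep(xm, 2, colMeans(xm))
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > min(dim(xm)))
    stop("n_components exceeds min(samples, genes)")
  sv <- svd(xm)
  tol <- max(dim(xm)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated")
    n_components <- rank
  }
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components),
                  2, flip, "*")
  loadings <- sweep(sv$v[, k, drop = FALSE], 2, flip, "*")
  total <- sum(sv$d^2)
  expl <- sv$d[k]^2 / total
  dimnames(scores) <- list(rownames(xm), paste0("PC", k))
  dimnames(loadings) <- list(colnames(xm), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 explained_fraction = expl,
                 residual_fraction = 1 - sum(expl),
                 singular_values = sv$d[k]),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat(sprintf("<expr_pca> %d components; explained: %s; residual %.3f\n",
              ncol(x$scores),
              paste(sprintf("%.3f", x$explained_fraction), collapse = ", "),
              x$residual_fraction))
  invisible(x)
}

#' @export
plot.expr_pca <- function(x, components = c(1, 2), labels = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1
  graphics::plot(s, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$explained_fraction[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$explained_fraction[components[2]]),
                 ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_len(nlevels(factor(labels))) + 1, pch = 19,
                     bty = "n")
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters sample expression profiles with Euclidean distance or the
#' Pearson dissimilarity (1 - Pearson correlation between per-sample
#' profiles) under Ward, average or complete linkage.
#'
#' @param x an \code{expr_matrix} (any post-log state) or samples x genes
#'   matrix.
#' @param distance \code{"euclidean"} or \code{"pearson"}.
#' @param linkage \code{"ward"} (Ward's minimum-variance, implemented as
#'   \code{"ward.D2"} on the distance matrix), \code{"average"} or
#'   \code{"complete"}.
#' @return An \code{hclust} object with attributes \code{"distance"} and
#'   \code{"linkage"}.
#' @seealso \code{\link{count_misclassified}}, \code{\link{tree_newick}}
#' @export
hcluster <- function(x, distance = c("euclidean", "pearson"),
                     linkage = c("ward", "average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  xm <- if (inherits(x, "expr_matrix")) t(x$values) else as.matrix(x)
  if (nrow(xm) < 2) stop("need at least 2 samples to cluster")
  d <- if (distance == "euclidean") {
    stats::dist(xm)
  } else {
    v <- apply(xm, 1, stats::var)
    if (any(v <= 0))
      stop("zero-variance sample(s) under pearson distance: ",
           paste(rownames(xm)[v <= 0], collapse = ", "))
    stats::as.dist(1 - stats::cor(t(xm)))
  }
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  tree <- stats::hclust(d, method = method)
  attr(tree, "distance") <- distance
  attr(tree, "linkage") <- linkage
  tree
}

#' Export a dendrogram as a Newick string
#'
#' @param tree an \code{hclust} object.
#' @param file optional path; when given the string is also written there.
#' @return The Newick string (branch lengths from merge heights),
#'   invisibly when writing to file.
#' @export
tree_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  s <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Count misclassified samples from a dendrogram cut
#'
#' Cuts the tree into \code{k_clusters} groups and maps clusters to
#' classes by the injective assignment that minimizes total
#' misclassification (exhaustive search; exact for a handful of classes).
#' A sample is misclassified when its cluster's mapped class differs from
#' its own label.
#'
#' @param tree an \code{hclust} over the labelled samples (as from
#'   \code{\link{hcluster}}).
#' @param labels named character vector (sample id -> class) or a vector
#'   in tree-leaf order.
#' @param k_clusters number of clusters to cut; defaults to the number of
#'   classes.
#' @return An object of class \code{"cluster_evaluation"}: the
#'   \code{assignment}, chosen \code{mapping}, \code{misclassified}
#'   sample ids and \code{n_misclassified}.
#' @export
count_misclassified <- function(tree, labels, k_clusters = NULL) {
  ids <- tree$labels
  if (!is.null(names(labels))) {
    if (is.null(ids)) stop("tree has no leaf labels to match names against")
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("labels missing for: ", paste(missing, collapse = ", "))
    labels <- labels[ids]
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(k_clusters)) k_clusters <- length(classes)
  if (k_clusters < 1) stop("k_clusters must be >= 1")
  n_leaves <- length(tree$order)
  if (k_clusters > n_leaves) stop("k_clusters exceeds the sample count")
  assignment <- stats::cutree(tree, k = k_clusters)

  best <- .best_cluster_mapping(assignment, labels, classes)
  miss_ids <- if (is.null(ids)) as.character(which(best$miss)) else
    ids[best$miss]
  structure(list(k_clusters = k_clusters, assignment = assignment,
                 mapping = best$mapping, misclassified = miss_ids,
                 n_misclassified = sum(best$miss),
                 distance = attr(tree, "distance"),
                 linkage = attr(tree, "linkage")),
            class = "cluster_evaluation")
}

# exhaustive search over cluster -> class mappings; injective when the
# cluster count does not exceed the class count
.best_cluster_mapping <- function(assignment, labels, classes) {
  k <- length(unique(assignment))
  clusters <- sort(unique(assignment))
  maps <- if (k <= length(classes)) {
    .permutations(classes, k)
  } else {
    as.matrix(expand.grid(rep(list(classes), k), stringsAsFactors = FALSE))
  }
  best_n <- Inf
  best <- NULL
  for (i in seq_len(nrow(maps))) {
    mapped <- maps[i, ][match(assignment, clusters)]
    miss <- mapped != labels
    if (sum(miss) < best_n) {
      best_n <- sum(miss)
      best <- list(mapping = stats::setNames(unname(maps[i, ]),
                                             clusters), miss = miss)
    }
  }
  best
}

# all ordered arrangements of k items drawn from v, as a matrix (rows)
.permutations <- function(v, k) {
  if (k == 0) return(matrix(character(0), 1, 0))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i], k - 1)
    out <- rbind(out, cbind(v[i], rest, deparse.level = 0))
  }
  out
}

#' @export
print.cluster_evaluation <- function(x, ...) {
  cat(sprintf("<cluster_evaluation> k = %d: %d misclassified",
              x$k_clusters, x$n_misclassified))
  if (x$n_misclassified > 0 && x$n_misclassified <= 20)
    cat(" (", paste(x$misclassified, collapse = ", "), ")", sep = "")
  cat("\n  cluster -> class: ",
      paste(sprintf("%s->%s", names(x$mapping), x$mapping), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Between- over within-class variance of a score vector
#'
#' Separation diagnostic for PCA score plots: the ratio of between-class
#' to within-class variance of one score component.
#'
#' @param scores numeric vector (e.g. one PCA score column).
#' @param labels class vector of equal length.
#' @return The F-like ratio (larger = better separated).
#' @export
class_separation <- function(scores, labels) {
  labels <- as.character(labels)
  mu <- mean(scores)
  groups <- split(scores, labels)
  between <- sum(vapply(groups, function(g) length(g) * (mean(g) - mu)^2,
                        numeric(1))) / (length(groups) - 1)
  within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                       numeric(1))) / (length(scores) - length(groups))
  between / within
}
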