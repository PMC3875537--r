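#' S-plot vectors of an OPLS-DA model
#'
#' For each gene g, the covariance and correlation of its centered profile
#' with the predictive score t:
#' \deqn{cov(t, X_g) = t^T X_g / (N - 1)}
#' \deqn{corr(t, X_g) = cov(t, X_g) / (s_t\, s_{X_g})}
#' with \eqn{s_t} and \eqn{s_{X_g}} sample standard deviations (N - 1
#' denominator). cov is the S-plot x-axis (contribution), corr the y-axis
#' (reliability, "p(corr)"). Genes whose centered profile is numerically
#' constant (\eqn{s_{X_g} < 10^{-12}}) get corr 0 and are flagged.
#'
#' @param model a fitted \code{\link{opls}} model.
#' @param x the training matrix the model was fitted on (samples x genes,
#'   or \code{expr_matrix}); defaults to the matrix stored in the model.
#' @return An object of class \code{"splot"}: list with \code{gene_ids},
#'   \code{cov}, \code{corr}, \code{s_x}, \code{s_t}, \code{flagged}
#'   (constant genes), \code{positive_class}.
#' @examples
#' set.seed(2)
#' x <- matrix(rnorm(16 * 12), 16, 12)
#' y <- rep(c("ctl", "dis"), each = 8)
#' x[y == "dis", 1] <- x[y == "dis", 1] + 3
#' sp <- splot(opls(x, y, positive_class = "dis"))
#' head(as.data.frame(sp))
#' @export
splot <- function(model, x = NULL) {
  stopifnot(inherits(model, "opls"))
  if (is.null(x)) {
    Xc <- model$x_centered
  } else {
    Xc <- .as_sample_gene_matrix(x)
    Xc <- sweep(sweep(Xc, 2, model$x_means), 2, model$x_scales, "/")
  }
  t <- model$t
  if (nrow(Xc) != length(t))
    stop("sample count of x does not match the model's score vector")
  n <- length(t)
  cv <- drop(crossprod(t, Xc)) / (n - 1)
  s_x <- apply(Xc, 2, stats::sd)
  s_t <- stats::sd(t)
  flagged <- s_x < 1e-12
  corr <- ifelse(flagged, 0, cv / (s_t * pmax(s_x, 1e-300)))
  gene_ids <- if (!is.null(colnames(Xc))) colnames(Xc) else
    as.character(seq_len(ncol(Xc)))
  structure(list(gene_ids = gene_ids, cov = unname(cv),
                 corr = unname(corr), s_x = unname(s_x), s_t = s_t,
                 flagged = gene_ids[flagged],
                 positive_class = model$positive_class),
            class = "splot")
}

#' @export
print.splot <- function(x, ...) {
  cat(sprintf("<splot> %d genes, positive class '%s'", length(x$gene_ids),
              x$positive_class))
  if (length(x$flagged))
    cat(sprintf(", %d constant gene(s) flagged", length(x$flagged)))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.splot <- function(x, ...) {
  data.frame(gene_id = x$gene_ids, cov = x$cov, corr = x$corr,
             s_x = x$s_x, stringsAsFactors = FALSE)
}

#' @export
plot.splot <- function(x, ...) {
  graphics::plot(x$cov, x$corr, xlab = "cov(t, X)", ylab = "corr(t, X)",
                 pch = 20, col = "grey40", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
}

#' Select top-ranked genes from an S-plot
#'
#' Genes are ranked by |corr| descending — correlation with the predictive
#' score is the primary criterion — and within any run of genes whose
#' |corr| values are separated by less than \code{corr_tie_window} the
#' order is refined by |cov| descending (larger contribution preferred
#' among near-ties), with remaining ties broken lexicographically by gene
#' id so the ranking is deterministic. Direction is \code{"up"} when corr
#' is positive (elevated in the model's positive class), \code{"down"}
#' otherwise.
#'
#' @param sp an \code{\link{splot}} object.
#' @param k number of genes to select, \code{1 <= k <= gene count}.
#' @param corr_tie_window |corr| gap below which consecutive ranked genes
#'   count as tied, default 0.01.
#' @param balanced if \code{TRUE}, take k/2 by most-positive and k/2 by
#'   most-negative corr instead of plain top-k (symmetric panels).
#' @param source_model label recorded with each entry.
#' @return A \code{"gene_selection"} data.frame with columns
#'   \code{gene_id}, \code{source_model}, \code{corr}, \code{cov},
#'   \code{direction}, \code{rank}; attribute \code{"k_requested"}.
#' @export
select_top_genes <- function(sp, k, corr_tie_window = 0.01,
                             balanced = FALSE, source_model = "model1") {
  stopifnot(inherits(sp, "splot"))
  ng <- length(sp$gene_ids)
  if (k < 1 || k > ng) stop("k must be between 1 and the gene count (", ng, ")")
  ord <- .splot_order(abs(sp$corr), abs(sp$cov), sp$gene_ids,
                      corr_tie_window)
  if (balanced) {
    k_up <- ceiling(k / 2)
    k_dn <- k - k_up
    up <- ord[sp$corr[ord] > 0]
    dn <- ord[sp$corr[ord] <= 0]
    if (length(up) < k_up || length(dn) < k_dn)
      stop("not enough genes on one side of corr = 0 for a balanced panel")
    idx <- c(up[seq_len(k_up)], dn[seq_len(k_dn)])
  } else {
    idx <- ord[seq_len(k)]
  }
  out <- data.frame(
    gene_id = sp$gene_ids[idx],
    source_model = source_model,
    corr = sp$corr[idx],
    cov = sp$cov[idx],
    direction = ifelse(sp$corr[idx] > 0, "up", "down"),
    rank = seq_along(idx),
    stringsAsFactors = FALSE)
  attr(out, "k_requested") <- k
  attr(out, "full_order") <- sp$gene_ids[ord]
  class(out) <- c("gene_selection", "data.frame")
  out
}

# rank order: |corr| descending, near-ties (gap < window between
# consecutive sorted values chain into one run) refined by |cov|
# descending, then gene id
.splot_order <- function(abs_corr, abs_cov, gene_ids, window) {
  base <- order(-abs_corr, -abs_cov, gene_ids)
  if (window <= 0) return(base)
  ac <- abs_corr[base]
  run_id <- cumsum(c(1, as.integer(diff(ac) < -window | diff(ac) > window)))
  # within each run, re-sort by |cov| then gene id
  split_idx <- split(base, run_id)
  unlist(lapply(split_idx, function(ix) {
    ix[order(-abs_cov[ix], gene_ids[ix])]
  }), use.names = FALSE)
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d genes", nrow(x)))
  dup <- attr(x, "duplicates_removed")
  if (!is.null(dup) && nrow(dup))
    cat(sprintf(" (%d duplicate pick(s) merged: %s)", nrow(dup),
                paste(dup$gene_id, collapse = ", ")))
  cat("\n")
  tab <- table(x$source_model, x$direction)
  print(tab)
  invisible(x)
}
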