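#' Expression matrix container
#'
#' A genes x samples intensity matrix with gene and sample identifiers,
#' optional per-sample class labels, and a preprocessing state tag. The
#' state machine enforces the Golub preprocessing order:
#' \code{raw -> clipped -> filtered -> log10 -> centered}.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the matrix rownames.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix colnames.
#' @param labels optional named character vector mapping sample id to class
#'   name (names must cover \code{sample_ids}), or an unnamed vector in
#'   sample order.
#' @param state preprocessing state, one of \code{"raw"}, \code{"clipped"},
#'   \code{"filtered"}, \code{"log10"}, \code{"centered"}.
#' @return An object of class \code{"expr_matrix"}.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' m
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), labels = NULL,
                              state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  state <- match.arg(state, .em_states)
  if (is.null(gene_ids)) stop("gene_ids required (or set rownames)")
  if (is.null(sample_ids)) stop("sample_ids required (or set colnames)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (state %in% c("raw", "clipped", "filtered") && any(values <= 0))
    stop("all intensities must be > 0 in state '", state, "'")
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(labels)) {
    labels <- as.character(labels) |> stats::setNames(
      if (is.null(names(labels))) sample_ids else names(labels))
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids]
  }
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels, state = state),
            class = "expr_matrix")
}

.em_states <- c("raw", "clipped", "filtered", "log10", "centered")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, state '%s'\n",
              nrow(x$values), ncol(x$values), x$state))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an \code{expr_matrix}.
#' @param genes,samples character ids or index vectors; \code{NULL} keeps all.
#' @return An \code{expr_matrix} with the same state.
#' @export
em_subset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  gi <- if (is.null(genes)) x$gene_ids else genes
  si <- if (is.null(samples)) x$sample_ids else samples
  if (is.character(gi)) {
    bad <- setdiff(gi, x$gene_ids)
    if (length(bad)) stop("unknown gene ids: ", paste(bad, collapse = ", "))
  }
  if (is.character(si)) {
    bad <- setdiff(si, x$sample_ids)
    if (length(bad)) stop("unknown sample ids: ", paste(bad, collapse = ", "))
  }
  v <- x$values[gi, si, drop = FALSE]
  expression_matrix(v, labels = if (!is.null(x$labels)) x$labels[colnames(v)],
                    state = x$state)
}

# internal: fail unless the matrix is in one of the allowed states
.require_state <- function(m, allowed, op) {
  if (!inherits(m, "expr_matrix"))
    stop(op, "() expects an expr_matrix")
  if (!m$state %in% allowed)
    stop(op, "() requires state ", paste(sQuote(allowed), collapse = " or "),
         " but matrix is in state '", m$state,
         "' (preprocessing order is raw -> clipped -> filtered -> log10 -> centered)")
  invisible(TRUE)
}

# internal: samples x genes numeric matrix from expr_matrix or plain matrix
.as_sample_gene_matrix <- function(x, allowed = c("log10", "centered")) {
  if (inherits(x, "expr_matrix")) {
    .require_state(x, allowed, "model input")
    t(x$values)
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}

# internal: labels for a set of samples, error if absent
.require_labels <- function(m) {
  if (is.null(m$labels)) stop("expression matrix carries no class labels")
  m$labels
}
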