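#' Read an expression matrix from GCT or plain TSV
#'
#' GCT: a \code{#1.2} version line, a \code{nrow\\tncol} dimension line,
#' then a header \code{Name\\tDescription\\t<sample ids>} and one row per
#' gene. Plain TSV: first row sample ids, first column gene ids. Parsers
#' are strict: ragged rows, non-numeric cells, duplicate ids and
#' dimension mismatches are errors naming the offending line.
#'
#' @param path file path.
#' @param format \code{"gct"}, \code{"tsv"}, or \code{"auto"} (by
#'   extension, default).
#' @param state preprocessing state to tag the matrix with (default
#'   \code{"raw"}).
#' @return An \code{expr_matrix} (no labels; see \code{\link{read_labels}}).
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv"),
                            state = "raw") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "gct") .parse_gct(lines, path, state)
  else .parse_matrix_tsv(lines, path, state)
}

.parse_gct <- function(lines, path, state) {
  if (length(lines) < 3) stop(path, ": truncated GCT (need >= 3 lines)")
  if (!grepl("^#1\\.2\\s*$", lines[1]))
    stop(path, ":1: expected GCT version line '#1.2'")
  dims <- strsplit(trimws(lines[2]), "\t")[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop(path, ":2: expected '<n_genes>\\t<n_samples>'")
  ng <- as.integer(dims[1]); ns <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t")[[1]]
  if (length(header) != ns + 2)
    stop(path, ":3: header has ", length(header) - 2,
         " sample columns, dimension line declares ", ns)
  sample_ids <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != ng)
    stop(path, ": declared ", ng, " genes but found ", length(body),
         " data rows")
  parsed <- .parse_rows(body, ns + 2, path, offset = 3)
  gene_ids <- vapply(parsed, `[`, character(1), 1)
  desc <- vapply(parsed, `[`, character(1), 2)
  values <- .numeric_block(parsed, drop_cols = 2, path, offset = 3)
  m <- expression_matrix(values, gene_ids = gene_ids,
                         sample_ids = sample_ids, state = state)
  attr(m, "gene_descriptions") <- stats::setNames(desc, gene_ids)
  m
}

.parse_matrix_tsv <- function(lines, path, state) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop(path, ": need a header and at least one gene")
  header <- strsplit(lines[1], "\t")[[1]]
  sample_ids <- header[-1]
  parsed <- .parse_rows(lines[-1], length(header), path, offset = 1)
  gene_ids <- vapply(parsed, `[`, character(1), 1)
  values <- .numeric_block(parsed, drop_cols = 1, path, offset = 1)
  expression_matrix(values, gene_ids = gene_ids, sample_ids = sample_ids,
                    state = state)
}

.parse_rows <- function(body, want, path, offset) {
  parsed <- strsplit(body, "\t")
  widths <- lengths(parsed)
  bad <- which(widths != want)
  if (length(bad))
    stop(path, ":", offset + bad[1], ": row has ", widths[bad[1]],
         " fields, expected ", want)
  parsed
}

.numeric_block <- function(parsed, drop_cols, path, offset) {
  vals <- lapply(parsed, function(r) suppressWarnings(
    as.numeric(r[-seq_len(drop_cols)])))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop(path, ":", offset + bad[1], ": non-numeric expression value")
  do.call(rbind, vals)
}

#' Write an expression matrix as GCT or plain TSV
#'
#' @param m an \code{expr_matrix}.
#' @param path output path.
#' @param format \code{"gct"}, \code{"tsv"} or \code{"auto"} (by
#'   extension).
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(m, path, format = c("auto", "gct", "tsv")) {
  stopifnot(inherits(m, "expr_matrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  v <- format(m$values, trim = TRUE, digits = 15, scientific = FALSE)
  if (format == "gct") {
    desc <- attr(m, "gene_descriptions")
    if (is.null(desc)) desc <- stats::setNames(rep("na", nrow(m$values)),
                                               m$gene_ids)
    rows <- paste(m$gene_ids, desc[m$gene_ids],
                  apply(v, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c("#1.2",
                 paste(nrow(m$values), ncol(m$values), sep = "\t"),
                 paste(c("Name", "Description", m$sample_ids),
                       collapse = "\t"), rows), path)
  } else {
    rows <- paste(m$gene_ids, apply(v, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(paste(c("gene_id", m$sample_ids), collapse = "\t"), rows),
               path)
  }
  invisible(path)
}

#' Read class labels from CLS or two-column TSV
#'
#' CLS: line 1 \code{<n_samples> <n_classes> 1}, line 2
#' \code{# <class names>}, line 3 space-separated labels (0-based indices
#' into the class names, or the names themselves), in sample order.
#' TSV: two tab-separated columns \code{sample_id\\tclass} with a header.
#'
#' @param path file path.
#' @param format \code{"cls"}, \code{"tsv"} or \code{"auto"}.
#' @param sample_ids sample ids the labels must align with: required for
#'   CLS (positional) and used to check/reorder TSV labels.
#' @return Named character vector, sample id -> class.
#' @export
read_labels <- function(path, format = c("auto", "cls", "tsv"),
                        sample_ids = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cls$", path, ignore.case = TRUE)) "cls" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "cls") {
    if (length(lines) < 3) stop(path, ": truncated CLS (need 3 lines)")
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(hdr) != 3)
      stop(path, ":1: expected '<n_samples> <n_classes> 1'")
    n <- as.integer(hdr[1]); k <- as.integer(hdr[2])
    nm <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    if (nm[1] != "#") stop(path, ":2: class-name line must start with '#'")
    cls_names <- nm[-1]
    if (length(cls_names) != k)
      stop(path, ":2: header declares ", k, " classes but names ",
           length(cls_names))
    toks <- strsplit(trimws(lines[3]), "\\s+")[[1]]
    if (length(toks) != n)
      stop(path, ":3: header declares ", n, " samples but line has ",
           length(toks))
    idx <- suppressWarnings(as.integer(toks))
    labels <- if (!anyNA(idx)) {
      if (any(idx < 0 | idx >= k)) stop(path, ":3: class index out of range")
      cls_names[idx + 1]
    } else {
      if (!all(toks %in% cls_names))
        stop(path, ":3: unknown class token(s): ",
             paste(setdiff(toks, cls_names), collapse = ", "))
      toks
    }
    if (is.null(sample_ids))
      stop("CLS labels are positional; supply sample_ids")
    if (length(sample_ids) != n)
      stop("CLS declares ", n, " samples, expression matrix has ",
           length(sample_ids))
    stats::setNames(labels, sample_ids)
  } else {
    rows <- strsplit(lines[nzchar(trimws(lines))], "\t")
    if (any(lengths(rows) != 2))
      stop(path, ": each TSV row needs exactly 'sample_id\\tclass'")
    tab <- do.call(rbind, rows)
    if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
    labels <- stats::setNames(tab[, 2], tab[, 1])
    if (anyDuplicated(names(labels)))
      stop(path, ": duplicate sample ids in label file")
    if (!is.null(sample_ids)) {
      missing <- setdiff(sample_ids, names(labels))
      if (length(missing))
        stop(path, ": labels missing for sample(s): ",
             paste(missing, collapse = ", "))
      labels <- labels[sample_ids]
    }
    labels
  }
}

#' Write class labels as CLS or TSV
#'
#' @param labels named character vector (sample id -> class).
#' @param path output path.
#' @param format \code{"cls"}, \code{"tsv"} or \code{"auto"}.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path, format = c("auto", "cls", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cls$", path, ignore.case = TRUE)) "cls" else "tsv"
  if (format == "cls") {
    cls_names <- unique(unname(labels))
    idx <- match(labels, cls_names) - 1L
    writeLines(c(paste(length(labels), length(cls_names), 1),
                 paste("#", paste(cls_names, collapse = " ")),
                 paste(idx, collapse = " ")), path)
  } else {
    writeLines(c("sample_id\tclass",
                 paste(names(labels), labels, sep = "\t")), path)
  }
  invisible(path)
}

#' Write a gene selection panel as TSV
#'
#' Columns: gene_id, source_model, corr, cov, direction, rank.
#'
#' @param sel a \code{"gene_selection"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_selection <- function(sel, path) {
  utils::write.table(as.data.frame(sel)[, c("gene_id", "source_model",
                                            "corr", "cov", "direction",
                                            "rank")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene selection panel written by \code{\link{write_selection}}
#' @param path TSV path.
#' @return A \code{"gene_selection"} data.frame.
#' @export
read_selection <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "source_model", "corr", "cov", "direction", "rank")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop(path, ": selection table lacks column(s): ",
         paste(missing, collapse = ", "))
  class(tab) <- c("gene_selection", "data.frame")
  tab
}

#' Serialize a fitted OPLS-DA model to a JSON file
#'
#' Writes weights, loadings, centering parameters and fit statistics under
#' a versioned schema; numbers are stored at full precision.
#'
#' @param model an \code{opls} model.
#' @param path output path.
#' @param keep_training keep the centered training matrix (needed to
#'   recompute S-plots after reload), default \code{TRUE}.
#' @return \code{path}, invisibly.
#' @export
write_opls <- function(model, path, keep_training = TRUE) {
  stopifnot(inherits(model, "opls"))
  obj <- unclass(model)
  obj$cv_anova <- model$cv_anova
  if (!keep_training) obj$x_centered <- NULL
  payload <- list(schema = "moplsda/opls", schema_version = 1L,
                  model = obj)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by \code{\link{write_opls}}
#' @param path JSON path.
#' @return An \code{opls} model.
#' @export
read_opls <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "moplsda/opls"))
    stop(path, ": not a serialized OPLS-DA model")
  m <- payload$model
  for (f in c("W_o", "T_o", "P_o", "x_centered"))
    if (!is.null(m[[f]])) m[[f]] <- as.matrix(m[[f]])
  for (f in c("w", "p", "x_means", "x_scales"))
    if (!is.null(m$gene_ids)) names(m[[f]]) <- m$gene_ids
  if (!is.null(m$x_centered))
    dimnames(m$x_centered) <- list(m$sample_ids, m$gene_ids)
  structure(m, class = "opls")
}
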