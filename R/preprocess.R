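#' Clip raw intensities to a floor and ceiling
#'
#' Golub-style thresholding: every intensity below \code{floor} is set to
#' \code{floor} and every intensity above \code{ceiling} to \code{ceiling}.
#'
#' @param m an \code{expr_matrix} in state \code{"raw"}.
#' @param floor,ceiling clip bounds in raw intensity units
#'   (defaults 100 and 16000).
#' @return The clipped \code{expr_matrix}, state \code{"clipped"}.
#' @export
threshold_clip <- function(m, floor = 100, ceiling = 16000) {
  .require_state(m, "raw", "threshold_clip")
  if (!(floor < ceiling)) stop("floor must be < ceiling")
  v <- pmin(pmax(m$values, floor), ceiling)
  out <- m
  out$values <- v
  out$state <- "clipped"
  out
}

#' Variation filter on clipped intensities
#'
#' Discards genes with \code{max/min <= fold_min} or
#' \code{max - min <= range_min} across all samples; equivalently, a gene is
#' retained iff both \code{max/min > fold_min} and
#' \code{max - min > range_min} hold strictly. max and min are taken on the
#' clipped intensity scale.
#'
#' @param m an \code{expr_matrix} in state \code{"clipped"}.
#' @param fold_min minimum max/min fold ratio (exclusive), default 5.
#' @param range_min minimum max - min range (exclusive), default 500.
#' @return The filtered \code{expr_matrix} (state \code{"filtered"}) with a
#'   \code{"filter_report"} attribute: a list with \code{kept},
#'   \code{dropped}, \code{fold_min}, \code{range_min}. Apply the same gene
#'   list to a held-out set with \code{\link{apply_filter}}.
#' @export
variation_filter <- function(m, fold_min = 5, range_min = 500) {
  .require_state(m, "clipped", "variation_filter")
  mx <- apply(m$values, 1, max)
  mn <- apply(m$values, 1, min)
  pass_fold <- mx / mn > fold_min
  pass_range <- mx - mn > range_min
  keep <- pass_fold & pass_range
  if (!any(keep)) {
    stricter <- if (sum(pass_fold) <= sum(pass_range))
      sprintf("fold criterion (max/min > %g)", fold_min)
    else sprintf("range criterion (max - min > %g)", range_min)
    stop("variation_filter removed every gene; stricter rule was the ",
         stricter)
  }
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out$gene_ids <- m$gene_ids[keep]
  out$state <- "filtered"
  attr(out, "filter_report") <- list(
    kept = m$gene_ids[keep], dropped = m$gene_ids[!keep],
    fold_min = fold_min, range_min = range_min)
  out
}

#' Apply a training-derived variation filter to another matrix
#'
#' Restricts \code{m} to the genes a previous \code{\link{variation_filter}}
#' call retained, so a test set uses the training-set gene list rather than
#' its own (no leakage).
#'
#' @param m an \code{expr_matrix} in state \code{"clipped"}.
#' @param report the \code{"filter_report"} attribute of a filtered training
#'   matrix, or that matrix itself.
#' @return The restricted \code{expr_matrix}, state \code{"filtered"}.
#' @export
apply_filter <- function(m, report) {
  .require_state(m, "clipped", "apply_filter")
  if (inherits(report, "expr_matrix")) report <- attr(report, "filter_report")
  if (is.null(report$kept)) stop("not a filter report")
  missing <- setdiff(report$kept, m$gene_ids)
  if (length(missing))
    stop("filter report names genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- em_subset(m, genes = report$kept)
  out$state <- "filtered"
  attr(out, "filter_report") <- report
  out
}

#' Log10-transform filtered intensities
#'
#' @param m an \code{expr_matrix} in state \code{"filtered"} with all
#'   values > 0.
#' @return The transformed \code{expr_matrix}, state \code{"log10"}.
#' @export
log10_transform <- function(m) {
  .require_state(m, "filtered", "log10_transform")
  if (any(m$values <= 0)) stop("log10_transform requires positive values")
  out <- m
  out$values <- log10(m$values)
  out$state <- "log10"
  out
}

#' Mean-center each gene
#'
#' Subtracts the per-gene mean across samples, or a supplied reference mean
#' (e.g. training-set means when projecting a test set into a trained
#' model).
#'
#' @param m an \code{expr_matrix} in state \code{"log10"}.
#' @param reference_means optional named numeric vector of per-gene means in
#'   log10 units; names must cover the matrix genes exactly.
#' @return The centered \code{expr_matrix}, state \code{"centered"}, with
#'   the means used stored in the \code{"gene_means"} attribute.
#' @export
mean_center <- function(m, reference_means = NULL) {
  .require_state(m, "log10", "mean_center")
  if (is.null(reference_means)) {
    mu <- rowMeans(m$values)
  } else {
    if (is.null(names(reference_means)))
      stop("reference_means must be named by gene id")
    missing <- setdiff(m$gene_ids, names(reference_means))
    if (length(missing))
      stop("reference_means missing genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    mu <- reference_means[m$gene_ids]
  }
  out <- m
  out$values <- m$values - mu
  out$state <- "centered"
  attr(out, "gene_means") <- stats::setNames(as.numeric(mu), m$gene_ids)
  out
}

#' Run the full Golub preprocessing pipeline
#'
#' \code{\link{threshold_clip}}, \code{\link{variation_filter}},
#' \code{\link{log10_transform}} and \code{\link{mean_center}} in the
#' enforced order.
#'
#' @param m an \code{expr_matrix} in state \code{"raw"}.
#' @param floor,ceiling,fold_min,range_min see the individual steps.
#' @param center subtract per-gene means (default \code{TRUE}); set
#'   \code{FALSE} to stop at state \code{"log10"} (e.g. for the t-test
#'   baseline).
#' @return The preprocessed \code{expr_matrix}; the variation-filter report
#'   is kept in the \code{"filter_report"} attribute.
#' @export
preprocess <- function(m, floor = 100, ceiling = 16000, fold_min = 5,
                       range_min = 500, center = TRUE) {
  f <- variation_filter(threshold_clip(m, floor, ceiling), fold_min, range_min)
  rep <- attr(f, "filter_report")
  out <- log10_transform(f)
  if (center) out <- mean_center(out)
  attr(out, "filter_report") <- rep
  out
}
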