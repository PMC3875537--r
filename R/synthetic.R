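#' Specification for a synthetic three-class microarray dataset
#'
#' Describes a planted-marker generator that emulates the structure of
#' Golub-style raw microarray data: positive intensities spanning roughly
#' 1 to 20000, three classes (optionally two of them subtypes of a
#' super-class), marker genes with class-specific shifts on the log10
#' scale, and a block of near-constant genes for the variation filter to
#' remove.
#'
#' Each gene g gets a baseline \eqn{b_g \sim N(\mu, \sigma_b)} in log10
#' units; sample value \eqn{10^{b_g + \delta_{gc} + \epsilon}} with
#' \eqn{\epsilon \sim N(0, \sigma)} and \eqn{\delta_{gc} = \pm effect}
#' for planted markers in the affected class, 0 otherwise. Low-variation
#' genes use \eqn{\sigma/20} and carry no effect. Marker sets of distinct
#' contrasts are disjoint.
#'
#' Contrasts: without a hierarchy, one one-versus-rest contrast per class
#' (markers shifted in that class only). With a hierarchy, two contrasts —
#' outgroup vs super-class (markers shifted in the outgroup) and subtype 1
#' vs subtype 2 (markers shifted in subtype 1).
#'
#' @param n_per_class named sample counts per class; default
#'   \code{c("ALL-B" = 19, "ALL-T" = 8, "AML" = 11)}, mirroring the
#'   unbalanced composition of the Golub training set.
#' @param n_genes total genes, default 2000.
#' @param n_markers_up,n_markers_down planted markers per contrast in each
#'   direction, default 25 + 25.
#' @param baseline_log_mean,baseline_log_sd baseline log10 intensity mean
#'   and between-gene spread (defaults 2.8 and 0.5).
#' @param effect marker shift in log10 units, default 0.6.
#' @param noise_sd within-gene log10 noise, default 0.2.
#' @param frac_low_variation fraction of genes drawn near-constant,
#'   default 0.1.
#' @param hierarchy optional list(super, subtypes, outgroup) as in
#'   \code{\link{class_scheme}}.
#' @param seed random seed (default 1).
#' @return A \code{"synthetic_spec"} list.
#' @export
synthetic_spec <- function(n_per_class = c("ALL-B" = 19, "ALL-T" = 8,
                                           "AML" = 11),
                           n_genes = 2000, n_markers_up = 25,
                           n_markers_down = 25, baseline_log_mean = 2.8,
                           baseline_log_sd = 0.5, effect = 0.6,
                           noise_sd = 0.2, frac_low_variation = 0.1,
                           hierarchy = NULL, seed = 1) {
  if (is.null(names(n_per_class)))
    names(n_per_class) <- paste0("class", seq_along(n_per_class))
  if (any(n_per_class < 1) || n_genes < 1 || n_markers_up < 0 ||
      n_markers_down < 0)
    stop("counts must be positive")
  if (effect < 0) stop("effect must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (frac_low_variation < 0 || frac_low_variation >= 1)
    stop("frac_low_variation must be in [0, 1)")
  if (!is.null(hierarchy)) {
    if (!all(c(hierarchy$subtypes, hierarchy$outgroup) %in%
             names(n_per_class)))
      stop("hierarchy classes must appear in n_per_class")
  }
  structure(list(n_per_class = n_per_class, n_genes = as.integer(n_genes),
                 n_markers_up = as.integer(n_markers_up),
                 n_markers_down = as.integer(n_markers_down),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, effect = effect,
                 noise_sd = noise_sd,
                 frac_low_variation = frac_low_variation,
                 hierarchy = hierarchy, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with planted markers
#'
#' Draws a raw-intensity genes x samples matrix from a
#' \code{\link{synthetic_spec}} together with the ground-truth marker
#' table. Fully reproducible from the spec's seed; the global RNG state is
#' left untouched.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list with \code{expr} (an \code{expr_matrix} in state
#'   \code{"raw"} with labels) and \code{truth} (data.frame gene_id,
#'   contrast, direction, affected_class).
#' @examples
#' d <- generate_expression(synthetic_spec(n_genes = 200, seed = 7))
#' d$expr
#' head(d$truth)
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .generate_expression_impl(spec))
}

.generate_expression_impl <- function(spec) {
  classes <- names(spec$n_per_class)
  n_samples <- sum(spec$n_per_class)
  sample_class <- rep(classes, spec$n_per_class)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))

  contrasts <- if (is.null(spec$hierarchy)) {
    lapply(classes, function(cls)
      list(name = sprintf("%s_vs_rest", cls), affected = cls))
  } else {
    h <- spec$hierarchy
    list(list(name = sprintf("%s_vs_%s", h$outgroup, h$super),
              affected = h$outgroup),
         list(name = sprintf("%s_vs_%s", h$subtypes[1], h$subtypes[2]),
              affected = h$subtypes[1]))
  }
  per_contrast <- spec$n_markers_up + spec$n_markers_down
  n_markers <- per_contrast * length(contrasts)
  n_low <- floor(spec$frac_low_variation * spec$n_genes)
  if (n_markers + n_low > spec$n_genes)
    stop("marker and low-variation demand (", n_markers + n_low,
         ") exceeds n_genes (", spec$n_genes, ")")

  # first genes are markers (shuffled ids keep position uninformative)
  perm <- sample(spec$n_genes)
  marker_idx <- perm[seq_len(n_markers)]
  low_idx <- perm[n_markers + seq_len(n_low)]

  truth <- NULL
  delta <- matrix(0, spec$n_genes, length(classes),
                  dimnames = list(NULL, classes))
  pos <- 0L
  for (ct in contrasts) {
    up <- marker_idx[pos + seq_len(spec$n_markers_up)]
    dn <- marker_idx[pos + spec$n_markers_up + seq_len(spec$n_markers_down)]
    pos <- pos + per_contrast
    delta[up, ct$affected] <- spec$effect
    delta[dn, ct$affected] <- -spec$effect
    truth <- rbind(truth, data.frame(
      gene_id = gene_ids[c(up, dn)], contrast = ct$name,
      direction = rep(c("up", "down"),
                      c(spec$n_markers_up, spec$n_markers_down)),
      affected_class = ct$affected, stringsAsFactors = FALSE))
  }

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_log_mean,
                           spec$baseline_log_sd)
  sd_gene <- rep(spec$noise_sd, spec$n_genes)
  sd_gene[low_idx] <- spec$noise_sd / 20
  delta[low_idx, ] <- 0

  noise <- matrix(stats::rnorm(spec$n_genes * n_samples, 0, sd_gene),
                  spec$n_genes, n_samples)  # sd recycles down columns: by gene
  logv <- baseline + delta[, sample_class, drop = FALSE] + noise
  values <- 10^logv
  expr <- expression_matrix(values, gene_ids = gene_ids,
                            sample_ids = sample_ids,
                            labels = stats::setNames(sample_class,
                                                     sample_ids),
                            state = "raw")
  attr(expr, "low_variation_genes") <- gene_ids[low_idx]
  list(expr = expr, truth = truth)
}
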