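#' Define a three-class selection scheme
#'
#' Two arrangements are supported. \code{"hierarchical"} treats two of the
#' classes as subtypes of one super-class (e.g. ALL = \{ALL-B, ALL-T\}
#' against the outgroup AML): model 1 contrasts the outgroup with the
#' merged super-class, model 2 contrasts the two subtypes using only the
#' super-class samples. \code{"parallel"} fits one one-versus-rest model
#' per class.
#'
#' @param mode \code{"hierarchical"} or \code{"parallel"}.
#' @param classes ordered class names (three for hierarchical; three or
#'   more, flagged experimental above three, for parallel).
#' @param hierarchy for hierarchical mode, a list with \code{super} (name),
#'   \code{subtypes} (two class names) and \code{outgroup} (one class
#'   name).
#' @param per_model_k genes per model: default \code{c(40, 10)} for
#'   hierarchical (outgroup model, subtype model), \code{17} per class for
#'   parallel.
#' @return A \code{"class_scheme"} list.
#' @examples
#' class_scheme("hierarchical", c("ALL-B", "ALL-T", "AML"),
#'   hierarchy = list(super = "ALL", subtypes = c("ALL-B", "ALL-T"),
#'                    outgroup = "AML"))
#' @export
class_scheme <- function(mode = c("hierarchical", "parallel"), classes,
                         hierarchy = NULL, per_model_k = NULL) {
  mode <- match.arg(mode)
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("class names must be distinct")
  if (mode == "hierarchical") {
    if (length(classes) != 3)
      stop("hierarchical mode requires exactly three leaf classes")
    if (is.null(hierarchy))
      stop("hierarchical mode requires a hierarchy (super, subtypes, outgroup)")
    if (length(hierarchy$subtypes) != 2 ||
        !all(hierarchy$subtypes %in% classes))
      stop("hierarchy must name exactly two subtypes drawn from classes")
    if (length(hierarchy$outgroup) != 1 ||
        !hierarchy$outgroup %in% classes ||
        hierarchy$outgroup %in% hierarchy$subtypes)
      stop("hierarchy outgroup must be the remaining class")
    if (is.null(per_model_k)) per_model_k <- c(40, 10)
    if (length(per_model_k) != 2)
      stop("hierarchical per_model_k must have length 2")
  } else {
    if (length(classes) < 3)
      stop("parallel mode requires at least three classes")
    if (length(classes) > 3)
      warning("more than three classes in parallel mode is experimental")
    if (is.null(per_model_k)) per_model_k <- rep(17L, length(classes))
    if (length(per_model_k) == 1)
      per_model_k <- rep(per_model_k, length(classes))
    if (length(per_model_k) != length(classes))
      stop("parallel per_model_k must have one entry per class")
  }
  if (any(per_model_k < 1)) stop("per_model_k must all be >= 1")
  structure(list(mode = mode, classes = classes, hierarchy = hierarchy,
                 per_model_k = as.integer(per_model_k)),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat(sprintf("<class_scheme> %s: %s\n", x$mode,
              paste(x$classes, collapse = ", ")))
  if (x$mode == "hierarchical")
    cat(sprintf("  %s = {%s}; outgroup %s; k = [%s]\n", x$hierarchy$super,
                paste(x$hierarchy$subtypes, collapse = ", "),
                x$hierarchy$outgroup, paste(x$per_model_k, collapse = ", ")))
  else
    cat(sprintf("  k per model = [%s]\n", paste(x$per_model_k, collapse = ", ")))
  invisible(x)
}

# internal checks shared by the selectors
.check_scheme_data <- function(m, scheme, min_n = 3) {
  lab <- .require_labels(m)
  missing <- setdiff(scheme$classes, unique(lab))
  if (length(missing))
    stop("classes absent from the data: ", paste(missing, collapse = ", "))
  tab <- table(lab)[scheme$classes]
  small <- names(tab)[tab < min_n]
  if (length(small))
    stop("class(es) with fewer than ", min_n, " samples: ",
         paste(small, collapse = ", "))
  lab
}

#' Hierarchical two-model gene selection
#'
#' Model 1 contrasts the outgroup against the merged super-class on all
#' samples and contributes the top \code{per_model_k[1]} S-plot genes;
#' model 2 contrasts the two subtypes using only the super-class samples
#' (re-centered on that subset) and contributes \code{per_model_k[2]}.
#' Duplicate picks keep the higher-|corr| occurrence; if deduplication
#' shrinks the panel below \code{k_total}, the next-ranked model-1 genes
#' top it up.
#'
#' @param m an \code{expr_matrix} in state \code{"log10"} or
#'   \code{"centered"}, with labels covering the scheme's classes.
#' @param scheme a hierarchical \code{\link{class_scheme}}.
#' @param n_ortho \code{"auto"} (cross-validated gain rule) or an integer
#'   vector (recycled) giving orthogonal components per model.
#' @param k_total panel size after merging, default 50.
#' @param corr_tie_window,balanced passed to \code{\link{select_top_genes}}.
#' @param n_folds,cv_scheme,seed cross-validation controls for the
#'   automatic \code{n_ortho} rule and the reported Q2.
#' @return A \code{"gene_selection"} data.frame (see
#'   \code{\link{select_top_genes}}) with attributes \code{"models"} (the
#'   fitted \code{opls} objects) and \code{"duplicates_removed"}.
#' @export
hierarchical_select <- function(m, scheme, n_ortho = "auto", k_total = 50,
                                corr_tie_window = 0.01, balanced = FALSE,
                                n_folds = 7, cv_scheme = "venetian_blind",
                                seed = NULL) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (scheme$mode != "hierarchical")
    stop("hierarchical_select needs a hierarchical scheme")
  lab <- .check_scheme_data(m, scheme)
  h <- scheme$hierarchy
  keep <- lab %in% scheme$classes
  xm <- .as_sample_gene_matrix(em_subset(m, samples = m$sample_ids[keep]))
  lab <- lab[keep]

  # model 1: outgroup vs merged subtypes, all samples
  y1 <- ifelse(lab == h$outgroup, h$outgroup, h$super)
  fit1 <- .fit_contrast(xm, y1, positive = h$outgroup, n_ortho, 1,
                        n_folds, cv_scheme, seed)
  name1 <- sprintf("%s_vs_%s", h$outgroup, h$super)
  # selection pool larger than k so dedup top-up can draw from model 1
  pool1 <- min(nrow(as.data.frame(splot(fit1))), k_total + scheme$per_model_k[1])
  sel1 <- select_top_genes(splot(fit1), pool1, corr_tie_window,
                           balanced = FALSE, source_model = name1)
  sel1_top <- if (balanced)
    select_top_genes(splot(fit1), scheme$per_model_k[1], corr_tie_window,
                     balanced = TRUE, source_model = name1)
  else sel1[seq_len(scheme$per_model_k[1]), ]

  # model 2: subtype 1 vs subtype 2, super-class samples only
  sub <- lab %in% h$subtypes
  fit2 <- .fit_contrast(xm[sub, , drop = FALSE], lab[sub],
                        positive = h$subtypes[1], n_ortho, 2,
                        n_folds, cv_scheme, seed)
  name2 <- sprintf("%s_vs_%s", h$subtypes[1], h$subtypes[2])
  sel2 <- select_top_genes(splot(fit2), scheme$per_model_k[2],
                           corr_tie_window, balanced = balanced,
                           source_model = name2)

  merged <- .merge_selections(list(sel1_top, sel2), k_total = k_total,
                              topup_from = sel1)
  attr(merged, "models") <- stats::setNames(list(fit1, fit2),
                                            c(name1, name2))
  attr(merged, "scheme") <- scheme
  merged
}

#' Parallel one-versus-rest gene selection
#'
#' Fits one OPLS-DA model per class (that class coded 1, all others 0) and
#' takes the top \code{k_per_model} S-plot genes from each; the union is
#' deduplicated keeping the higher-|corr| occurrence, so the final panel
#' has \code{length(classes) * k_per_model - duplicates} genes.
#'
#' @inheritParams hierarchical_select
#' @param scheme a parallel \code{\link{class_scheme}}.
#' @param k_per_model genes per class model; defaults to the scheme's
#'   \code{per_model_k}.
#' @return A \code{"gene_selection"} data.frame with attributes
#'   \code{"models"} and \code{"duplicates_removed"}.
#' @export
parallel_ovr_select <- function(m, scheme, n_ortho = "auto",
                                k_per_model = NULL, corr_tie_window = 0.01,
                                balanced = FALSE, n_folds = 7,
                                cv_scheme = "venetian_blind", seed = NULL) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (scheme$mode != "parallel")
    stop("parallel_ovr_select needs a parallel scheme")
  lab <- .check_scheme_data(m, scheme)
  keep <- lab %in% scheme$classes
  xm <- .as_sample_gene_matrix(em_subset(m, samples = m$sample_ids[keep]))
  lab <- lab[keep]
  ks <- if (is.null(k_per_model)) scheme$per_model_k
        else rep_len(k_per_model, length(scheme$classes))

  sels <- vector("list", length(scheme$classes))
  models <- vector("list", length(scheme$classes))
  names(models) <- sprintf("%s_vs_rest", scheme$classes)
  for (i in seq_along(scheme$classes)) {
    cls <- scheme$classes[i]
    y <- ifelse(lab == cls, cls, "rest")
    fit <- .fit_contrast(xm, y, positive = cls, n_ortho, i,
                         n_folds, cv_scheme, seed)
    models[[i]] <- fit
    sels[[i]] <- select_top_genes(splot(fit), ks[i], corr_tie_window,
                                  balanced = balanced,
                                  source_model = names(models)[i])
  }
  merged <- .merge_selections(sels, k_total = NULL)
  attr(merged, "models") <- models
  attr(merged, "scheme") <- scheme
  merged
}

# fit one contrast with fixed or auto n_ortho (i-th model of a scheme)
.fit_contrast <- function(xm, y, positive, n_ortho, model_index,
                          n_folds, cv_scheme, seed) {
  no <- if (identical(n_ortho, "auto")) "auto"
        else rep_len(as.integer(n_ortho), model_index)[model_index]
  opls_fit_cv(xm, y, n_ortho = no, positive_class = positive,
              n_folds = n_folds, scheme = cv_scheme, seed = seed)
}

# union of per-model selections; duplicate gene keeps the higher-|corr|
# occurrence; optional top-up from a deeper ranking to reach k_total
.merge_selections <- function(sels, k_total = NULL, topup_from = NULL) {
  all <- do.call(rbind, lapply(sels, function(s) as.data.frame(s)))
  dup_log <- NULL
  if (anyDuplicated(all$gene_id)) {
    for (g in unique(all$gene_id[duplicated(all$gene_id)])) {
      rows <- which(all$gene_id == g)
      winner <- rows[which.max(abs(all$corr[rows]))]
      losers <- setdiff(rows, winner)
      dup_log <- rbind(dup_log, data.frame(
        gene_id = g, kept_model = all$source_model[winner],
        dropped_model = all$source_model[losers],
        stringsAsFactors = FALSE))
      all <- all[-losers, , drop = FALSE]
    }
  }
  if (!is.null(k_total)) {
    if (nrow(all) > k_total) {
      all <- all[order(-abs(all$corr)), ][seq_len(k_total), ]
    } else if (nrow(all) < k_total && !is.null(topup_from)) {
      extra <- topup_from[!topup_from$gene_id %in% all$gene_id, ]
      need <- min(k_total - nrow(all), nrow(extra))
      if (need > 0) all <- rbind(all, as.data.frame(extra[seq_len(need), ]))
    }
  }
  # stable order: by source model then rank
  all <- all[order(match(all$source_model, unique(all$source_model)),
                   all$rank), ]
  rownames(all) <- NULL
  class(all) <- c("gene_selection", "data.frame")
  attr(all, "duplicates_removed") <- dup_log
  all
}

#' One-versus-rest Welch t-test baseline selection
#'
#' For every contrast of the scheme (identical contrasts to the
#' corresponding OPLS-DA arrangement) computes a per-gene two-sample Welch
#' t-statistic on log10 expression, ranks genes by ascending p-value
#' (|t| descending breaks ties), and takes the top k per model. A
#' \eqn{10^{-12}} guard on the standard error keeps zero-variance genes
#' finite; they rank last.
#'
#' @param m an \code{expr_matrix} in state \code{"log10"} (uncentered).
#' @param scheme a \code{\link{class_scheme}}; both modes supported.
#' @param k genes per model; defaults to the scheme's \code{per_model_k}.
#' @return A \code{"gene_selection"} data.frame; \code{corr} holds the
#'   t statistic and \code{cov} the mean difference
#'   (positive class minus rest), direction from the sign of the mean
#'   difference; attribute \code{"pvalues"} carries the per-model tables.
#' @export
ovr_ttest_select <- function(m, scheme, k = NULL) {
  stopifnot(inherits(scheme, "class_scheme"))
  .require_state(m, c("log10", "centered"), "ovr_ttest_select")
  lab <- .check_scheme_data(m, scheme, min_n = 2)
  keep <- lab %in% scheme$classes
  xm <- .as_sample_gene_matrix(em_subset(m, samples = m$sample_ids[keep]))
  lab <- lab[keep]
  ks <- if (is.null(k)) scheme$per_model_k else
    rep_len(k, length(scheme$per_model_k))

  contrasts <- if (scheme$mode == "hierarchical") {
    h <- scheme$hierarchy
    list(list(name = sprintf("%s_vs_%s", h$outgroup, h$super),
              pos = lab == h$outgroup, neg = lab %in% h$subtypes),
         list(name = sprintf("%s_vs_%s", h$subtypes[1], h$subtypes[2]),
              pos = lab == h$subtypes[1], neg = lab == h$subtypes[2]))
  } else {
    lapply(scheme$classes, function(cls)
      list(name = sprintf("%s_vs_rest", cls), pos = lab == cls,
           neg = lab != cls))
  }

  sels <- vector("list", length(contrasts))
  ptabs <- vector("list", length(contrasts))
  for (i in seq_along(contrasts)) {
    ct <- contrasts[[i]]
    tt <- welch_t(xm[ct$pos, , drop = FALSE], xm[ct$neg, , drop = FALSE])
    ord <- order(tt$p, -abs(tt$t), colnames(xm))
    idx <- ord[seq_len(ks[i])]
    sels[[i]] <- structure(data.frame(
      gene_id = colnames(xm)[idx], source_model = ct$name,
      corr = tt$t[idx], cov = tt$mean_diff[idx],
      direction = ifelse(tt$mean_diff[idx] > 0, "up", "down"),
      rank = seq_along(idx), stringsAsFactors = FALSE),
      class = c("gene_selection", "data.frame"))
    ptabs[[i]] <- data.frame(gene_id = colnames(xm), t = tt$t, p = tt$p,
                             stringsAsFactors = FALSE)
    names(ptabs)[i] <- ct$name
  }
  merged <- .merge_selections(sels, k_total = NULL)
  attr(merged, "pvalues") <- ptabs
  attr(merged, "scheme") <- scheme
  merged
}

#' Vectorized Welch two-sample t-test per gene
#'
#' Unequal-variance t statistic and two-sided p-value for every column of
#' two sample x gene matrices, with a 1e-12 guard on the standard error so
#' zero-variance genes stay finite (t = 0 when the means also agree).
#'
#' @param a,b samples x genes matrices for the two groups (same columns).
#' @return A list of per-gene vectors: \code{t}, \code{df}, \code{p},
#'   \code{mean_diff} (a minus b).
#' @export
welch_t <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(pmax(se2, 1e-12^2))
  t <- (m1 - m2) / se
  df_num <- se2^2
  df_den <- (v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)
  df <- ifelse(df_den > 0, df_num / df_den, n1 + n2 - 2)
  df <- pmax(df, 1)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = unname(t), df = unname(df), p = unname(p),
       mean_diff = unname(m1 - m2))
}

#' Marker recovery against a planted ground truth
#'
#' Fraction of planted marker genes that appear in a selection panel,
#' overall and per contrast. Markers can be restricted to those present in
#' the analyzed matrix (genes the variation filter removed cannot be
#' selected by any method).
#'
#' @param selection a \code{"gene_selection"}.
#' @param truth a data.frame with columns \code{gene_id}, \code{contrast},
#'   \code{direction} (as produced by \code{\link{generate_expression}}).
#' @param retained_genes optional character vector of genes present in the
#'   analyzed matrix; markers outside it are excluded from the denominator
#'   (they are counted separately in \code{n_lost}).
#' @return A list: \code{recovery} (overall fraction), \code{per_contrast}
#'   (named vector), \code{n_truth}, \code{n_lost},
#'   \code{recovery_all} (denominator = all planted markers).
#' @export
marker_recovery <- function(selection, truth, retained_genes = NULL) {
  sel <- unique(selection$gene_id)
  n_all <- nrow(truth)
  kept <- truth
  n_lost <- 0L
  if (!is.null(retained_genes)) {
    lost <- !truth$gene_id %in% retained_genes
    n_lost <- sum(lost)
    kept <- truth[!lost, , drop = FALSE]
  }
  hit <- kept$gene_id %in% sel
  per <- vapply(split(hit, kept$contrast), mean, numeric(1))
  list(recovery = mean(hit), per_contrast = per, n_truth = nrow(kept),
       n_lost = n_lost,
       recovery_all = sum(truth$gene_id %in% sel) / n_all)
}
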