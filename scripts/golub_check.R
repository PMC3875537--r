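#!/usr/bin/env Rscript
# Optional reproduction on the Golub (1999) leukemia training set, which
# must be supplied locally (it is distributed as supplementary files of
# the original publication and is not bundled here). Expects:
#   --expr   genes x samples table (GCT or TSV) of the 38-sample,
#            7129-probe training set, raw intensities
#   --labels CLS or two-column TSV mapping the 38 samples to
#            ALL-B / ALL-T / AML
# Reports: genes retained by the variation filter (expected 3571), fit
# statistics of the two hierarchical and three parallel OPLS-DA models,
# and the duplicate count of the parallel top-17x3 panel.
#
# Usage: Rscript scripts/golub_check.R --expr <file> --labels <file>

suppressPackageStartupMessages(library(moplsda))

args <- commandArgs(trailingOnly = TRUE)
opt <- list()
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1]
  i <- i + 2
}
if (is.null(opt$expr) || is.null(opt$labels))
  stop("usage: Rscript scripts/golub_check.R --expr <file> --labels <file>")

raw <- read_expression(opt$expr)
raw$labels <- read_labels(opt$labels, sample_ids = raw$sample_ids)
pp <- preprocess(raw)
cat(sprintf("genes retained by variation filter: %d (expected 3571)\n",
            nrow(pp$values)))

classes <- sort(unique(pp$labels))
hier <- list(super = "ALL", subtypes = c("ALL-B", "ALL-T"),
             outgroup = "AML")

cat("\nhierarchical arrangement (AML vs ALL, then ALL-B vs ALL-T):\n")
sel_h <- hierarchical_select(
  pp, class_scheme("hierarchical", classes, hierarchy = hier),
  n_ortho = c(2, 2), k_total = 50)
for (nm in names(attr(sel_h, "models"))) {
  m <- attr(sel_h, "models")[[nm]]
  cat(sprintf("  %-18s R2X=%.3f R2Y=%.3f Q2Y=%.3f (p=%.3g)\n", nm,
              m$r2x, m$r2y, m$q2y, m$cv_anova$p_value))
}
print(table(sel_h$source_model, sel_h$direction))

cat("\nparallel one-versus-rest arrangement (top 17 per model):\n")
sel_p <- parallel_ovr_select(pp, class_scheme("parallel", classes),
                             n_ortho = "auto", k_per_model = 17)
for (nm in names(attr(sel_p, "models"))) {
  m <- attr(sel_p, "models")[[nm]]
  cat(sprintf("  %-18s R2X=%.3f R2Y=%.3f Q2Y=%.3f\n", nm, m$r2x, m$r2y,
              m$q2y))
}
dup <- attr(sel_p, "duplicates_removed")
cat(sprintf("panel size %d, duplicate picks: %s\n", nrow(sel_p),
            if (is.null(dup)) "none" else paste(dup$gene_id,
                                                collapse = ", ")))

panel <- em_subset(pp, genes = unique(sel_p$gene_id))
ev <- count_misclassified(hcluster(panel, "euclidean", "complete"),
                          panel$labels)
cat(sprintf("cluster misclassification on the top-50 panel: %d\n",
            ev$n_misclassified))
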