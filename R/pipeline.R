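#' Run the full selection pipeline from a configuration
#'
#' Executes preprocess -> multi-model selection -> evaluation and writes
#' the panel TSV, evaluation JSON, dendrogram Newick and a run manifest
#' (input digests, parameters, package version) to \code{out_dir}.
#' Rerunning with the same config and inputs reproduces byte-identical
#' outputs.
#'
#' Config keys (a named list, or a YAML file path): \code{seed};
#' \code{expr} + \code{labels} (input files) or \code{simulate} (arguments
#' to \code{\link{synthetic_spec}}); \code{preprocess} (floor, ceiling,
#' fold_min, range_min); \code{select} (mode, classes, hierarchy,
#' k_total, k_per_model, n_ortho, method \code{"oplsda"} or
#' \code{"ttest"}, balanced); \code{evaluate} (distance, linkage,
#' k_clusters); \code{out_dir}. Unknown keys are rejected before any
#' computation starts.
#'
#' @param config named list or path to a YAML config document.
#' @return Invisibly, a list with the preprocessed matrix, selection,
#'   fitted models, evaluation and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || length(config) == 0)
    stop("config must be a non-empty named list or YAML file")
  known <- c("seed", "expr", "labels", "simulate", "preprocess", "select",
             "evaluate", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$select) || is.null(config$select$mode))
    stop("config$select$mode is required ('hierarchical' or 'parallel')")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) message(sprintf("[moplsda %6.1fs] ",
                                             proc.time()[["elapsed"]] - t0),
                                     ...)

  inputs <- list()
  truth <- NULL
  if (!is.null(config$simulate)) {
    log_stage("simulate")
    spec <- do.call(synthetic_spec,
                    c(config$simulate,
                      if (is.null(config$simulate$seed)) list(seed = seed)))
    gen <- generate_expression(spec)
    raw <- gen$expr
    truth <- gen$truth
  } else {
    if (is.null(config$expr) || is.null(config$labels))
      stop("config needs either 'simulate' or both 'expr' and 'labels'")
    log_stage("read ", config$expr)
    raw <- read_expression(config$expr)
    raw$labels <- read_labels(config$labels, sample_ids = raw$sample_ids)
    inputs <- list(expr = unname(tools::md5sum(config$expr)),
                   labels = unname(tools::md5sum(config$labels)))
  }

  log_stage("preprocess (", nrow(raw$values), " genes)")
  pp_args <- config$preprocess
  centered <- do.call(preprocess, c(list(raw), pp_args))
  log_stage("retained ", nrow(centered$values), " genes")

  sc <- config$select
  classes <- if (!is.null(sc$classes)) sc$classes else
    sort(unique(centered$labels))
  hierarchy <- sc$hierarchy
  if (!is.null(hierarchy)) hierarchy$subtypes <- unlist(hierarchy$subtypes)
  scheme <- class_scheme(sc$mode, classes, hierarchy = hierarchy,
                         per_model_k = sc$per_model_k)
  n_ortho <- if (is.null(sc$n_ortho)) "auto" else sc$n_ortho
  method <- if (is.null(sc$method)) "oplsda" else sc$method
  log_stage("select (", method, ", ", sc$mode, ")")
  sel <- if (method == "ttest") {
    uncentered <- do.call(preprocess, c(list(raw), pp_args,
                                        list(center = FALSE)))
    k <- if (sc$mode == "hierarchical") {
      if (is.null(sc$k_total)) NULL else NULL
    } else sc$k_per_model
    ovr_ttest_select(uncentered, scheme, k = k)
  } else if (sc$mode == "hierarchical") {
    hierarchical_select(centered, scheme, n_ortho = n_ortho,
                        k_total = if (is.null(sc$k_total)) 50 else
                          sc$k_total,
                        balanced = isTRUE(sc$balanced), seed = seed)
  } else {
    parallel_ovr_select(centered, scheme, n_ortho = n_ortho,
                        k_per_model = sc$k_per_model,
                        balanced = isTRUE(sc$balanced), seed = seed)
  }
  write_selection(sel, file.path(config$out_dir, "panel.tsv"))

  ec <- config$evaluate
  distance <- if (is.null(ec$distance)) "euclidean" else ec$distance
  linkage <- if (is.null(ec$linkage)) "average" else ec$linkage
  log_stage("evaluate (", distance, " + ", linkage, ")")
  panel <- em_subset(centered, genes = unique(sel$gene_id))
  tree <- hcluster(panel, distance = distance, linkage = linkage)
  evaluation <- count_misclassified(tree, panel$labels,
                                    k_clusters = ec$k_clusters)
  tree_newick(tree, file.path(config$out_dir, "dendrogram.nwk"))
  pca <- expr_pca(panel, n_components = min(3, dim(panel)[2] - 1))
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), class = panel$labels,
               pca$scores, check.names = FALSE),
    file.path(config$out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  models <- attr(sel, "models")
  eval_out <- list(
    n_genes_retained = nrow(centered$values),
    panel_size = nrow(sel),
    duplicates_removed = attr(sel, "duplicates_removed"),
    n_misclassified = evaluation$n_misclassified,
    misclassified = evaluation$misclassified,
    distance = distance, linkage = linkage,
    pca_explained = pca$explained_fraction,
    model_stats = if (!is.null(models)) lapply(models, function(f)
      list(n_ortho = f$n_ortho, r2x = f$r2x, r2y = f$r2y, q2y = f$q2y,
           cv_anova_p = f$cv_anova$p_value)))
  if (!is.null(truth)) {
    rec <- marker_recovery(sel, truth, retained_genes = centered$gene_ids)
    eval_out$marker_recovery <- rec$recovery
    eval_out$marker_recovery_all_planted <- rec$recovery_all
  }
  jsonlite::write_json(eval_out, file.path(config$out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  manifest <- list(
    tool = "moplsda",
    version = as.character(utils::packageVersion("moplsda")),
    seed = seed, inputs = inputs, config = config,
    outputs = c("panel.tsv", "eval.json", "dendrogram.nwk",
                "pca_scores.tsv"))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log_stage("done -> ", config$out_dir)
  invisible(list(preprocessed = centered, selection = sel,
                 models = models, evaluation = evaluation,
                 manifest = manifest, truth = truth))
}

# ---------------------------------------------------------------------------
# command-line entry point; inst/cli/moplsda.R dispatches here. Thin
# wrappers over the exported functions; each subcommand prints where its
# outputs went.

cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: moplsda <simulate|preprocess|fit|splot|select|evaluate|run> [options]\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opts <- .cli_opts(rest)
  switch(cmd,
         simulate = .cli_simulate(opts),
         preprocess = .cli_preprocess(opts),
         fit = .cli_fit(opts),
         splot = .cli_splot(opts),
         select = .cli_select(opts),
         evaluate = .cli_evaluate(opts),
         run = {
           run_pipeline(.cli_req(opts, "config"))
           invisible(0L)
         },
         stop("unknown subcommand: ", cmd))
  invisible(0L)
}

# parse --key value pairs (and bare --flag) into a named list
.cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}

.cli_req <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key)
  opts[[key]]
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

.cli_simulate <- function(o) {
  spec_args <- if (!is.null(o$spec)) yaml::read_yaml(o$spec) else list()
  spec_args$seed <- .cli_num(o, "seed", 1)
  gen <- generate_expression(do.call(synthetic_spec, spec_args))
  write_expression(gen$expr, .cli_req(o, "out"))
  if (!is.null(o$labels)) write_labels(gen$expr$labels, o$labels)
  if (!is.null(o$truth))
    utils::write.table(gen$truth, o$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  message("wrote ", o$out)
}

.cli_preprocess <- function(o) {
  m <- read_expression(.cli_req(o, "expr"))
  out <- preprocess(m, floor = .cli_num(o, "floor", 100),
                    ceiling = .cli_num(o, "ceiling", 16000),
                    fold_min = .cli_num(o, "fold-min", 5),
                    range_min = .cli_num(o, "range-min", 500),
                    center = !isTRUE(o[["no-center"]]))
  write_expression(out, .cli_req(o, "out"))
  if (!is.null(o$report)) {
    rep <- attr(out, "filter_report")
    jsonlite::write_json(rep[c("kept", "dropped", "fold_min", "range_min")],
                         o$report, auto_unbox = TRUE, pretty = TRUE)
  }
  message("wrote ", o$out, " (", nrow(out$values), " genes retained)")
}

.cli_fit <- function(o) {
  m <- read_expression(.cli_req(o, "expr"), state = "log10")
  m$labels <- read_labels(.cli_req(o, "labels"), sample_ids = m$sample_ids)
  n_ortho <- if (is.null(o[["n-ortho"]]) || o[["n-ortho"]] == "auto")
    "auto" else as.integer(o[["n-ortho"]])
  fit <- opls_fit_cv(m, positive_class = .cli_req(o, "positive"),
                     n_ortho = n_ortho,
                     n_folds = .cli_num(o, "folds", 7),
                     seed = .cli_num(o, "seed", 1))
  print(fit)
  write_opls(fit, .cli_req(o, "out"))
  message("wrote ", o$out)
}

.cli_splot <- function(o) {
  fit <- read_opls(.cli_req(o, "model"))
  sp <- splot(fit)
  sel <- select_top_genes(sp, k = .cli_num(o, "top", 50),
                          source_model = basename(o$model))
  write_selection(sel, .cli_req(o, "out"))
  message("wrote ", o$out)
}

.cli_select <- function(o) {
  m <- read_expression(.cli_req(o, "expr"), state = "log10")
  m$labels <- read_labels(.cli_req(o, "labels"), sample_ids = m$sample_ids)
  centered <- mean_center(m)
  mode <- .cli_req(o, "mode")
  hierarchy <- if (!is.null(o$hierarchy)) .parse_hierarchy(o$hierarchy)
  scheme <- class_scheme(mode, sort(unique(m$labels)),
                         hierarchy = hierarchy)
  sel <- if (mode == "hierarchical")
    hierarchical_select(centered, scheme,
                        k_total = .cli_num(o, "k", 50),
                        seed = .cli_num(o, "seed", 1))
  else
    parallel_ovr_select(centered, scheme,
                        k_per_model = .cli_num(o, "k-per-model", 17),
                        seed = .cli_num(o, "seed", 1))
  write_selection(sel, .cli_req(o, "out"))
  if (!is.null(o[["models-dir"]])) {
    dir.create(o[["models-dir"]], showWarnings = FALSE, recursive = TRUE)
    models <- attr(sel, "models")
    for (nm in names(models))
      write_opls(models[[nm]],
                 file.path(o[["models-dir"]], paste0(nm, ".oplsda.json")))
  }
  message("wrote ", o$out, " (", nrow(sel), " genes)")
}

# "ALL:ALL-B,ALL-T;out:AML" -> list(super, subtypes, outgroup)
.parse_hierarchy <- function(s) {
  parts <- strsplit(s, ";")[[1]]
  sup <- strsplit(parts[1], ":")[[1]]
  out <- strsplit(parts[2], ":")[[1]]
  list(super = sup[1], subtypes = strsplit(sup[2], ",")[[1]],
       outgroup = out[2])
}

.cli_evaluate <- function(o) {
  m <- read_expression(.cli_req(o, "expr"), state = "log10")
  m$labels <- read_labels(.cli_req(o, "labels"), sample_ids = m$sample_ids)
  centered <- mean_center(m)
  if (!is.null(o$panel)) {
    sel <- read_selection(o$panel)
    centered <- em_subset(centered, genes = unique(sel$gene_id))
  }
  tree <- hcluster(centered,
                   distance = if (is.null(o$distance)) "euclidean" else
                     o$distance,
                   linkage = if (is.null(o$linkage)) "average" else
                     o$linkage)
  ev <- count_misclassified(tree, centered$labels,
                            k_clusters = if (is.null(o$k)) NULL else
                              as.integer(o$k))
  print(ev)
  jsonlite::write_json(
    list(n_misclassified = ev$n_misclassified,
         misclassified = ev$misclassified, mapping = as.list(ev$mapping),
         distance = attr(tree, "distance"),
         linkage = attr(tree, "linkage")),
    .cli_req(o, "out"), auto_unbox = TRUE, pretty = TRUE)
  message("wrote ", o$out)
}
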