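# shared small synthetic datasets; 400 genes keeps these tests quick, and
# the raised/tightened baselines keep every planted marker above the
# variation filter so the selector sees the full truth set
small_parallel <- function(seed = 11)
  synthetic_preprocessed(seed = seed, n_genes = 400, n_markers_up = 5,
                         n_markers_down = 5, baseline_log_mean = 3.2,
                         baseline_log_sd = 0.25)
small_hier <- function(seed = 11)
  synthetic_preprocessed(seed = seed, hierarchy = default_hierarchy(),
                         n_genes = 400, n_markers_up = 5, n_markers_down = 5,
                         baseline_log_mean = 3.2, baseline_log_sd = 0.25)

test_that("class_scheme validates its structure", {
  classes <- c("ALL-B", "ALL-T", "AML")
  h <- default_hierarchy()
  sch <- class_scheme("hierarchical", classes, hierarchy = h)
  expect_identical(sch$per_model_k, c(40L, 10L))
  expect_identical(class_scheme("parallel", classes)$per_model_k,
                   rep(17L, 3))
  expect_error(class_scheme("hierarchical", classes), "hierarchy")
  expect_error(class_scheme("hierarchical", classes[1:2], hierarchy = h),
               "three")
  expect_error(class_scheme("parallel", c("A", "B")), "three")
  expect_error(class_scheme("parallel", classes, per_model_k = c(1, 2)),
               "one entry per class")
  expect_error(class_scheme("hierarchical", classes,
                            hierarchy = list(super = "S",
                                             subtypes = c("ALL-B", "AML"),
                                             outgroup = "AML")),
               "outgroup")
  bad <- class_scheme("parallel", classes)
  expect_error(class_scheme("parallel", c("A", "A", "B")), "distinct")
})

test_that("hierarchical selection recovers disjoint planted contrast markers", {
  d <- small_hier()
  sch <- class_scheme("hierarchical", c("ALL-B", "ALL-T", "AML"),
                      hierarchy = default_hierarchy(),
                      per_model_k = c(10, 10))
  sel <- hierarchical_select(d$pp, sch, n_ortho = 1, k_total = 20)
  rec <- marker_recovery(sel, d$truth, retained_genes = d$pp$gene_ids)
  expect_gte(rec$recovery, 0.9)
  models <- attr(sel, "models")
  expect_length(models, 2)
  # model 2 is fitted only on the super-class samples
  n_super <- sum(d$pp$labels %in% c("ALL-B", "ALL-T"))
  expect_equal(length(models[[2]]$t), n_super)
  expect_equal(length(models[[1]]$t), length(d$pp$labels))
  # bookkeeping: each selected gene has exactly one source model
  expect_false(anyDuplicated(sel$gene_id) > 0)
})

test_that("hierarchical top-up keeps the panel at k_total after dedup", {
  d <- small_hier()
  sch <- class_scheme("hierarchical", c("ALL-B", "ALL-T", "AML"),
                      hierarchy = default_hierarchy(),
                      per_model_k = c(15, 15))
  sel <- hierarchical_select(d$pp, sch, n_ortho = 1, k_total = 30)
  dup <- attr(sel, "duplicates_removed")
  n_dup <- if (is.null(dup)) 0 else nrow(dup)
  expect_equal(nrow(sel), 30)  # topped up from model 1 when dup > 0
  expect_false(anyDuplicated(sel$gene_id) > 0)
})

test_that("tiny per-model counts behave: top-1 from each contrast", {
  d <- small_hier()
  sch <- class_scheme("hierarchical", c("ALL-B", "ALL-T", "AML"),
                      hierarchy = default_hierarchy(),
                      per_model_k = c(1, 1))
  sel <- hierarchical_select(d$pp, sch, n_ortho = 1, k_total = 2)
  expect_equal(nrow(sel), 2)
  expect_setequal(unique(sel$source_model),
                  c("AML_vs_ALL", "ALL-B_vs_ALL-T"))
})

test_that("parallel OVR selection with disjoint markers has no duplicates", {
  d <- small_parallel()
  sch <- class_scheme("parallel", c("ALL-B", "ALL-T", "AML"))
  sel <- parallel_ovr_select(d$pp, sch, n_ortho = 1, k_per_model = 10)
  rec <- marker_recovery(sel, d$truth, retained_genes = d$pp$gene_ids)
  expect_gte(rec$recovery, 0.9)
  expect_equal(nrow(sel), 30)  # 3 x 10, zero duplicates
  expect_null(attr(sel, "duplicates_removed"))
  counts <- table(sel$source_model)
  expect_true(all(counts == 10))
})

test_that("duplicate picks are merged keeping the higher-|corr| occurrence", {
  # one gene separates AML from everything, so every OVR model ranks it
  set.seed(50)
  n <- c(8, 8, 8)
  lab <- rep(c("A", "B", "C"), n)
  x <- matrix(rnorm(24 * 20, sd = 0.3), 24, 20)
  colnames(x) <- sprintf("g%02d", 1:20)
  rownames(x) <- sprintf("s%02d", 1:24)
  x[lab == "C", 1] <- x[lab == "C", 1] + 4   # shared marker
  x[lab == "A", 2] <- x[lab == "A", 2] + 3
  x[lab == "B", 3] <- x[lab == "B", 3] + 3
  m <- expression_matrix(t(x), labels = lab, state = "centered")
  sch <- class_scheme("parallel", c("A", "B", "C"))
  sel <- parallel_ovr_select(m, sch, n_ortho = 0, k_per_model = 2)
  dup <- attr(sel, "duplicates_removed")
  expect_false(anyDuplicated(sel$gene_id) > 0)
  expect_false(is.null(dup))
  expect_true("g01" %in% dup$gene_id)
  # panel size accounts for every merged duplicate
  expect_equal(nrow(sel), 3 * 2 - nrow(dup))
  # the surviving row is attributed to the model the dedup log says won
  expect_identical(sel$source_model[sel$gene_id == "g01"],
                   dup$kept_model[dup$gene_id == "g01"][1])
})

test_that("permuting class order leaves the panel unchanged as a set", {
  d <- small_parallel()
  sel1 <- parallel_ovr_select(d$pp, class_scheme(
    "parallel", c("ALL-B", "ALL-T", "AML")), n_ortho = 1, k_per_model = 8)
  sel2 <- parallel_ovr_select(d$pp, class_scheme(
    "parallel", c("AML", "ALL-B", "ALL-T")), n_ortho = 1, k_per_model = 8)
  expect_setequal(sel1$gene_id, sel2$gene_id)
})

test_that("selectors enforce class presence and sample-size floors", {
  d <- small_parallel()
  pp <- d$pp
  sch <- class_scheme("parallel", c("ALL-B", "ALL-T", "XYZ"))
  expect_error(parallel_ovr_select(pp, sch), "absent")
  few <- em_subset(pp, samples = pp$sample_ids[
    c(which(pp$labels == "ALL-B"), which(pp$labels == "ALL-T")[1:2],
      which(pp$labels == "AML"))])
  expect_error(parallel_ovr_select(
    few, class_scheme("parallel", c("ALL-B", "ALL-T", "AML")),
    n_ortho = 1), "fewer than")
  expect_error(hierarchical_select(
    pp, class_scheme("parallel", c("ALL-B", "ALL-T", "AML"))),
    "hierarchical")
})

test_that("welch_t matches the textbook Welch test", {
  a <- matrix(c(5.1, 4.8, 5.6, 1.0, 1.4, 0.9), 3, 2)
  b <- matrix(c(3.9, 4.4, 3.6, 1.1, 1.2, 1.3), 3, 2)
  w <- welch_t(a, b)
  for (g in 1:2) {
    ref <- t.test(a[, g], b[, g])
    expect_equal(w$t[g], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df[g], unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p[g], ref$p.value, tolerance = 1e-10)
  }
  # random wider check
  set.seed(51)
  A <- matrix(rnorm(8 * 6), 8, 6)
  B <- matrix(rnorm(10 * 6, mean = 0.5), 10, 6)
  w2 <- welch_t(A, B)
  for (g in 1:6)
    expect_equal(w2$p[g], t.test(A[, g], B[, g])$p.value, tolerance = 1e-10)
})

test_that("welch_t survives zero-variance genes via the epsilon guard", {
  a <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2)
  b <- matrix(c(1, 1, 1, 5, 6, 7), 3, 2)
  w <- welch_t(a, b)
  expect_equal(w$t[1], 0)  # identical constant means
  expect_true(all(is.finite(w$t)))
})

test_that("OVR t-test baseline ranks by p and honors configured counts", {
  d <- small_hier()
  lg <- preprocess(d$raw, center = FALSE)
  sch <- class_scheme("hierarchical", c("ALL-B", "ALL-T", "AML"),
                      hierarchy = default_hierarchy(),
                      per_model_k = c(8, 4))
  sel <- ovr_ttest_select(lg, sch)
  counts <- table(sel$source_model)
  dup <- attr(sel, "duplicates_removed")
  expect_equal(nrow(sel) + if (is.null(dup)) 0 else nrow(dup), 12)
  expect_true(all(sel$rank[sel$source_model == "AML_vs_ALL"] ==
                    seq_len(sum(sel$source_model == "AML_vs_ALL"))))
  # a gene with identical group means ranks last
  ptab <- attr(sel, "pvalues")[["AML_vs_ALL"]]
  expect_true(all(diff(ptab$p[order(ptab$p)]) >= 0))
  # parallel mode produces one model per class
  sel_p <- ovr_ttest_select(lg, class_scheme("parallel",
                                             c("ALL-B", "ALL-T", "AML")),
                            k = 5)
  expect_setequal(unique(sel_p$source_model),
                  c("ALL-B_vs_rest", "ALL-T_vs_rest", "AML_vs_rest"))
})

test_that("t-test baseline recovers strong planted markers too", {
  d <- small_parallel()
  lg <- preprocess(d$raw, center = FALSE)
  sel <- ovr_ttest_select(lg, class_scheme("parallel",
                                           c("ALL-B", "ALL-T", "AML")),
                          k = 10)
  rec <- marker_recovery(sel, d$truth, retained_genes = lg$gene_ids)
  expect_gte(rec$recovery, 0.8)
})
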