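# Small in-code datasets shared by the tests.

# two-class samples x genes matrix with the first n_marker genes shifted
# in class B
two_class_matrix <- function(n1 = 8, n2 = 8, n_genes = 12, effect = 2,
                             noise = 1, n_marker = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * n_genes, sd = noise), n1 + n2, n_genes)
  y <- rep(c("A", "B"), c(n1, n2))
  x[y == "B", seq_len(n_marker)] <- x[y == "B", seq_len(n_marker)] + effect
  colnames(x) <- sprintf("g%02d", seq_len(n_genes))
  rownames(x) <- sprintf("s%02d", seq_len(n1 + n2))
  list(x = x, y = y)
}

# raw expr_matrix with hand-set values (positive), for preprocessing tests
toy_raw_matrix <- function(values, labels = NULL) {
  ng <- nrow(values)
  ns <- ncol(values)
  expression_matrix(values,
                    gene_ids = sprintf("g%d", seq_len(ng)),
                    sample_ids = sprintf("s%d", seq_len(ns)),
                    labels = labels, state = "raw")
}

# default synthetic three-class data, parallel contrasts, preprocessed
synthetic_preprocessed <- function(seed = 11, hierarchy = NULL, ...) {
  d <- generate_expression(synthetic_spec(seed = seed,
                                          hierarchy = hierarchy, ...))
  list(pp = preprocess(d$expr), truth = d$truth, raw = d$expr)
}

default_hierarchy <- function() {
  list(super = "ALL", subtypes = c("ALL-B", "ALL-T"), outgroup = "AML")
}
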