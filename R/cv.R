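#' Cross-validated Q2 for an OPLS-DA contrast
#'
#' K-fold cross-validation of the predictive ability
#' \deqn{Q^2 = 1 - PRESS/SS}
#' where \eqn{PRESS = \sum_i (y_i - \hat y_i^{(-fold)})^2} accumulates the
#' squared prediction error of each sample when its fold is held out, and
#' \eqn{SS = \sum_i (y_i - \bar y)^2} is the total response sum of squares
#' about the full-data mean. Each fold refits the model on the remaining
#' samples, re-centering X and y within the fold's training part.
#'
#' @param x samples x genes matrix (any centering; folds re-center), or an
#'   \code{expr_matrix} in state \code{"log10"} or \code{"centered"}.
#' @param y class vector as in \code{\link{opls}}.
#' @param n_ortho orthogonal components per refit.
#' @param n_folds number of folds, default 7.
#' @param scheme fold assignment: \code{"venetian_blind"} (deterministic,
#'   sample i of the stable sample-id ordering goes to fold
#'   \code{i mod n_folds}; the default, reproducible without a seed),
#'   \code{"contiguous"} blocks, or \code{"random"} (requires \code{seed}).
#' @param seed RNG seed for \code{scheme = "random"}.
#' @param positive_class,scale passed to \code{\link{opls}}.
#' @return A list of class \code{"opls_cv"}: \code{q2y}, \code{press},
#'   \code{ss}, \code{n_ortho}, \code{n_folds}, \code{n_samples},
#'   \code{folds}, per-sample held-out predictions \code{y_hat_cv}.
#' @export
opls_cv <- function(x, y, n_ortho = 0, n_folds = 7,
                    scheme = c("venetian_blind", "contiguous", "random"),
                    seed = NULL, positive_class = NULL,
                    scale = "center") {
  scheme <- match.arg(scheme)
  if (inherits(x, "expr_matrix") && missing(y)) {
    lab <- .require_labels(x)
    if (is.null(positive_class)) stop("positive_class required")
    y <- if (length(unique(lab)) > 2)
      ifelse(lab == positive_class, positive_class, "rest") else lab
  }
  xm <- .as_sample_gene_matrix(x)
  yd <- dummy_response(y, positive_class)
  yv <- yd$values
  n <- nrow(xm)
  if (length(yv) != n) stop("length(y) must match the sample count")
  if (n_folds < 2 || n_folds > n) stop("n_folds must be in [2, n_samples]")

  folds <- .cv_folds(n, n_folds, scheme, seed,
                     sample_ids = rownames(xm))
  y_hat <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(yv[train])) < 2)
      stop("fold ", f, " leaves a single-class training part; ",
           "use fewer folds or a stratified scheme")
    fit <- opls(xm[train, , drop = FALSE],
                ifelse(yv[train] == 1, yd$positive_class, "rest__"),
                n_ortho = n_ortho, positive_class = yd$positive_class,
                scale = scale)
    y_hat[test] <- predict(fit, xm[test, , drop = FALSE])$y_hat
  }
  press <- sum((yv - y_hat)^2)
  ss <- sum((yv - mean(yv))^2)
  structure(list(q2y = 1 - press / ss, press = press, ss = ss,
                 n_ortho = n_ortho, n_folds = n_folds, n_samples = n,
                 scheme = scheme, folds = folds, y = yv, y_hat_cv = y_hat),
            class = "opls_cv")
}

# internal fold assignment; venetian blind is deterministic under a stable
# ordering by sample id (falls back to input order without names)
.cv_folds <- function(n, n_folds, scheme, seed, sample_ids = NULL) {
  ord <- if (!is.null(sample_ids)) order(sample_ids) else seq_len(n)
  folds <- integer(n)
  if (scheme == "venetian_blind") {
    folds[ord] <- ((seq_len(n) - 1L) %% n_folds) + 1L
  } else if (scheme == "contiguous") {
    folds[ord] <- as.integer(cut(seq_len(n), n_folds, labels = FALSE))
  } else {
    if (is.null(seed)) stop("scheme = 'random' requires a seed")
    folds <- .with_seed(seed, sample(((seq_len(n) - 1L) %% n_folds) + 1L))
  }
  folds
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA %d-fold CV (%s), %d orthogonal: Q2Y = %.3f (PRESS = %.4g, SS = %.4g)\n",
    x$n_folds, x$scheme, x$n_ortho, x$q2y, x$press, x$ss))
  invisible(x)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Starts at 0 orthogonal components and accepts one more while the
#' cross-validated Q2 improves by more than \code{gain_threshold};
#' deterministic given the fold scheme and seed.
#'
#' @inheritParams opls_cv
#' @param max_ortho maximum orthogonal components to consider, default 5.
#' @param gain_threshold minimum Q2 improvement to accept a component,
#'   default 0.01.
#' @return The chosen count, with the Q2 path in attribute \code{"q2_path"}.
#' @export
select_n_ortho <- function(x, y, max_ortho = 5, gain_threshold = 0.01,
                           n_folds = 7, scheme = "venetian_blind",
                           seed = NULL, positive_class = NULL) {
  if (max_ortho < 0) stop("max_ortho must be >= 0")
  best <- 0L
  q2_path <- numeric(0)
  q2_best <- tryCatch(
    opls_cv(x, y, n_ortho = 0, n_folds = n_folds, scheme = scheme,
            seed = seed, positive_class = positive_class)$q2y,
    error = function(e) stop(e))
  q2_path <- c(q2_path, q2_best)
  k <- 0L
  while (k < max_ortho) {
    q2_next <- tryCatch(
      opls_cv(x, y, n_ortho = k + 1L, n_folds = n_folds, scheme = scheme,
              seed = seed, positive_class = positive_class)$q2y,
      error = function(e) NA_real_)  # rank exhausted: stop growing
    if (is.na(q2_next) || q2_next - q2_best <= gain_threshold) break
    k <- k + 1L
    q2_best <- q2_next
    q2_path <- c(q2_path, q2_next)
  }
  structure(k, q2_path = q2_path)
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F-test comparing the cross-validated prediction error against the total
#' response variation:
#' \deqn{F = \frac{(SS - PRESS)/d_1}{PRESS/d_2}}
#' with \eqn{d_1} the degrees of freedom consumed by the extracted
#' components (one per component: \code{1 + n_ortho}) and
#' \eqn{d_2 = n - d_1 - 1}. The p-value is the upper tail of
#' \eqn{F(d_1, d_2)}; a negative F (PRESS exceeding SS) maps to p = 1.
#'
#' @param cv an \code{opls_cv} result (or a list with \code{press} and
#'   \code{ss}).
#' @param n_samples number of samples; defaults to \code{cv$n_samples}.
#' @param n_components model degrees of freedom d1; defaults to
#'   \code{1 + cv$n_ortho}.
#' @return A list with \code{f}, \code{p_value}, \code{df1}, \code{df2}.
#' @export
cv_anova <- function(cv, n_samples = cv$n_samples,
                     n_components = 1 + cv$n_ortho) {
  press <- cv$press
  ss <- cv$ss
  if (!is.finite(press) || press <= 0) stop("press must be > 0")
  d1 <- n_components
  d2 <- n_samples - d1 - 1
  if (d2 <= 0)
    stop("insufficient samples: n - n_components - 1 must be > 0")
  f <- ((ss - press) / d1) / (press / d2)
  p <- if (f < 0) 1 else stats::pf(f, d1, d2, lower.tail = FALSE)
  list(f = f, p_value = p, df1 = d1, df2 = d2)
}

#' Fit, cross-validate and test one OPLS-DA contrast
#'
#' Convenience wrapper: fits \code{\link{opls}} (choosing \code{n_ortho}
#' automatically when \code{n_ortho = "auto"}), attaches Q2/PRESS/SS from
#' \code{\link{opls_cv}} and the \code{\link{cv_anova}} significance test.
#'
#' @inheritParams opls_cv
#' @param n_ortho integer count or \code{"auto"}.
#' @param max_ortho cap for the automatic rule.
#' @return An \code{opls} model with \code{q2y}, \code{press}, \code{ss}
#'   and \code{cv_anova} filled in.
#' @export
opls_fit_cv <- function(x, y, n_ortho = "auto", positive_class = NULL,
                        n_folds = 7, scheme = "venetian_blind", seed = NULL,
                        max_ortho = 5) {
  if (inherits(x, "expr_matrix") && missing(y)) {
    lab <- .require_labels(x)
    if (is.null(positive_class)) stop("positive_class required")
    y <- if (length(unique(lab)) > 2)
      ifelse(lab == positive_class, positive_class, "rest") else lab
    x <- .as_sample_gene_matrix(x)
  }
  if (identical(n_ortho, "auto"))
    n_ortho <- as.integer(select_n_ortho(
      x, y, max_ortho = max_ortho, n_folds = n_folds, scheme = scheme,
      seed = seed, positive_class = positive_class))
  fit <- opls(x, y, n_ortho = n_ortho, positive_class = positive_class)
  cv <- opls_cv(x, y, n_ortho = n_ortho, n_folds = n_folds, scheme = scheme,
                seed = seed, positive_class = positive_class)
  fit$q2y <- cv$q2y
  fit$press <- cv$press
  fit$ss <- cv$ss
  fit$cv_anova <- cv_anova(cv)
  fit
}

# run expr with a private RNG stream, restoring global .Random.seed
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
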