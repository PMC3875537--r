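#' Fit a two-class OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis by the NIPALS
#' sequence with built-in orthogonal signal correction: the class contrast
#' is coded as a 0/1 dummy response, structured X-variation uncorrelated
#' with the response is deflated into \code{n_ortho} orthogonal components,
#' and a single predictive component is extracted from the corrected
#' matrix. Variables are mean-centered only (no unit-variance scaling);
#' optional \code{"uv"} and \code{"pareto"} scaling are available but off
#' by default because log10 preprocessing already brings gene ranges onto a
#' comparable scale.
#'
#' The algorithm: with centered X (samples x genes) and centered dummy y,
#' \deqn{w \propto X^T y,\ \|w\| = 1}
#' then for each orthogonal component \eqn{t = Xw}, \eqn{p = X^T t/t^T t},
#' \eqn{w_o \propto p - (w^T p)w}, \eqn{t_o = X w_o},
#' \eqn{p_o = X^T t_o / t_o^T t_o}, \eqn{X \leftarrow X - t_o p_o^T};
#' finally \eqn{t = Xw}, \eqn{b = t^T y/t^T t}. The predictive score is
#' oriented so the positive class has positive mean score.
#'
#' @param x samples x genes numeric matrix, or an \code{expr_matrix} in
#'   state \code{"log10"} or \code{"centered"} (transposed internally).
#'   Columns are centered internally; the means used are stored for
#'   prediction.
#' @param y class membership: a factor/character/logical vector, or 0/1
#'   numeric. Exactly two classes, each with at least 2 samples. If \code{x}
#'   is a labelled \code{expr_matrix} and \code{y} is missing, labels are
#'   used (requires \code{positive_class}, others pooled as the rest).
#' @param n_ortho number of orthogonal (Y-uncorrelated) components to
#'   remove, default 0.
#' @param positive_class class coded 1. Defaults to the second factor level
#'   (or \code{1} for numeric y).
#' @param scale \code{"center"} (default), \code{"uv"} or \code{"pareto"}.
#' @return An object of class \code{"opls"}: a list with predictive weight
#'   \code{w} (unit norm), score \code{t}, loading \code{p}, inner
#'   coefficient \code{b}, orthogonal sets \code{W_o}, \code{T_o},
#'   \code{P_o}, centering/scaling parameters, and fit statistics
#'   \code{r2x}, \code{r2y}, \code{s_t}. Cross-validated \code{q2y} is
#'   added by \code{\link{opls_cv}}.
#' @seealso \code{\link{opls_cv}}, \code{\link{splot}},
#'   \code{\link{predict.opls}}
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(20 * 10), 20, 10)
#' y <- rep(c("A", "B"), each = 10)
#' x[y == "B", 1:3] <- x[y == "B", 1:3] + 2
#' fit <- opls(x, y, n_ortho = 1, positive_class = "B")
#' fit
#' @export
opls <- function(x, y, n_ortho = 0, positive_class = NULL,
                 scale = c("center", "uv", "pareto")) {
  scale <- match.arg(scale)
  if (inherits(x, "expr_matrix") && missing(y)) {
    lab <- .require_labels(x)
    if (is.null(positive_class))
      stop("positive_class required when deriving y from matrix labels")
    # one-versus-rest pooling when more than two classes are labelled
    y <- if (length(unique(lab)) > 2)
      ifelse(lab == positive_class, positive_class, "rest") else lab
  }
  xm <- .as_sample_gene_matrix(x)
  yd <- dummy_response(y, positive_class)
  if (length(yd$values) != nrow(xm))
    stop("length(y) must equal the number of samples (rows of x)")
  if (nrow(xm) < 4) stop("need at least 4 samples")
  if (n_ortho < 0) stop("n_ortho must be >= 0")

  x_means <- colMeans(xm)
  X0 <- sweep(xm, 2, x_means)
  x_scales <- rep(1, ncol(X0))
  if (scale != "center") {
    sd_x <- apply(X0, 2, stats::sd)
    x_scales <- switch(scale, uv = pmax(sd_x, 1e-12),
                       pareto = pmax(sqrt(sd_x), 1e-12))
    X0 <- sweep(X0, 2, x_scales, "/")
  }
  y0 <- yd$values - yd$y_mean
  ssx <- sum(X0^2)
  ssy <- sum(y0^2)

  w <- crossprod(X0, y0)[, 1]
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12 * sqrt(ssx * ssy / length(y0)) || wn == 0)
    stop("degenerate model: X carries no covariance with the class response")
  w <- w / wn

  ng <- ncol(X0)
  W_o <- T_o <- P_o <- NULL
  ss_ortho <- numeric(0)
  X <- X0
  for (i in seq_len(n_ortho)) {
    t_i <- drop(X %*% w)
    p_i <- drop(crossprod(X, t_i)) / sum(t_i^2)
    w_o <- p_i - sum(w * p_i) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10)
      stop("rank error: no Y-orthogonal variation left for component ", i)
    w_o <- w_o / nwo
    t_o <- drop(X %*% w_o)
    tto <- sum(t_o^2)
    if (tto < 1e-12)
      stop("rank error: orthogonal score ", i, " vanished")
    p_o <- drop(crossprod(X, t_o)) / tto
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    T_o <- cbind(T_o, t_o)
    P_o <- cbind(P_o, p_o)
    ss_ortho <- c(ss_ortho, tto * sum(p_o^2))
  }

  t <- drop(X %*% w)
  tt <- sum(t^2)
  if (tt < 1e-12) stop("rank error: predictive score vanished")
  p <- drop(crossprod(X, t)) / tt
  # orient so the positive class sits at positive t
  if (mean(t[yd$values == 1]) < 0) {
    w <- -w; t <- -t; p <- -p
  }
  b <- sum(t * y0) / tt

  r2y <- 1 - sum((y0 - b * t)^2) / ssy
  r2x <- (tt * sum(p^2) + sum(ss_ortho)) / ssx

  structure(list(
    w = w, t = t, p = p, b = b,
    W_o = W_o, T_o = T_o, P_o = P_o, n_ortho = n_ortho,
    x_means = x_means, x_scales = x_scales, scale = scale,
    y_mean = yd$y_mean, y = yd$values, positive_class = yd$positive_class,
    negative_class = yd$negative_class,
    gene_ids = colnames(xm), sample_ids = rownames(xm),
    x_centered = X0,
    r2x = r2x, r2y = r2y, q2y = NA_real_, press = NA_real_, ss = NA_real_,
    s_t = stats::sd(t)), class = "opls")
}

#' Build a 0/1 dummy response for a two-class contrast
#'
#' @param y factor/character/logical/0-1 numeric class vector.
#' @param positive_class class coded 1 (default: second factor level, or 1).
#' @return A list with \code{values} (0/1 vector), \code{positive_class},
#'   \code{negative_class} and \code{y_mean}.
#' @export
dummy_response <- function(y, positive_class = NULL) {
  if (is.logical(y)) y <- ifelse(y, "TRUE", "FALSE")
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1)) || length(u) != 2)
      stop("numeric y must contain exactly the codes 0 and 1")
    if (is.null(positive_class)) positive_class <- "1"
    y <- as.character(y)
  }
  f <- factor(y)
  if (nlevels(f) != 2)
    stop("y must contain exactly two classes, got: ",
         paste(levels(f), collapse = ", "))
  if (is.null(positive_class)) positive_class <- levels(f)[2]
  positive_class <- as.character(positive_class)
  if (!positive_class %in% levels(f))
    stop("positive_class '", positive_class, "' not among classes")
  v <- as.numeric(f == positive_class)
  if (sum(v) < 2 || sum(1 - v) < 2)
    stop("each class needs at least 2 samples")
  list(values = v, positive_class = positive_class,
       negative_class = setdiff(levels(f), positive_class),
       y_mean = mean(v))
}

#' Predict class scores for new samples
#'
#' Centers \code{newdata} with the training means, strips the model's
#' orthogonal components sequentially, and returns the predictive score
#' \eqn{t = Xw} and the unbounded fitted response
#' \eqn{\hat y = b t + \bar y}. Values above 0.5 lean toward the positive
#' class.
#'
#' @param object an \code{opls} model.
#' @param newdata samples x genes matrix in log10 units (uncentered), or an
#'   \code{expr_matrix} in state \code{"log10"} or \code{"centered"}. Gene
#'   set must match the training genes in order (matched by name when
#'   available). Defaults to the training data.
#' @param ... unused.
#' @return A list with \code{y_hat} and \code{scores} (predictive t), plus
#'   \code{t_ortho} (orthogonal scores, if any).
#' @export
predict.opls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- sweep(object$x_centered, 2, object$x_scales, "*")  # undo scaling
    X <- sweep(X, 2, object$x_means, "+")
  } else {
    X <- .as_sample_gene_matrix(newdata)
  }
  if (!is.null(colnames(X)) && !is.null(object$gene_ids)) {
    if (!setequal(colnames(X), object$gene_ids))
      stop("gene set of newdata does not match the model's training genes")
    X <- X[, object$gene_ids, drop = FALSE]
  } else if (ncol(X) != length(object$w)) {
    stop("newdata has ", ncol(X), " genes; model was trained on ",
         length(object$w))
  }
  X <- sweep(sweep(X, 2, object$x_means), 2, object$x_scales, "/")
  t_ortho <- NULL
  for (i in seq_len(object$n_ortho)) {
    t_o <- drop(X %*% object$W_o[, i])
    X <- X - tcrossprod(t_o, object$P_o[, i])
    t_ortho <- cbind(t_ortho, t_o)
  }
  t <- drop(X %*% object$w)
  list(y_hat = object$b * t + object$y_mean, scores = t, t_ortho = t_ortho)
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA: %s (1) vs %s (0), %d samples x %d genes\n",
    x$positive_class, paste(x$negative_class, collapse = "+"),
    length(x$t), length(x$w)))
  cat(sprintf("  components: 1 predictive + %d orthogonal\n", x$n_ortho))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2Y = %s\n", x$r2x, x$r2y,
              if (is.na(x$q2y)) "<not cross-validated>"
              else sprintf("%.3f", x$q2y)))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  structure(list(model = object), class = "summary.opls")
}

#' @export
print.summary.opls <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  inner coefficient b = %.4g, s_t = %.4g\n", m$b, m$s_t))
  if (!is.na(m$q2y))
    cat(sprintf("  PRESS = %.4g  SS = %.4g\n", m$press, m$ss))
  if (!is.null(m$cv_anova))
    cat(sprintf("  CV-ANOVA: F = %.3f on (%d, %d) df, p = %.3g\n",
                m$cv_anova$f, m$cv_anova$df1, m$cv_anova$df2,
                m$cv_anova$p_value))
  tab <- data.frame(class = ifelse(m$y == 1, m$positive_class,
                                   paste(m$negative_class, collapse = "+")),
                    t = m$t)
  agg <- stats::aggregate(t ~ class, tab, mean)
  cat("  mean predictive score by class:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %-12s %8.4f\n", agg$class[i], agg$t[i]))
  invisible(x)
}

#' @export
coef.opls <- function(object, type = c("loading", "weight"), ...) {
  type <- match.arg(type)
  out <- if (type == "loading") object$p else object$w
  stats::setNames(out, object$gene_ids)
}

#' @export
fitted.opls <- function(object, ...) {
  object$b * object$t + object$y_mean
}

#' @export
residuals.opls <- function(object, ...) {
  object$y - fitted(object)
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index
#' when the model has no orthogonal component), colored by class.
#'
#' @param x an \code{opls} model.
#' @param ... passed to \code{plot.default}.
#' @export
plot.opls <- function(x, ...) {
  t2 <- if (x$n_ortho > 0) x$T_o[, 1] else seq_along(x$t)
  ylab <- if (x$n_ortho > 0) "t_ortho[1]" else "sample index"
  graphics::plot(x$t, t2, col = ifelse(x$y == 1, 2, 4),
                 pch = ifelse(x$y == 1, 17, 19),
                 xlab = "t (predictive)", ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = c(x$positive_class,
                   paste(x$negative_class, collapse = "+")),
                   col = c(2, 4), pch = c(17, 19), bty = "n")
}
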