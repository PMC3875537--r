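test_that("Q2 reproduces a hand-accumulated fold computation exactly", {
  d <- two_class_matrix(n1 = 6, n2 = 6, n_genes = 8, effect = 2, seed = 21)
  n_folds <- 4
  cv <- opls_cv(d$x, d$y, n_ortho = 1, n_folds = n_folds,
                positive_class = "B")
  # accumulate PRESS by hand: refit per fold, predict the held-out part
  y <- as.numeric(d$y == "B")
  ord <- order(rownames(d$x))
  folds <- integer(12)
  folds[ord] <- ((seq_len(12) - 1L) %% n_folds) + 1L
  press <- 0
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    fit <- opls(d$x[-test, ], d$y[-test], n_ortho = 1,
                positive_class = "B")
    press <- press + sum((y[test] -
                            predict(fit, d$x[test, , drop = FALSE])$y_hat)^2)
  }
  ss <- sum((y - mean(y))^2)
  expect_identical(cv$folds, folds)
  expect_equal(cv$press, press, tolerance = 1e-12)
  expect_equal(cv$ss, ss, tolerance = 1e-12)
  expect_equal(cv$q2y, 1 - press / ss, tolerance = 1e-12)
})

test_that("venetian-blind CV is deterministic and PRESS is non-negative", {
  d <- two_class_matrix(seed = 22)
  a <- opls_cv(d$x, d$y, n_ortho = 0, positive_class = "B")
  b <- opls_cv(d$x, d$y, n_ortho = 0, positive_class = "B")
  expect_identical(a$q2y, b$q2y)
  expect_gte(a$press, 0)
  expect_lte(a$q2y, 1)
})

test_that("permuted labels give no predictive ability", {
  d <- two_class_matrix(n1 = 10, n2 = 10, n_genes = 30, effect = 3,
                        seed = 23)
  set.seed(101)
  q2 <- replicate(20, {
    yp <- sample(d$y)
    opls_cv(d$x, yp, n_ortho = 0, positive_class = "B")$q2y
  })
  expect_lt(mean(q2), 0.1)
})

test_that("a strong noiseless effect approaches perfect prediction", {
  set.seed(24)
  n <- 28
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 20, sd = 0.05), n, 20)
  x[y == "B", 1:5] <- x[y == "B", 1:5] + 5
  q2 <- opls_cv(x, y, n_ortho = 0, positive_class = "B")$q2y
  expect_gt(q2, 0.9)
})

test_that("folds whose training part is single-class are rejected", {
  d <- two_class_matrix(n1 = 2, n2 = 10, seed = 25)
  # 12 samples, 12 folds: some training parts lose class A entirely?
  # with n1 = 2 and leave-one-out both A samples stay unless one held out;
  # force the error with contiguous blocks of 6 (one block holds all of A)
  expect_error(opls_cv(d$x, d$y, n_folds = 6, scheme = "contiguous",
                       positive_class = "B"),
               "single-class|at least 2")
})

test_that("random fold scheme is reproducible from its seed", {
  d <- two_class_matrix(seed = 26)
  a <- opls_cv(d$x, d$y, scheme = "random", seed = 5, positive_class = "B")
  b <- opls_cv(d$x, d$y, scheme = "random", seed = 5, positive_class = "B")
  expect_identical(a$q2y, b$q2y)
  expect_error(opls_cv(d$x, d$y, scheme = "random", positive_class = "B"),
               "seed")
})

test_that("select_n_ortho returns 0 when X has a single y-aligned direction", {
  set.seed(27)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  latent <- (y - 0.5) * 2
  x <- outer(latent, rnorm(10)) + matrix(rnorm(n * 10, sd = 0.05), n, 10)
  expect_identical(as.integer(select_n_ortho(x, y, max_ortho = 3)), 0L)
})

test_that("select_n_ortho finds a strong y-orthogonal confounder", {
  set.seed(28)
  n <- 24
  y <- rep(c(0, 1), each = n / 2)
  z <- rnorm(n)          # confounder, independent of y
  z <- z - mean(z)
  x <- cbind(outer(y - 0.5, rep(1, 6)) + outer(z, rep(2, 6)),
             outer(z, rep(3, 8))) +
    matrix(rnorm(n * 14, sd = 0.05), n, 14)
  chosen <- select_n_ortho(x, y, max_ortho = 3)
  expect_gte(as.integer(chosen), 1L)
  path <- attr(chosen, "q2_path")
  expect_gt(path[length(path)], path[1])  # the component earned its keep
})

test_that("select_n_ortho honors max_ortho = 0", {
  d <- two_class_matrix(seed = 29)
  expect_identical(as.integer(select_n_ortho(d$x, d$y, max_ortho = 0)), 0L)
})

test_that("CV-ANOVA behaves at its analytic anchors", {
  base <- list(press = 10, ss = 10, n_samples = 38, n_ortho = 2)
  at_zero <- cv_anova(base)
  expect_equal(at_zero$f, 0)
  expect_equal(at_zero$p_value, 1)
  # press -> 0 drives the p-value to 0
  tiny <- cv_anova(list(press = 10 * 1e-6, ss = 10), n_samples = 38,
                   n_components = 3)
  expect_lt(tiny$p_value, 1e-6)
  # press > ss means negative F, reported as p = 1
  neg <- cv_anova(list(press = 12, ss = 10), n_samples = 38,
                  n_components = 3)
  expect_equal(neg$p_value, 1)
  expect_error(cv_anova(list(press = 5, ss = 10), n_samples = 4,
                        n_components = 3), "insufficient")
  expect_error(cv_anova(list(press = 0, ss = 10), n_samples = 38,
                        n_components = 3), "press")
})

test_that("a strong synthetic effect is highly significant under CV-ANOVA", {
  d <- two_class_matrix(n1 = 12, n2 = 12, n_genes = 40, effect = 3,
                        noise = 0.5, seed = 30)
  cv <- opls_cv(d$x, d$y, n_ortho = 0, positive_class = "B")
  expect_lt(cv_anova(cv)$p_value, 0.001)
})

test_that("opls_fit_cv attaches CV statistics to the fitted model", {
  d <- two_class_matrix(seed = 31, effect = 3)
  fit <- opls_fit_cv(d$x, d$y, n_ortho = "auto", positive_class = "B")
  expect_false(is.na(fit$q2y))
  expect_equal(fit$q2y, 1 - fit$press / fit$ss, tolerance = 1e-12)
  expect_true(is.list(fit$cv_anova))
  expect_output(print(summary(fit)), "CV-ANOVA")
})
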