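# PLS-DA (NIPALS), OPLS-DA and S-line loadings.

test_that("class encoding builds sorted indicator columns", {
  y <- encode_classes(c("B", "A", "B", "A"))
  expect_equal(colnames(y$indicator_matrix), c("A", "B"))
  expect_equal(unname(y$indicator_matrix[, "A"]), c(0, 1, 0, 1))
  expect_equal(y$binary, unname(y$indicator_matrix[, 1]),
               ignore_attr = TRUE)
  y4 <- encode_classes(rep(c("a", "b", "c", "d"), each = 3))
  expect_equal(ncol(y4$indicator_matrix), 4)
  expect_equal(unname(colSums(y4$indicator_matrix)), rep(3, 4))
  expect_null(y4$binary)
  expect_error(encode_classes(c("A", "B", "A")), "singleton")
  expect_error(encode_classes(rep("A", 4)), "2 classes")
})

test_that("a response living on X's first latent direction is fit by one component", {
  set.seed(1)
  t0 <- rnorm(30)
  p0 <- rnorm(6)
  X <- outer(t0, p0) + matrix(rnorm(30 * 6, sd = 1e-4), 30, 6)
  fit <- fit_plsda(X, cbind(y = t0), 1)
  expect_gte(fit$R2Y, 0.999)
})

test_that("NIPALS scores agree with the kernel-algorithm oracle and mixOmics", {
  set.seed(2)
  X <- matrix(rnorm(20 * 8), 20, 8)
  Y <- encode_classes(rep(c("a", "b"), each = 10))
  k <- 3
  fit <- fit_plsda(X, Y, k)
  oracle <- kernel_pls_oracle(X, Y$indicator_matrix, k)
  for (h in seq_len(k)) {
    s <- sign(sum(fit$x_scores[, h] * oracle[, h]))
    expect_equal(fit$x_scores[, h], s * oracle[, h], tolerance = 1e-6)
  }
  skip_if_not_installed("mixOmics")
  mo <- mixOmics::pls(X, Y$indicator_matrix, ncomp = k, scale = FALSE,
                      mode = "regression")
  for (h in seq_len(k)) {
    msc <- mo$variates$X[, h]
    s <- sign(sum(fit$x_scores[, h] * msc))
    expect_equal(unname(fit$x_scores[, h]), unname(s * msc),
                 tolerance = 1e-6)
  }
})

test_that("PLS score vectors are mutually orthogonal and rows equivariant", {
  set.seed(3)
  X <- matrix(rnorm(24 * 10), 24, 10)
  Y <- encode_classes(rep(c("a", "b", "c"), each = 8))
  fit <- fit_plsda(X, Y, 4)
  G <- crossprod(fit$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  # R2 bookkeeping
  expect_true(all(fit$R2X_per_component >= 0))
  expect_lte(fit$R2X, 1 + 1e-9)
  expect_true(fit$R2Y >= 0 && fit$R2Y <= 1)
  # permuting samples permutes score rows identically
  perm <- sample(24)
  fit_p <- fit_plsda(X[perm, ], Y$indicator_matrix[perm, ], 4)
  expect_equal(fit_p$x_scores, fit$x_scores[perm, ], tolerance = 1e-8)
})

test_that("OPLS-DA with no orthogonal components reduces to 1-component PLS-DA", {
  set.seed(4)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rep(c(0, 1), each = 15)
  op <- fit_oplsda(X, y, n_ortho = 0)
  pl <- fit_plsda(X, cbind(y = y), 1)
  s <- sign(sum(op$t * pl$x_scores[, 1]))
  expect_equal(op$t, s * pl$x_scores[, 1], tolerance = 1e-6)
  # identical predictions
  expect_equal(predict(op, X), drop(predict(pl, X)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("orthogonal filtering sharpens the predictive score (projection oracle)", {
  set.seed(5)
  n <- 60; p <- 10
  y <- rep(c(-1, 1), each = n / 2)
  v <- c(1, rep(0, p - 1))            # class direction
  u <- c(0, 1, rep(0, p - 2))         # strong orthogonal variation
  z <- rnorm(n, sd = 4)
  X <- outer(y, v) + outer(z, u) + matrix(rnorm(n * p, sd = 0.3), n, p)
  op <- fit_oplsda(X, (y + 1) / 2, n_ortho = 1)
  pl <- fit_plsda(X, cbind(y = y), 1)
  c_op <- abs(cor(op$t, y))
  c_pl <- abs(cor(pl$x_scores[, 1], y))
  expect_gt(c_op, c_pl)
  # oracle: explicit projection filter by hand linear algebra
  Xc <- scale(X, scale = FALSE)
  w <- drop(crossprod(Xc, y - mean(y))); w <- w / sqrt(sum(w^2))
  t0 <- drop(Xc %*% w)
  p0 <- drop(crossprod(Xc, t0)) / sum(t0^2)
  wo <- p0 - drop(crossprod(w, p0)) * w; wo <- wo / sqrt(sum(wo^2))
  to <- drop(Xc %*% wo)
  Ef <- Xc - tcrossprod(to, drop(crossprod(Xc, to)) / sum(to^2))
  t_hand <- drop(Ef %*% w)
  s <- sign(sum(op$t * t_hand))
  expect_equal(op$t, s * t_hand, tolerance = 1e-8)
  # predictive score orthogonal to every orthogonal score
  expect_lt(abs(sum(op$t * op$t_ortho[, 1])), 1e-8 * sum(op$t^2))
  # variance bookkeeping
  expect_lte(op$variance_fraction_predictive +
               sum(op$variance_fraction_orthogonal), 1 + 1e-9)
})

test_that("OPLS-DA rejects non-binary responses and oversized n_ortho", {
  set.seed(6)
  X <- matrix(rnorm(18 * 4), 18, 4)
  Y3 <- encode_classes(rep(c("a", "b", "c"), each = 6))
  expect_error(fit_oplsda(X, Y3, 1), "binary")
  y <- rep(c(0, 1), each = 9)
  expect_error(fit_oplsda(X, y, n_ortho = 10), "n_ortho")
})

test_that("S-line covariance/correlation behave on planted structure", {
  set.seed(7)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 6, sd = 0.2), n, 6)
  X[, 3] <- X[, 3] + 2 * y            # strong planted signal
  X[, 5] <- 1                         # zero-variance bucket
  colnames(X) <- sprintf("%.2f", seq(6, 1))
  op <- fit_oplsda(X, y, n_ortho = 0)
  sl <- sline(op, X)
  expect_true(all(abs(sl$correlation) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(is.na(sl$correlation[5]))
  expect_equal(which.max(abs(sl$covariance)), 3L)
  # a bucket equal to the predictive score itself correlates at 1
  X2 <- cbind(X[, 1:4], t1 = op$t)
  colnames(X2) <- sprintf("%.2f", seq(5, 1))
  sl2 <- sline(op, X2)
  expect_equal(abs(sl2$correlation[5]), 1, tolerance = 1e-9)
})

test_that("planted year effect on the saturated methylene is recovered by the S-line", {
  ye <- zero_year_effects()
  ye$Coratina <- c(oleic = -0.03, linoleic = 0, linolenic = 0,
                   saturated = 0.03)
  d <- tiny_design(plants = 10, seed = 11, year_effect = ye,
                   plant_effect_sd = 0.005)
  co <- generate_cohort(d)
  keep <- co$metadata$cultivar == "Coratina"
  bt <- bucket_spectra(co$spectra[keep], bucket_scheme(),
                       co$metadata[keep, ])
  sc <- pareto_scale(normalize_total_sum(bt))
  y <- encode_classes(sc$metadata$harvest)
  op <- fit_oplsda(sc$values, y, n_ortho = 1)
  sl <- sline(op, sc$values)
  top3 <- sl$bucket[order(-abs(sl$covariance))][1:3]
  expect_true("1.26" %in% top3)
})
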