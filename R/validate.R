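# Cross-validated predictive ability (Q2) and response permutation testing.

make_folds <- function(n, folds, seed) {
  if (folds < 2) stop2("folds must be >= 2")
  if (folds > n) stop2("folds (%d) exceed sample count (%d)", folds, n)
  idx <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(folds), times = sizes))
}

#' Cross-validated Q2 of a PLS-DA or OPLS-DA model
#'
#' Q2 = 1 - PRESS/TSS with the prediction residual sum of squares
#' accumulated over held-out folds.  Fold assignment is a seeded shuffle
#' followed by contiguous blocks; column means (and, with
#' `scale = "pareto"`, Pareto divisors) are re-estimated inside each
#' training fold so no scaling information leaks from held-out samples.
#'
#' @param X samples x variables matrix.
#' @param Y response ([encode_classes()] result, matrix or vector).
#' @param k number of PLS components (ignored when `n_ortho` is given).
#' @param n_ortho if non-NULL, fit binary OPLS-DA with this many
#'   orthogonal components instead of PLS-DA.
#' @param folds number of folds (default 7); `folds = n` is leave-one-out.
#' @param seed integer seed for the fold shuffle.
#' @param scale `"none"` (X is already scaled) or `"pareto"` (re-estimate
#'   Pareto divisors per training fold).
#' @param ... further arguments (NIPALS `tol`, `max_iter`) passed to
#'   [fit_plsda()].
#' @return Q2 value (scalar).
#' @export
q2_crossval <- function(X, Y, k = 2, n_ortho = NULL, folds = 7, seed = 1,
                        scale = c("none", "pareto"), ...) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  Ymat <- response_matrix(Y)
  n <- nrow(X)
  fold_idx <- make_folds(n, folds, seed)
  labels <- apply(Ymat, 1L, which.max)
  press <- 0
  for (f in fold_idx) {
    train <- setdiff(seq_len(n), f)
    if (ncol(Ymat) > 1 && length(unique(labels[train])) < ncol(Ymat))
      stop2("fold empties a class in training; use fewer folds")
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[f, , drop = FALSE]
    if (scale == "pareto") {
      div <- sqrt(col_sds(Xtr))
      div[div == 0] <- 1
      mu <- colMeans(Xtr)
      Xtr <- sweep(sweep(Xtr, 2L, mu, `-`), 2L, div, `/`)
      Xte <- sweep(sweep(Xte, 2L, mu, `-`), 2L, div, `/`)
    }
    Ytr <- Ymat[train, , drop = FALSE]
    if (is.null(n_ortho)) {
      fit <- fit_plsda(Xtr, Ytr, k, ...)
      pred <- predict(fit, Xte)
    } else {
      fit <- fit_oplsda(Xtr, Ytr[, 1], n_ortho)
      pred <- cbind(predict(fit, Xte))
    }
    ytest <- if (is.null(n_ortho)) Ymat[f, , drop = FALSE]
             else Ymat[f, 1, drop = FALSE]
    press <- press + sum((ytest - pred)^2)
  }
  Yref <- if (is.null(n_ortho)) Ymat else Ymat[, 1, drop = FALSE]
  tss <- sum(sweep(Yref, 2L, colMeans(Yref), `-`)^2)
  1 - press / tss
}

#' Response permutation test
#'
#' Refits the model on `n_perm` row-permuted responses and compares the
#' cross-validated Q2 of each permutation with the observed one.  The
#' empirical p-value is `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams q2_crossval
#' @param n_perm number of permutations (default 400).
#' @param folds,seed cross-validation settings shared by the observed and
#'   the permuted fits.
#' @return A `permutation_result`: `observed_Q2`, `permuted_Q2` (length
#'   `n_perm`), `empirical_p`.
#' @export
permutation_test <- function(X, Y, k = 2, n_ortho = NULL, n_perm = 400,
                             folds = 7, seed = 1, scale = "none", ...) {
  if (n_perm < 1) stop2("n_perm must be >= 1")
  Ymat <- response_matrix(Y)
  observed <- q2_crossval(X, Ymat, k = k, n_ortho = n_ortho, folds = folds,
                          seed = seed, scale = scale, ...)
  perms <- with_seed(seed + 1L, {
    lapply(seq_len(n_perm), function(i) sample.int(nrow(Ymat)))
  })
  permuted <- vapply(perms, function(pm) {
    q2_crossval(X, Ymat[pm, , drop = FALSE], k = k, n_ortho = n_ortho,
                folds = folds, seed = seed, scale = scale, ...)
  }, numeric(1))
  structure(list(observed_Q2 = observed,
                 permuted_Q2 = permuted,
                 empirical_p = (1 + sum(permuted >= observed)) / (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: Q2 = %.3f, p = %.4g (%d permutations)>\n",
              x$observed_Q2, x$empirical_p, length(x$permuted_Q2)))
  invisible(x)
}
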