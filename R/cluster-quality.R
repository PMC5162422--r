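# Cluster separation and compactness in PCA score space: within/between
# scatter matrices, the J2 determinant-ratio criterion, and group
# Mahalanobis distances.

#' Within- and between-class scatter matrices
#'
#' Unnormalized scatter sums: `S_w` adds, over classes, the outer products
#' of member deviations from the class mean; `S_b` adds the size-weighted
#' outer products of class-mean deviations from the grand mean.  Their sum
#' is the total scatter about the grand mean.
#'
#' @param scores n x k score matrix.
#' @param labels per-sample class labels (>= 2 classes, each >= 2 members).
#' @return A `scatter_decomposition`: `S_w`, `S_b`, `class_means`,
#'   `grand_mean`, `class_sizes`.
#' @export
scatter_matrices <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop2("need >= 2 classes")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop2("singleton class: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  k <- ncol(scores)
  grand <- colMeans(scores)
  Sw <- matrix(0, k, k); Sb <- matrix(0, k, k)
  means <- matrix(NA_real_, length(classes), k,
                  dimnames = list(classes, colnames(scores)))
  for (cl in classes) {
    xc <- scores[labels == cl, , drop = FALSE]
    m <- colMeans(xc)
    means[cl, ] <- m
    dev <- sweep(xc, 2L, m, `-`)
    Sw <- Sw + crossprod(dev)
    Sb <- Sb + nrow(xc) * tcrossprod(m - grand)
  }
  structure(list(S_w = Sw, S_b = Sb, class_means = means,
                 grand_mean = grand,
                 class_sizes = as.integer(sizes[classes])),
            class = "scatter_decomposition")
}

#' J2 cluster-quality criterion
#'
#' The determinant ratio `|S_w + S_b| / |S_w|`.  It is at least 1, equals
#' 1 exactly when all class means coincide, grows with between-class
#' separation relative to within-class spread, and is invariant under any
#' invertible linear transformation of the score space.
#'
#' @param decomp a [scatter_matrices()] result.
#' @param ridge optional ridge (fraction of the mean diagonal of `S_w`)
#'   added before inversion when `S_w` is ill-conditioned; default 0.
#' @return J2 value (scalar, >= 1).
#' @export
j2_criterion <- function(decomp, ridge = 0) {
  stopifnot(inherits(decomp, "scatter_decomposition"))
  Sw <- decomp$S_w
  if (ridge > 0) Sw <- Sw + diag(ridge * mean(diag(Sw)), nrow(Sw))
  if (rcond_sym(Sw) < 1e-12)
    stop2("S_w is numerically singular; use fewer PCs or a ridge")
  # |Sw + Sb| / |Sw| computed via log-determinants for stability
  ld <- determinant(Sw + decomp$S_b, logarithm = TRUE)
  ldw <- determinant(Sw, logarithm = TRUE)
  exp(as.numeric(ld$modulus) - as.numeric(ldw$modulus))
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Mahalanobis distance between two class means
#'
#' `d = sqrt((m_a - m_b)' C^-1 (m_a - m_b))` with `C` the pooled
#' within-class covariance of the two classes (divisor `n_a + n_b - 2`).
#' The distance accounts for per-direction variances and is invariant to
#' any joint invertible linear rescaling of the score space.
#'
#' @param scores n x k score matrix.
#' @param labels per-sample class labels.
#' @param class_a,class_b class names to compare.
#' @param ridge ridge fraction of the mean diagonal applied if `C` is
#'   singular (default `1e-8`); a labelled error follows if `C` is still
#'   singular.
#' @return Distance (scalar >= 0).
#' @export
group_mahalanobis <- function(scores, labels, class_a, class_b,
                              ridge = 1e-8) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  for (cl in c(class_a, class_b))
    if (sum(labels == cl) < 2) stop2("class '%s' needs >= 2 members", cl)
  xa <- scores[labels == class_a, , drop = FALSE]
  xb <- scores[labels == class_b, , drop = FALSE]
  ma <- colMeans(xa); mb <- colMeans(xb)
  na <- nrow(xa); nb <- nrow(xb)
  pooled <- (crossprod(sweep(xa, 2L, ma, `-`)) +
             crossprod(sweep(xb, 2L, mb, `-`))) / (na + nb - 2)
  d2 <- tryCatch(mahalanobis_sq(ma - mb, pooled),
                 error = function(e) NULL)
  if (is.null(d2)) {
    pooled <- pooled + diag(ridge * mean(diag(pooled)), ncol(scores))
    d2 <- tryCatch(mahalanobis_sq(ma - mb, pooled),
                   error = function(e)
                     stop2("pooled covariance singular even after ridge"))
  }
  sqrt(max(d2, 0))
}

mahalanobis_sq <- function(delta, C) {
  R <- chol(C)
  z <- backsolve(R, delta, transpose = TRUE)
  sum(z^2)
}

#' Cluster-quality report over component-selection configurations
#'
#' For each configuration (a fixed component count, or a cumulative-
#' variance threshold resolved on the PCA), truncates the scores and
#' computes the partition J2, per-class one-vs-rest J2, and all pairwise
#' group Mahalanobis distances, together with the variance actually
#' covered.
#'
#' @param pca a [fit_pca()] model.
#' @param labels per-sample class labels aligned with the PCA scores.
#' @param configurations list of `list(rule = "fixed_k" | "cumvar",
#'   value = ...)`.
#' @param j2_ridge ridge forwarded to [j2_criterion()].
#' @return A `quality_report`: data frames `j2` (partition and per-class
#'   rows) and `mahalanobis` (one row per configuration x class pair).
#' @export
quality_report <- function(pca, labels, configurations, j2_ridge = 0) {
  stopifnot(inherits(pca, "pca_model"))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  j2_rows <- list(); mah_rows <- list()
  for (cfg in configurations) {
    k <- switch(cfg$rule,
                fixed_k = as.integer(cfg$value),
                cumvar = select_ncomp_by_cumvar(pca, cfg$value),
                stop2("unknown rule '%s'", cfg$rule))
    if (k > ncol(pca$scores))
      stop2("configuration needs %d components but the model has %d",
            k, ncol(pca$scores))
    covered <- sum(pca$explained_variance_all[seq_len(k)])
    sc <- pca$scores[, seq_len(k), drop = FALSE]
    tag <- sprintf("%s=%s", cfg$rule, format(cfg$value))
    dec <- scatter_matrices(sc, labels)
    j2_rows[[length(j2_rows) + 1L]] <-
      data.frame(configuration = tag, k = k, covered_variance = covered,
                 scope = "partition", class = NA_character_,
                 J2 = j2_criterion(dec, ridge = j2_ridge))
    for (cl in classes) {
      ovr <- ifelse(labels == cl, cl, "rest")
      dec1 <- scatter_matrices(sc, ovr)
      j2_rows[[length(j2_rows) + 1L]] <-
        data.frame(configuration = tag, k = k, covered_variance = covered,
                   scope = "one_vs_rest", class = cl,
                   J2 = j2_criterion(dec1, ridge = j2_ridge))
    }
    pairs <- utils::combn(classes, 2)
    for (j in seq_len(ncol(pairs))) {
      mah_rows[[length(mah_rows) + 1L]] <-
        data.frame(configuration = tag, k = k, covered_variance = covered,
                   class_a = pairs[1, j], class_b = pairs[2, j],
                   MAH = group_mahalanobis(sc, labels,
                                           pairs[1, j], pairs[2, j]))
    }
  }
  structure(list(j2 = do.call(rbind, j2_rows),
                 mahalanobis = do.call(rbind, mah_rows)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n$j2\n")
  print(x$j2)
  cat("$mahalanobis\n")
  print(x$mahalanobis)
  invisible(x)
}
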