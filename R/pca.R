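# Principal component analysis via singular-value decomposition.

#' Fit a PCA model
#'
#' Scores and loadings come from the singular-value decomposition of the
#' column-centered matrix; the explained-variance fraction of component i
#' is its squared singular value over the total sum of squares.  Each
#' loading vector is oriented so its largest-magnitude entry is positive.
#'
#' @param X numeric samples x variables matrix (typically Pareto-scaled
#'   bucket values).
#' @param k number of components, `k <= min(n - 1, p)` and at most the
#'   matrix rank; `NULL` (default) keeps every component up to the rank.
#' @return A `pca_model`: `column_means`, `loadings` (p x k), `scores`
#'   (n x k), `explained_variance_fraction`, `cumulative_R2X`, `sdev`.
#' @export
fit_pca <- function(X, k = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is.null(k) && (k < 1 || k > min(n - 1, p)))
    stop2("k = %d exceeds the admissible range 1..%d", k, min(n - 1, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, `-`)
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (is.null(k)) k <- rank
  if (k > rank)
    stop2("k = %d exceeds the matrix rank (%d)", k, rank)
  d <- sv$d[seq_len(k)]
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  ori <- orient_columns(loadings)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2L, d * ori$signs, `*`)
  expl <- sv$d^2 / tot
  rownames(loadings) <- colnames(X)
  rownames(scores) <- rownames(X)
  colnames(ori$mat) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(column_means = mu,
                 loadings = ori$mat,
                 scores = scores,
                 explained_variance_fraction = expl[seq_len(k)],
                 explained_variance_all = expl,
                 cumulative_R2X = cumsum(expl)[seq_len(k)],
                 sdev = d / sqrt(max(n - 1, 1)),
                 n = n, k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components, R2X(cum) = %.3f>\n",
              x$k, x$cumulative_R2X[x$k]))
  invisible(x)
}

#' Project new samples into a PCA score space
#'
#' @param object a `pca_model`.
#' @param newdata matrix with the model's variables.
#' @param ... unused.
#' @return Score matrix (rows x k).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2L, object$column_means, `-`) %*% object$loadings
}

#' Number of components reaching a cumulative-variance threshold
#'
#' @param model a `pca_model`.
#' @param threshold cumulative explained-variance fraction in (0, 1].
#' @return The smallest component count whose cumulative explained
#'   variance reaches the threshold (at least 1).  If the fitted model is
#'   truncated below the threshold the model's component count is returned
#'   with a warning.
#' @export
select_ncomp_by_cumvar <- function(model, threshold = 0.99) {
  stopifnot(inherits(model, "pca_model"))
  if (threshold <= 0) return(1L)
  if (threshold > 1) stop2("threshold must be <= 1")
  cum <- cumsum(model$explained_variance_all)
  hit <- which(cum >= threshold - 1e-12)
  if (!length(hit)) {
    warning("threshold not reached; returning all components",
            call. = FALSE)
    return(length(cum))
  }
  max(1L, min(hit))
}
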