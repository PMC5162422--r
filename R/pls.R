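# Partial least squares discriminant analysis (NIPALS) and its
# orthogonal-filtered variant.

#' Encode class labels as a dummy response
#'
#' @param labels per-sample class labels (>= 2 classes, each >= 2 members).
#' @return A `dummy_response`: `class_labels`, `indicator_matrix` (columns
#'   in sorted class-name order) and, for 2 classes, `binary` (the first
#'   indicator column as a single 0/1 vector).
#' @export
encode_classes <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop2("need >= 2 classes")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop2("singleton class: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  Y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  colnames(Y) <- classes
  structure(list(class_labels = labels,
                 indicator_matrix = Y,
                 binary = if (length(classes) == 2) Y[, 1] else NULL),
            class = "dummy_response")
}

response_matrix <- function(Y) {
  if (inherits(Y, "dummy_response")) Y$indicator_matrix
  else as.matrix(Y)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Extracts components maximizing the covariance between X scores and the
#' class-indicator response, deflating X and Y per component.  The start
#' vector of each NIPALS iteration is the response column of maximal
#' variance, making the fit deterministic.
#'
#' @param X samples x variables matrix (scaled data).
#' @param Y a [encode_classes()] response (or numeric matrix).
#' @param k number of components.
#' @param tol,max_iter NIPALS convergence tolerance and iteration cap.
#' @return A `plsda_model` with per-component `x_weights`, `x_loadings`,
#'   `x_scores`, `y_loadings`, the cumulative `R2X`, `R2Y`, and per-component
#'   explained fractions.
#' @export
fit_plsda <- function(X, Y, k, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  Ymat <- response_matrix(Y)
  n <- nrow(X)
  if (nrow(Ymat) != n) stop2("X and Y row counts differ")
  xmu <- colMeans(X); ymu <- colMeans(Ymat)
  E <- sweep(X, 2L, xmu, `-`)
  F <- sweep(Ymat, 2L, ymu, `-`)
  ssx <- sum(E^2); ssy <- sum(F^2)
  if (k > min(n - 1, ncol(X))) stop2("k = %d exceeds admissible range", k)

  W <- matrix(0, ncol(X), k); P <- matrix(0, ncol(X), k)
  Tm <- matrix(0, n, k); C <- matrix(0, ncol(Ymat), k)
  r2x <- r2y <- numeric(k)
  for (h in seq_len(k)) {
    u <- F[, which.max(apply(F, 2L, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stop2("degenerate component %d (rank exhausted)", h)
      w <- w / nw
      t <- drop(E %*% w)
      cc <- drop(crossprod(F, t)) / sum(t^2)
      u <- drop(F %*% cc) / sum(cc^2)
      if (sqrt(sum((t - t_old)^2)) <= tol * sqrt(sum(t^2))) break
      t_old <- t
      if (it == max_iter)
        stop2("NIPALS failed to converge in %d iterations", max_iter)
    }
    p <- drop(crossprod(E, t)) / sum(t^2)
    E <- E - tcrossprod(t, p)
    F <- F - tcrossprod(t, cc)
    W[, h] <- w; P[, h] <- p; Tm[, h] <- t; C[, h] <- cc
    r2x[h] <- sum(t^2) * sum(p^2) / ssx
    r2y[h] <- (ssy - sum(F^2)) / ssy
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(k)))
  structure(list(x_weights = W, x_loadings = P, x_scores = Tm,
                 y_loadings = C,
                 x_means = xmu, y_means = ymu,
                 R2X_per_component = r2x, R2X = sum(r2x),
                 R2Y_cum = r2y, R2Y = r2y[k],
                 classes = colnames(Ymat), k = k),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model: %d components, R2X = %.3f, R2Y = %.3f>\n",
              x$k, x$R2X, x$R2Y))
  invisible(x)
}

#' Predict responses from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix with the model's variables.
#' @param ... unused.
#' @return Predicted response matrix on the indicator scale.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  B <- object$x_weights %*%
    solve(crossprod(object$x_loadings, object$x_weights)) %*%
    t(object$y_loadings)
  Xc <- sweep(as.matrix(newdata), 2L, object$x_means, `-`)
  sweep(Xc %*% B, 2L, object$y_means, `+`)
}

#' Fit a binary OPLS-DA model
#'
#' Removes `n_ortho` components of structured variation orthogonal to the
#' class direction, then fits a single predictive component on the
#' filtered matrix, concentrating the between-class variation in one
#' score.  With `n_ortho = 0` the model coincides with 1-component PLS-DA.
#'
#' @param X samples x variables matrix (scaled data).
#' @param Y binary response: an [encode_classes()] result with 2 classes,
#'   or a 0/1 vector.
#' @param n_ortho number of orthogonal components (>= 0).
#' @return An `oplsda_model`: predictive `t`, `p`, `w`, `c`, orthogonal
#'   `t_ortho`, `p_ortho`, `w_ortho`, per-component variance fractions,
#'   `R2X`, `R2Y`.
#' @export
fit_oplsda <- function(X, Y, n_ortho) {
  X <- as.matrix(X)
  y <- if (inherits(Y, "dummy_response")) {
    if (is.null(Y$binary)) stop2("OPLS-DA requires a binary response")
    Y$binary
  } else if (is.matrix(Y) && ncol(Y) > 1) {
    stop2("OPLS-DA requires a binary response")
  } else as.numeric(Y)
  if (n_ortho < 0) stop2("n_ortho must be >= 0")
  n <- nrow(X)
  if (n_ortho + 1 > min(n - 1, ncol(X)))
    stop2("n_ortho = %d too large for the matrix rank", n_ortho)
  xmu <- colMeans(X); ymu <- mean(y)
  E <- sweep(X, 2L, xmu, `-`)
  f <- y - ymu
  ssx <- sum(E^2); ssy <- sum(f^2)

  w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
  To <- matrix(0, n, n_ortho)
  Po <- matrix(0, ncol(X), n_ortho); Wo <- matrix(0, ncol(X), n_ortho)
  frac_ortho <- numeric(n_ortho)
  for (j in seq_len(n_ortho)) {
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10)
      stop2("n_ortho = %d exceeds the Y-orthogonal structured rank", n_ortho)
    wo <- wo / nwo
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    To[, j] <- to; Po[, j] <- po; Wo[, j] <- wo
    frac_ortho[j] <- sum(to^2) * sum(po^2) / ssx
  }
  t <- drop(E %*% w)
  p <- drop(crossprod(E, t)) / sum(t^2)
  cc <- sum(f * t) / sum(t^2)
  frac_pred <- sum(t^2) * sum(p^2) / ssx
  resid <- f - t * cc
  structure(list(t = t, p = p, w = w, c = cc,
                 t_ortho = To, p_ortho = Po, w_ortho = Wo,
                 x_means = xmu, y_mean = ymu,
                 variance_fraction_predictive = frac_pred,
                 variance_fraction_orthogonal = frac_ortho,
                 R2X = frac_pred + sum(frac_ortho),
                 R2Y = 1 - sum(resid^2) / ssy,
                 n_ortho = n_ortho),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("<oplsda_model: 1 + %d + 0 components, R2X = %.3f, R2Y = %.3f>\n",
              x$n_ortho, x$R2X, x$R2Y))
  invisible(x)
}

#' Predict a binary response from an OPLS-DA model
#'
#' Orthogonal components are stripped from the new samples before the
#' predictive score is formed.
#'
#' @param object an `oplsda_model`.
#' @param newdata matrix with the model's variables.
#' @param ... unused.
#' @return Numeric vector of predicted responses on the 0/1 scale.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  E <- sweep(as.matrix(newdata), 2L, object$x_means, `-`)
  for (j in seq_len(object$n_ortho)) {
    to <- drop(E %*% object$w_ortho[, j])
    E <- E - tcrossprod(to, object$p_ortho[, j])
  }
  drop(E %*% object$w) * object$c + object$y_mean
}

#' S-line covariance/correlation loadings of an OPLS-DA model
#'
#' For every bucket, the covariance and the Pearson correlation between
#' the bucket column and the model's predictive score: covariance carries
#' the magnitude of the signal, correlation its reliability.
#'
#' @param model an `oplsda_model`.
#' @param X the training matrix the model was fitted on.
#' @return An `sline` data frame: `bucket`, `covariance`, `correlation`
#'   (NA for zero-variance buckets).
#' @export
sline <- function(model, X) {
  stopifnot(inherits(model, "oplsda_model"))
  X <- as.matrix(X)
  t <- model$t
  Xc <- sweep(X, 2L, colMeans(X), `-`)
  covv <- drop(crossprod(Xc, t - mean(t))) / (nrow(X) - 1)
  sds <- col_sds(X)
  corr <- ifelse(sds == 0, NA_real_, covv / (sds * stats::sd(t)))
  structure(data.frame(bucket = colnames(X) %||% seq_len(ncol(X)),
                       covariance = covv, correlation = corr),
            class = c("sline", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
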