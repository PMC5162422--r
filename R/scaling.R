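# Normalization, Pareto scaling and score-space outlier screening.

#' Total-sum normalization
#'
#' Rescales every sample's bucket row to a fixed row sum, removing global
#' concentration and acquisition-intensity differences between samples.
#'
#' @param table a raw or normalized `bucket_table` with positive row sums.
#' @param target row-sum constant (default 100).
#' @return The table with `state = "normalized"`.
#' @export
normalize_total_sum <- function(table, target = 100) {
  stopifnot(inherits(table, "bucket_table"))
  sums <- rowSums(table$values)
  bad <- which(sums <= 0)
  if (length(bad))
    stop2("nonpositive row sum for sample(s): %s",
          paste(table$metadata$sample_id[bad], collapse = ", "))
  table$values <- table$values * (target / sums)
  table$state <- "normalized"
  table$normalization_constant <- target
  table
}

#' Pareto scaling
#'
#' Mean-centers every bucket column and divides by the square root of its
#' sample standard deviation (denominator n - 1), damping the dominance of
#' intense signals while keeping the data in interpretable units.
#' Zero-variance columns map to all-zero with a warning.
#'
#' @param table a normalized `bucket_table` with at least 2 samples.
#' @return The table with `state = "scaled"` and `scaling_params` recording
#'   the per-bucket mean and standard deviation.
#' @export
pareto_scale <- function(table) {
  stopifnot(inherits(table, "bucket_table"))
  if (table$state != "normalized")
    stop2("pareto_scale expects a normalized table (state is '%s')",
          table$state)
  if (nrow(table$values) < 2) stop2("need >= 2 samples to scale")
  mu <- colMeans(table$values)
  sd <- col_sds(table$values)
  centered <- sweep(table$values, 2L, mu, `-`)
  zero <- sd == 0
  if (any(zero))
    warning(sprintf("%d zero-variance bucket(s) set to zero", sum(zero)),
            call. = FALSE)
  div <- sqrt(sd)
  div[zero] <- 1
  scaled <- sweep(centered, 2L, div, `/`)
  scaled[, zero] <- 0
  table$values <- scaled
  table$state <- "scaled"
  table$scaling_params <- data.frame(bucket = table$bucket_labels,
                                     mean = mu, sd = sd)
  table
}

#' Hotelling T2 outlier screening in PCA score space
#'
#' Computes Hotelling's T2 on the first `n_components` PCA scores and flags
#' samples above the F-distribution-based (1 - alpha) control limit.  A
#' single pass: flagged samples are reported, not removed iteratively.
#'
#' @param table a scaled `bucket_table`.
#' @param alpha significance level of the control limit (default 0.05).
#' @param n_components number of leading PCs (default 2, the conventional
#'   score-plot ellipse).
#' @return An `outlier_report`: list with `flagged_ids`, per-sample
#'   `statistic`, `threshold` and `n_components_used`.
#' @export
detect_outliers <- function(table, alpha = 0.05, n_components = 2) {
  stopifnot(inherits(table, "bucket_table"))
  if (table$state != "scaled")
    stop2("detect_outliers expects a scaled table")
  n <- nrow(table$values)
  if (n_components >= n)
    stop2("n_components (%d) must be < sample count (%d)", n_components, n)
  pca <- fit_pca(table$values, n_components)
  scores <- pca$scores
  lambda <- apply(scores, 2L, stats::var)
  t2 <- rowSums(sweep(scores^2, 2L, lambda, `/`))
  a <- n_components
  limit <- a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a)
  flagged <- table$metadata$sample_id[t2 > limit]
  structure(list(flagged_ids = flagged,
                 statistic = stats::setNames(t2, table$metadata$sample_id),
                 threshold = limit,
                 n_components_used = a,
                 alpha = alpha),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report: %d flagged of %d (T2 > %.3f, %d PCs, alpha = %g)>\n",
              length(x$flagged_ids), length(x$statistic), x$threshold,
              x$n_components_used, x$alpha))
  invisible(x)
}

#' Drop samples from a bucket table
#'
#' @param table a `bucket_table`.
#' @param sample_ids ids to remove.
#' @return The table without those samples.
#' @export
drop_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "bucket_table"))
  keep <- !table$metadata$sample_id %in% sample_ids
  table$values <- table$values[keep, , drop = FALSE]
  table$metadata <- table$metadata[keep, , drop = FALSE]
  rownames(table$metadata) <- NULL
  table
}
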