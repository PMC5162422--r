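# Plant-level paired analysis: pairwise Mahalanobis distances between the
# two harvest cohorts of a cultivar, split into the plant-plant set (one
# tree's two oils) and the plant-cultivar set (one tree's first-harvest
# oil against every second-harvest oil of the cultivar).

#' Pair samples of the same plant across the two harvests
#'
#' @param metadata data frame with `sample_id`, `harvest`, `plant_id` (and
#'   optionally `cultivar`).
#' @return A `paired_design`: data frame `pairs` (plant_id,
#'   sample_id_year1, sample_id_year2) and character vector `unmatched`
#'   of excluded sample ids.  Plants with no counterpart in the other
#'   harvest are excluded, mirroring the removal of trees that yielded
#'   oil in only one season.
#' @export
build_pairing <- function(metadata) {
  stopifnot(all(c("sample_id", "harvest", "plant_id") %in% names(metadata)))
  harvests <- sort(unique(metadata$harvest))
  if (length(harvests) != 2) stop2("pairing needs exactly 2 harvests")
  dup <- stats::aggregate(sample_id ~ plant_id + harvest, metadata, length)
  if (any(dup$sample_id > 1))
    stop2("plant(s) with two samples in one harvest: %s",
          paste(unique(dup$plant_id[dup$sample_id > 1]), collapse = ", "))
  m1 <- metadata[metadata$harvest == harvests[1], ]
  m2 <- metadata[metadata$harvest == harvests[2], ]
  common <- intersect(m1$plant_id, m2$plant_id)
  if (!length(common)) warning("no plant present in both harvests",
                               call. = FALSE)
  pairs <- data.frame(
    plant_id = common,
    sample_id_year1 = m1$sample_id[match(common, m1$plant_id)],
    sample_id_year2 = m2$sample_id[match(common, m2$plant_id)],
    stringsAsFactors = FALSE)
  matched_ids <- c(pairs$sample_id_year1, pairs$sample_id_year2)
  structure(list(pairs = pairs,
                 unmatched = setdiff(metadata$sample_id, matched_ids)),
            class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design: %d pairs, %d unmatched>\n",
              nrow(x$pairs), length(x$unmatched)))
  invisible(x)
}

#' Pairwise Mahalanobis distances between two score sets
#'
#' Entry (i, j) is `sqrt((x_i - y_j)' C^-1 (x_i - y_j))`: the square root
#' of the squared Mahalanobis distance between sample i of the first set
#' and sample j of the second.
#'
#' @param scores_year1,scores_year2 n1 x k and n2 x k score matrices.
#' @param covariance k x k covariance matrix (invertible).
#' @param ridge ridge fraction applied if `covariance` is singular.
#' @return n1 x n2 matrix of distances.
#' @export
pairwise_mahalanobis <- function(scores_year1, scores_year2, covariance,
                                 ridge = 1e-8) {
  X <- as.matrix(scores_year1); Y <- as.matrix(scores_year2)
  if (ncol(X) != ncol(Y) || ncol(X) != ncol(covariance))
    stop2("dimension mismatch between scores and covariance")
  R <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(R)) {
    covariance <- covariance +
      diag(ridge * mean(diag(covariance)), ncol(covariance))
    R <- tryCatch(chol(covariance), error = function(e)
      stop2("covariance singular even after ridge"))
  }
  # whiten both sets, then distances are Euclidean
  Xw <- t(backsolve(R, t(X), transpose = TRUE))
  Yw <- t(backsolve(R, t(Y), transpose = TRUE))
  d2 <- outer(rowSums(Xw^2), rowSums(Yw^2), `+`) - 2 * tcrossprod(Xw, Yw)
  out <- sqrt(pmax(d2, 0))
  dimnames(out) <- list(rownames(X), rownames(Y))
  out
}

#' Split a cultivar's distance matrix into plant-plant and plant-cultivar sets
#'
#' The plant-plant set holds, per tree, the distance between its two
#' harvest oils (the matched diagonal); the plant-cultivar set holds every
#' first-harvest sample's distances to all second-harvest samples of the
#' cultivar (the full matrix, own pair included unless
#' `exclude_own_pair`).
#'
#' @param matrix distance matrix from [pairwise_mahalanobis()] with rows
#'   named by year-1 sample ids and columns by year-2 sample ids.
#' @param pairing a [build_pairing()] result restricted to the cultivar.
#' @param cultivar cultivar name recorded on the output.
#' @param k_used,covariance_meta provenance recorded on the output.
#' @param exclude_own_pair drop each sample's own matched distance from
#'   the plant-cultivar set (default FALSE).
#' @return A `distance_sets`: numeric vectors `plant_plant` and
#'   `plant_cultivar` plus provenance fields.
#' @export
split_sets <- function(matrix, pairing, cultivar, k_used = NA_integer_,
                       covariance_meta = "", exclude_own_pair = FALSE) {
  stopifnot(inherits(pairing, "paired_design"))
  pr <- pairing$pairs
  if (!nrow(pr)) stop2("no pairs for cultivar '%s'", cultivar)
  if (!all(pr$sample_id_year1 %in% rownames(matrix)) ||
      !all(pr$sample_id_year2 %in% colnames(matrix)))
    stop2("matrix rows/columns do not cover the pairing for '%s'", cultivar)
  pp <- matrix[cbind(pr$sample_id_year1, pr$sample_id_year2)]
  names(pp) <- pr$plant_id
  pc <- as.vector(matrix[pr$sample_id_year1, pr$sample_id_year2,
                         drop = FALSE])
  if (exclude_own_pair) {
    m <- matrix[pr$sample_id_year1, pr$sample_id_year2, drop = FALSE]
    diag(m) <- NA
    pc <- as.vector(m)
    pc <- pc[!is.na(pc)]
  }
  structure(list(plant_plant = abs(pp), plant_cultivar = abs(pc),
                 cultivar = cultivar, k_used = k_used,
                 covariance_meta = covariance_meta),
            class = "distance_sets")
}

#' @export
print.distance_sets <- function(x, ...) {
  cat(sprintf("<distance_sets '%s': %d plant-plant, %d plant-cultivar>\n",
              x$cultivar, length(x$plant_plant), length(x$plant_cultivar)))
  invisible(x)
}

#' Summarize a distance set
#'
#' @param set nonempty numeric vector of distances.
#' @return A `distribution_summary` one-row data frame: minimum, median,
#'   mean, standard deviation (n - 1; NA for a singleton), maximum.
#' @export
summarize_distances <- function(set) {
  set <- as.numeric(set)
  if (!length(set)) stop2("empty distance set")
  data.frame(minimum = min(set),
             median = stats::median(set),
             mean = mean(set),
             standard_deviation = if (length(set) > 1) stats::sd(set)
                                  else NA_real_,
             maximum = max(set))
}

#' Gaussian kernel density of a distance set
#'
#' Density on a 512-point grid spanning `[min - 3h, max + 3h]`; the
#' default bandwidth is Silverman's rule of thumb.
#'
#' @param set numeric vector (length >= 2).
#' @param bandwidth kernel bandwidth; required when the set has zero
#'   variance.
#' @return A `kernel_density_curve`: `grid`, `density`, `bandwidth`.
#' @export
kernel_density <- function(set, bandwidth = NULL) {
  set <- as.numeric(set)
  if (length(set) < 2) stop2("need >= 2 distances")
  if (is.null(bandwidth)) {
    if (stats::sd(set) == 0)
      stop2("zero-variance set: supply an explicit bandwidth")
    bandwidth <- stats::bw.nrd0(set)
  }
  grid <- seq(min(set) - 3 * bandwidth, max(set) + 3 * bandwidth,
              length.out = 512)
  # exact kernel sum (no FFT binning): mean of Gaussians at the data
  dens <- rowMeans(vapply(set, function(x)
    stats::dnorm(grid, x, bandwidth), numeric(512)))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth),
            class = "kernel_density_curve")
}

#' Paired plant-level distance analysis of a bucket table
#'
#' End-to-end convenience: per cultivar, fits a PCA on the cultivar's
#' scaled two-harvest data, truncates scores by a cumulative-variance (or
#' fixed-k) rule, computes pairwise Mahalanobis distances between the
#' harvest cohorts under the pooled within-harvest covariance of the
#' retained scores, and splits them into plant-plant and plant-cultivar
#' sets.
#'
#' @param table a scaled `bucket_table` with complete metadata.
#' @param cumvar cumulative-variance threshold for score truncation.
#' @param fixed_k fixed component count overriding `cumvar` if non-NULL.
#' @param exclude_own_pair forwarded to [split_sets()].
#' @return Named list of `distance_sets`, one per cultivar.
#' @export
paired_analysis <- function(table, cumvar = 0.99, fixed_k = NULL,
                            exclude_own_pair = FALSE) {
  stopifnot(inherits(table, "bucket_table"))
  meta <- table$metadata
  harvests <- sort(unique(meta$harvest))
  out <- list()
  for (cv in sort(unique(meta$cultivar))) {
    sel <- meta$cultivar == cv
    sub <- table$values[sel, , drop = FALSE]
    msub <- meta[sel, , drop = FALSE]
    pca <- fit_pca(sub)
    kmax <- pca$k
    k <- if (is.null(fixed_k)) select_ncomp_by_cumvar(pca, cumvar)
         else fixed_k
    k <- min(k, kmax)
    sc <- pca$scores[, seq_len(k), drop = FALSE]
    rownames(sc) <- msub$sample_id
    y1 <- msub$harvest == harvests[1]
    s1 <- sc[y1, , drop = FALSE]
    s2 <- sc[!y1, , drop = FALSE]
    C <- (crossprod(sweep(s1, 2L, colMeans(s1), `-`)) +
          crossprod(sweep(s2, 2L, colMeans(s2), `-`))) /
         (nrow(s1) + nrow(s2) - 2)
    dm <- pairwise_mahalanobis(s1, s2, C)
    pairing <- build_pairing(msub)
    out[[cv]] <- split_sets(dm, pairing, cv, k_used = k,
                            covariance_meta = "pooled within-harvest covariance of retained PCA scores",
                            exclude_own_pair = exclude_own_pair)
  }
  out
}
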