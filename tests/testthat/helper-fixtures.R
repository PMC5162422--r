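# Fixtures shared across the suite: small cohort designs on a coarse ppm
# grid (fast to render, still finer than the bucket width) and a wrapper
# turning a bare matrix into a bucket_table.

tiny_design <- function(plants = 4, seed = 1,
                        plant_effect_sd = 0.010,
                        shift_jitter_sd = 0.0015,
                        noise_sd = 0.02,
                        year_effect = NULL,
                        n_points = 4096) {
  args <- list(plants_per_cultivar = plants, seed = seed,
               plant_effect_sd = plant_effect_sd,
               shift_jitter_sd = shift_jitter_sd,
               noise_sd = noise_sd,
               ppm_grid = seq(10.2, 0.3, length.out = n_points))
  if (!is.null(year_effect)) args$year_effect <- year_effect
  do.call(cohort_design, args)
}

zero_year_effects <- function(cultivars = c("Coratina", "CimaDiMola",
                                            "Ogliarola", "Peranzana")) {
  z <- setNames(numeric(4), c("oleic", "linoleic", "linolenic", "saturated"))
  setNames(rep(list(z), length(cultivars)), cultivars)
}

# wrap a numeric matrix as a bucket_table (via the CSV round trip, so only
# exported surface is used) for functions that demand table semantics
make_table <- function(mat, state = "scaled",
                       cultivar = rep("A", nrow(mat)),
                       harvest = rep("H1", nrow(mat)),
                       plant_id = sprintf("p%03d", seq_len(nrow(mat)))) {
  mat <- as.matrix(mat)
  labels <- sprintf("%.2f", seq(ncol(mat), 1))
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(mat))),
                     cultivar = cultivar, harvest = harvest,
                     plant_id = plant_id, stringsAsFactors = FALSE)
  df <- cbind(meta, as.data.frame(`colnames<-`(mat, labels),
                                  check.names = FALSE))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  tab <- read_bucket_table(path)
  unlink(path)
  tab$state <- state
  tab
}

# independent kernel-algorithm PLS oracle (eigen decomposition of
# X'YY'X per component, X and Y deflated as in the kernel formulation)
kernel_pls_oracle <- function(X, Y, k) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  Tm <- matrix(0, nrow(X), k)
  for (h in seq_len(k)) {
    M <- crossprod(X, Y) %*% crossprod(Y, X)
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    c_ <- drop(crossprod(Y, t)) / sum(t^2)
    X <- X - tcrossprod(t, p)
    Y <- Y - tcrossprod(t, c_)
    Tm[, h] <- t
  }
  Tm
}

# naive from-the-formula J2 and group Mahalanobis used as oracles
naive_j2 <- function(scores, labels) {
  scores <- as.matrix(scores)
  classes <- unique(labels)
  k <- ncol(scores)
  grand <- colMeans(scores)
  Sw <- matrix(0, k, k); Sb <- matrix(0, k, k)
  for (cl in classes) {
    xc <- scores[labels == cl, , drop = FALSE]
    m <- colMeans(xc)
    for (i in seq_len(nrow(xc)))
      Sw <- Sw + tcrossprod(xc[i, ] - m)
    Sb <- Sb + nrow(xc) * tcrossprod(m - grand)
  }
  det(Sw + Sb) / det(Sw)
}

naive_group_mahalanobis <- function(scores, labels, a, b) {
  xa <- as.matrix(scores)[labels == a, , drop = FALSE]
  xb <- as.matrix(scores)[labels == b, , drop = FALSE]
  ma <- colMeans(xa); mb <- colMeans(xb)
  Sa <- crossprod(sweep(xa, 2, ma)); Sb <- crossprod(sweep(xb, 2, mb))
  C <- (Sa + Sb) / (nrow(xa) + nrow(xb) - 2)
  sqrt(drop(t(ma - mb) %*% solve(C) %*% (ma - mb)))
}
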