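# Paired plant-level distance analysis.

meta_df <- function(plant, harvest) {
  data.frame(sample_id = paste0(plant, "_", harvest),
             cultivar = "A", harvest = harvest, plant_id = plant,
             stringsAsFactors = FALSE)
}

test_that("pairing matches plants across harvests and excludes the rest", {
  meta <- rbind(meta_df(c("p1", "p2", "p3", "p4"), "H1"),
                meta_df(c("p1", "p2", "p3"), "H2"))
  pd <- build_pairing(meta)
  expect_equal(nrow(pd$pairs), 3)
  expect_equal(pd$unmatched, "p4_H1")
  # symmetric in year order: same plant pairs either direction
  meta_rev <- meta
  meta_rev$harvest <- ifelse(meta$harvest == "H1", "H2", "H1")
  meta_rev$sample_id <- paste0(meta_rev$plant_id, "_", meta_rev$harvest)
  pd_rev <- build_pairing(meta_rev)
  expect_equal(sort(pd_rev$pairs$plant_id), sort(pd$pairs$plant_id))
  # duplicate sample within one harvest errors
  dup <- rbind(meta, meta_df("p1", "H1"))
  dup$sample_id[nrow(dup)] <- "p1_H1b"
  expect_error(build_pairing(dup), "two samples")
  # empty intersection warns
  empty <- rbind(meta_df(c("p1", "p2"), "H1"), meta_df(c("p3", "p4"), "H2"))
  expect_warning(build_pairing(empty), "no plant")
})

test_that("pairwise Mahalanobis matches hand cases", {
  # identical points
  expect_equal(pairwise_mahalanobis(rbind(c(1, 2)), rbind(c(1, 2)),
                                    diag(2))[1, 1], 0)
  # identity covariance: Pythagorean 3-4-5
  expect_equal(pairwise_mahalanobis(rbind(c(0, 0)), rbind(c(3, 4)),
                                    diag(2))[1, 1], 5, tolerance = 1e-12)
  # diag(4, 1): squared distance 4/4 = 1
  expect_equal(pairwise_mahalanobis(rbind(c(2, 0)), rbind(c(0, 0)),
                                    diag(c(4, 1)))[1, 1], 1,
               tolerance = 1e-12)
  # agrees with stats::mahalanobis on random data
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(15), 5, 3)
  S <- crossprod(matrix(rnorm(30), 10, 3)) / 9
  dm <- pairwise_mahalanobis(X, Y, S)
  for (j in 1:5)
    expect_equal(dm[, j]^2, stats::mahalanobis(X, Y[j, ], S),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("distances are invariant under joint congruent transformation", {
  set.seed(2)
  X <- matrix(rnorm(18), 6, 3); Y <- matrix(rnorm(12), 4, 3)
  S <- crossprod(matrix(rnorm(30), 10, 3)) / 9
  A <- matrix(rnorm(9), 3, 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
  d0 <- pairwise_mahalanobis(X, Y, S)
  d1 <- pairwise_mahalanobis(X %*% A, Y %*% A, t(A) %*% S %*% A)
  expect_equal(d1, d0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("set splitting keeps the matched diagonal inside the full set", {
  meta <- rbind(meta_df(c("p1", "p2", "p3"), "H1"),
                meta_df(c("p1", "p2", "p3"), "H2"))
  pd <- build_pairing(meta)
  m <- matrix(c(0.1, 1, 2,
                1.5, 0.2, 2.5,
                3, 3.5, 0.3), 3, 3, byrow = TRUE,
              dimnames = list(paste0(c("p1", "p2", "p3"), "_H1"),
                              paste0(c("p1", "p2", "p3"), "_H2")))
  ds <- split_sets(m, pd, "A")
  expect_length(ds$plant_plant, 3)
  expect_length(ds$plant_cultivar, 9)
  expect_equal(sort(unname(ds$plant_plant)), c(0.1, 0.2, 0.3))
  # multiset containment
  tab_pp <- table(ds$plant_plant)
  tab_pc <- table(ds$plant_cultivar)
  expect_true(all(names(tab_pp) %in% names(tab_pc)))
  expect_true(all(tab_pc[names(tab_pp)] >= tab_pp))
  # excluding the own pair removes exactly the diagonal
  ds2 <- split_sets(m, pd, "A", exclude_own_pair = TRUE)
  expect_length(ds2$plant_cultivar, 6)
  expect_false(any(c(0.1, 0.2, 0.3) %in% ds2$plant_cultivar))
})

test_that("distance summaries match hand values and handle singletons", {
  s <- summarize_distances(c(1, 2, 3))
  expect_equal(unlist(s),
               c(minimum = 1, median = 2, mean = 2,
                 standard_deviation = 1, maximum = 3))
  s1 <- summarize_distances(0.5)
  expect_true(is.na(s1$standard_deviation))
  expect_equal(s1$minimum, 0.5)
  expect_equal(s1$maximum, 0.5)
  expect_error(summarize_distances(numeric(0)), "empty")
})

test_that("kernel density curves are normalized, symmetric and closed-form", {
  set.seed(3)
  kd <- kernel_density(rexp(100))
  trap <- sum(diff(kd$grid) * (kd$density[-1] + kd$density[-512]) / 2)
  expect_equal(trap, 1, tolerance = 1e-3)
  # two points at +/-1: symmetric about 0
  kd2 <- kernel_density(c(-1, 1), bandwidth = 0.1)
  at <- function(x) approx(kd2$grid, kd2$density, x)$y
  xs <- seq(0.1, 0.9, by = 0.2)
  expect_equal(at(xs), at(-xs), tolerance = 1e-9)
  # repeated value with explicit bandwidth: a Gaussian of sd h
  kd3 <- kernel_density(rep(2, 5), bandwidth = 0.3)
  expect_equal(kd3$density, dnorm(kd3$grid, 2, 0.3), tolerance = 1e-9)
  expect_error(kernel_density(rep(2, 5)), "bandwidth")
  expect_error(kernel_density(1), ">= 2")
})

test_that("degenerate cohorts zero the plant-plant set only", {
  # identical paired samples, distinct plants: matched distances 0,
  # cross-plant distances positive
  set.seed(4)
  pts <- matrix(rnorm(8), 4, 2)
  s1 <- pts; s2 <- pts
  rownames(s1) <- paste0("p", 1:4, "_H1")
  rownames(s2) <- paste0("p", 1:4, "_H2")
  meta <- rbind(meta_df(paste0("p", 1:4), "H1"),
                meta_df(paste0("p", 1:4), "H2"))
  pd <- build_pairing(meta)
  dm <- pairwise_mahalanobis(s1, s2, diag(2))
  ds <- split_sets(dm, pd, "A")
  expect_true(all(ds$plant_plant == 0))
  expect_true(all(dm[upper.tri(dm)] > 0))
})

test_that("shared plant effects shrink the paired distances on synthetic cohorts", {
  hits <- 0
  for (s in 1:6) {
    d <- tiny_design(plants = 8, seed = 200 + s, plant_effect_sd = 0.02,
                     noise_sd = 0.01)
    tab <- pareto_scale(normalize_total_sum(bucket_cohort(generate_cohort(d))))
    pa <- paired_analysis(tab, cumvar = 0.99)
    mean_pp <- mean(unlist(lapply(pa, `[[`, "plant_plant")))
    mean_pc <- mean(unlist(lapply(pa, `[[`, "plant_cultivar")))
    if (mean_pp < mean_pc) hits <- hits + 1
  }
  expect_gte(hits, 5)
})
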