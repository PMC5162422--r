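# Synthetic cohort generator: line library, profile arithmetic, Lorentzian
# rendering and the paired two-harvest structure.

test_that("component library carries the expected acyl assignments", {
  lib <- build_component_library()
  has <- function(comp, shift)
    any(lib$component == comp & abs(lib$center_shift - shift) < 1e-9)
  expect_true(has("linoleic", 2.74))
  expect_true(has("linolenic", 2.78))
  expect_true(has("linolenic", 2.06))
  expect_true(has("linolenic", 0.90))
  expect_true(has("linolenic", 5.38))
  expect_true(has("saturated", 1.26))
  for (s in c(5.34, 2.02, 1.98, 1.30))
    expect_true(has("oleic", s))
  # invariants and bucketing-region containment
  expect_true(all(lib$halfwidth > 0))
  expect_true(all(lib$relative_area > 0))
  expect_true(all(lib$center_shift >= 0.50 & lib$center_shift <= 10.00))
  expect_false(any(lib$center_shift <= 7.6 & lib$center_shift >= 6.9))
})

test_that("sample_profile applies year and plant effects then renormalizes", {
  d <- tiny_design()
  base <- d$base_profile$Coratina
  # identity: no effects in the first harvest
  p1 <- sample_profile(d, "Coratina", "H13")
  expect_equal(p1, base, tolerance = 1e-12)

  # +0.05 linolenic year effect: exceeds the base by 0.05 before
  # renormalization (recovered by undoing the sum-1 rescale)
  ye <- zero_year_effects()
  ye$Coratina["linolenic"] <- 0.05
  d2 <- tiny_design(year_effect = ye)
  p2 <- sample_profile(d2, "Coratina", "H14")
  acyl <- c("oleic", "linoleic", "linolenic", "saturated")
  prenorm <- p2[acyl] * 1.05  # unnormalized sum was 1 + 0.05
  expect_equal(unname(prenorm["linolenic"] - base["linolenic"]), 0.05,
               tolerance = 1e-9, ignore_attr = TRUE)

  # clipping: a shift below zero clips at 0 and the result resums to 1
  pe <- c(oleic = 0, linoleic = 0, linolenic = -0.5, saturated = 0)
  p3 <- sample_profile(d, "Coratina", "H13", pe)
  expect_equal(unname(p3["linolenic"]), 0)
  expect_equal(sum(p3[acyl]), 1, tolerance = 1e-12)

  expect_error(sample_profile(d, "Nonesuch", "H13"), "cultivar")
  expect_error(sample_profile(d, "Coratina", "H99"), "harvest")
})

test_that("rendering is deterministic, linear and quadrature-accurate", {
  d <- tiny_design(noise_sd = 0, shift_jitter_sd = 0)
  lib <- build_component_library()
  prof <- d$base_profile$Coratina

  # determinism: same seed twice is bit-identical
  s1 <- render_spectrum(prof, lib, d, seed = 11)
  s2 <- render_spectrum(prof, lib, d, seed = 11)
  expect_identical(s1$intensity, s2$intensity)

  # null case: all fractions zero gives a flat zero spectrum
  zero <- prof * 0
  s0 <- render_spectrum(zero, lib, d, seed = 11)
  expect_true(all(s0$intensity == 0))

  # quadrature oracle: one isolated line integrates to
  # fraction * area * (analytic Lorentzian mass over the grid span)
  one <- lib[lib$component == "linoleic" &
               abs(lib$center_shift - 2.74) < 1e-9, ]
  pr <- c(oleic = 0, linoleic = 0.4, linolenic = 0, saturated = 0.6,
          glycerol_backbone = 0)
  lib1 <- one
  sp <- render_spectrum(pr, lib1, d, seed = 1)
  num <- -sum(diff(sp$ppm) * (sp$intensity[-1] +
                                sp$intensity[-length(sp$ppm)]) / 2)
  analytic <- stats::integrate(
    function(x) (one$halfwidth / pi) /
      ((x - one$center_shift)^2 + one$halfwidth^2),
    min(d$ppm_grid), max(d$ppm_grid), rel.tol = 1e-10)$value
  expect_equal(num, 0.4 * one$relative_area * analytic, tolerance = 0.01)

  # area linearity: doubling a fraction doubles the rendered intensity
  pr2 <- pr; pr2["linoleic"] <- 0.8
  sp2 <- render_spectrum(pr2, lib1, d, seed = 1)
  expect_equal(sp2$intensity, 2 * sp$intensity, tolerance = 1e-6)
})

test_that("generate_cohort yields the paired bookkeeping", {
  d <- tiny_design(plants = 10, seed = 5)
  co <- generate_cohort(d)
  expect_length(co$spectra, 4 * 10 * 2)
  counts <- table(co$metadata$plant_id)
  expect_true(all(counts == 2))
  expect_true(all(table(co$metadata$plant_id, co$metadata$harvest) == 1))
  # reproducible from the seed
  co2 <- generate_cohort(d)
  expect_identical(co$spectra[[7]]$intensity, co2$spectra[[7]]$intensity)
  expect_error(generate_cohort(cohort_design(plants_per_cultivar = 1)),
               "plants_per_cultivar")
})

test_that("all-zero effect cohort renders each plant's two spectra identical", {
  d <- tiny_design(plants = 2, plant_effect_sd = 0, shift_jitter_sd = 0,
                   noise_sd = 0, year_effect = zero_year_effects())
  co <- generate_cohort(d)
  for (pl in unique(co$metadata$plant_id)) {
    idx <- which(co$metadata$plant_id == pl)
    expect_equal(co$spectra[[idx[1]]]$intensity,
                 co$spectra[[idx[2]]]$intensity, tolerance = 1e-12)
  }
})

test_that("plant effects dominate within-plant variation when year effect is off", {
  d <- tiny_design(plants = 12, seed = 9, plant_effect_sd = 0.02,
                   noise_sd = 0.005, shift_jitter_sd = 0,
                   year_effect = zero_year_effects())
  co <- generate_cohort(d)
  bt <- bucket_cohort(co)
  # variance decomposition over plants: between-plant variance of the
  # bucket vectors must exceed the within-plant (across-year) variance
  meta <- bt$metadata
  plants <- unique(meta$plant_id)
  pm <- t(vapply(plants, function(p)
    colMeans(bt$values[meta$plant_id == p, , drop = FALSE]),
    numeric(ncol(bt$values))))
  within <- mean(vapply(plants, function(p) {
    rows <- bt$values[meta$plant_id == p, , drop = FALSE]
    sum((rows[1, ] - rows[2, ])^2) / 2
  }, numeric(1)))
  between <- sum(apply(pm, 2, var))
  expect_gt(between, within)
})
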