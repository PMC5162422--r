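# Synthetic single-tree olive-oil cohort generator.
#
# Spectra are sums of Lorentzian lines.  Each line belongs to one lipid
# component (acyl chains of the triacylglycerols, plus the glycerol
# backbone); line areas are proportional to proton counts so that the
# rendered spectrum of a fatty-acid profile carries the compositional
# signal the downstream chemometrics is meant to recover.

ACYL_COMPONENTS <- c("oleic", "linoleic", "linolenic", "saturated")
ALL_COMPONENTS  <- c(ACYL_COMPONENTS, "glycerol_backbone")

#' Lorentzian line library for olive-oil lipid signals
#'
#' Returns the fixed set of Lorentzian line templates used to render
#' synthetic olive-oil spectra.  Chemical shifts follow the conventional
#' assignments of the triacylglycerol acyl signals: olefinic protons at
#' 5.3-5.4 ppm, allylic protons near 2.0 ppm, bis-allylic protons at 2.74
#' (linoleic) and 2.78 ppm (linolenic), the long methylene envelope at
#' 1.26-1.30 ppm, and terminal methyls near 0.9 ppm; the glycerol backbone
#' contributes signals at 4.1-4.3 and 5.26 ppm.
#'
#' @return A data frame with one row per line and columns `component`,
#'   `center_shift` (ppm), `relative_area` (proton-count proportional) and
#'   `halfwidth` (ppm, half width at half maximum).
#' @examples
#' lib <- build_component_library()
#' subset(lib, component == "linoleic")
#' @export
build_component_library <- function() {
  lib <- rbind(
    # oleic (18:1): olefinic CH=CH, allylic CH2 x2, methylene envelope, CH3
    data.frame(component = "oleic",
               center_shift = c(5.34, 2.02, 1.98, 1.30, 0.88),
               relative_area = c(2, 2, 2, 20, 3)),
    # linoleic (18:2): olefinic, bis-allylic 2.74, allylic, envelope, CH3
    data.frame(component = "linoleic",
               center_shift = c(5.36, 2.74, 2.04, 1.31, 0.89),
               relative_area = c(4, 2, 4, 14, 3)),
    # linolenic (18:3): olefinic 5.38, bis-allylic 2.78, allylic 2.06,
    # envelope and the upfield-shifted CH3 at 0.90
    data.frame(component = "linolenic",
               center_shift = c(5.38, 2.78, 2.06, 1.32, 0.90),
               relative_area = c(6, 4, 4, 8, 3)),
    # saturated acyl: methylene envelope 1.26, alpha-CH2, CH3
    data.frame(component = "saturated",
               center_shift = c(1.26, 2.30, 1.60, 0.87),
               relative_area = c(24, 2, 2, 3)),
    # glycerol backbone of the TAG: sn-1/3 CH2 (two doublet-of-doublets
    # centroids) and the sn-2 CH
    data.frame(component = "glycerol_backbone",
               center_shift = c(4.28, 4.14, 5.26),
               relative_area = c(2, 2, 1))
  )
  lib$halfwidth <- 0.01
  validate_component_library(lib)
  lib
}

validate_component_library <- function(lib) {
  stopifnot(is.data.frame(lib),
            all(c("component", "center_shift", "relative_area",
                  "halfwidth") %in% names(lib)))
  if (any(lib$halfwidth <= 0)) stop2("library halfwidths must be > 0")
  if (any(lib$relative_area <= 0)) stop2("library areas must be > 0")
  if (any(lib$center_shift < 0.3 | lib$center_shift > 9.9))
    stop2("library chemical shifts must lie in [0.3, 9.9] ppm")
  invisible(lib)
}

#' Fatty-acid profile constructor
#'
#' A profile maps each lipid component to its molar proportion.  The four
#' acyl components must sum to one; the glycerol backbone proportion is
#' fixed by stoichiometry (one glycerol per three acyl chains) and is not
#' subject to year or plant effects.
#'
#' @param oleic,linoleic,linolenic,saturated acyl proportions, summing to 1.
#' @param glycerol_backbone backbone proportion; default 1/3.
#' @return Named numeric vector over the five components.
#' @export
fatty_acid_profile <- function(oleic, linoleic, linolenic, saturated,
                               glycerol_backbone = 1 / 3) {
  p <- c(oleic = oleic, linoleic = linoleic, linolenic = linolenic,
         saturated = saturated, glycerol_backbone = glycerol_backbone)
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  if (!all(ALL_COMPONENTS %in% names(p)))
    stop2("profile must name components: %s",
          paste(ALL_COMPONENTS, collapse = ", "))
  if (any(p < 0)) stop2("profile proportions must be >= 0")
  s <- sum(p[ACYL_COMPONENTS])
  if (abs(s - 1) > 1e-9)
    stop2("acyl proportions must sum to 1 (got %.12f)", s)
  invisible(p)
}

#' Cohort design for the synthetic study
#'
#' Describes a two-harvest, multi-cultivar cohort of single-tree oils:
#' per-cultivar base fatty-acid profiles, per-cultivar harvest-year effects
#' (added to the second harvest only), per-plant random effects shared
#' across the two harvests, chemical-shift jitter, and additive noise.
#'
#' The defaults emulate a four-cultivar study of roughly 450 trees per
#' harvest: an oleic-rich Coratina with the smallest year effect, a
#' PUFA-rich Peranzana with the second-smallest, and two saturated-leaning
#' cultivars (Cima di Mola, Ogliarola) with the largest year effects.
#'
#' @param cultivars character vector of cultivar names.
#' @param plants_per_cultivar trees per cultivar (>= 2); each tree yields
#'   one oil per harvest.
#' @param harvests length-2 vector of harvest labels.
#' @param base_profile named list of [fatty_acid_profile()] per cultivar.
#' @param year_effect named list, per cultivar, of additive shifts (in
#'   proportion units) applied to the acyl fractions of the second harvest.
#' @param plant_effect_sd standard deviation (proportion units) of the
#'   zero-mean Gaussian per-plant effect on each acyl fraction.
#' @param shift_jitter_sd standard deviation (ppm) of the per-line
#'   chemical-shift jitter.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param ppm_grid descending ppm vector the spectra are rendered on.
#' @param seed integer seed making the cohort reproducible.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(cultivars = c("Coratina", "CimaDiMola",
                                        "Ogliarola", "Peranzana"),
                          plants_per_cultivar = 112,
                          harvests = c("H13", "H14"),
                          base_profile = default_base_profiles(cultivars),
                          year_effect = default_year_effects(cultivars),
                          plant_effect_sd = 0.010,
                          shift_jitter_sd = 0.0015,
                          noise_sd = 0.02,
                          ppm_grid = seq(10.2, 0.3, length.out = 16384),
                          seed = 1L) {
  if (plants_per_cultivar < 2) stop2("plants_per_cultivar must be >= 2")
  if (length(harvests) != 2) stop2("exactly two harvests are supported")
  if (any(diff(ppm_grid) >= 0)) stop2("ppm_grid must be strictly decreasing")
  if (plant_effect_sd < 0 || shift_jitter_sd < 0 || noise_sd < 0)
    stop2("sd parameters must be >= 0")
  if (!setequal(names(base_profile), cultivars))
    stop2("base_profile must be named by cultivar")
  if (!setequal(names(year_effect), cultivars))
    stop2("year_effect must be named by cultivar")
  for (p in base_profile) validate_profile(p)
  structure(list(cultivars = cultivars,
                 plants_per_cultivar = as.integer(plants_per_cultivar),
                 harvests = harvests,
                 base_profile = base_profile[cultivars],
                 year_effect = year_effect[cultivars],
                 plant_effect_sd = plant_effect_sd,
                 shift_jitter_sd = shift_jitter_sd,
                 noise_sd = noise_sd,
                 ppm_grid = ppm_grid,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_base_profiles <- function(cultivars) {
  stylized <- list(
    Coratina   = fatty_acid_profile(0.78, 0.080, 0.010, 0.130),
    CimaDiMola = fatty_acid_profile(0.70, 0.095, 0.010, 0.195),
    Ogliarola  = fatty_acid_profile(0.72, 0.090, 0.015, 0.175),
    Peranzana  = fatty_acid_profile(0.67, 0.150, 0.025, 0.155)
  )
  out <- stylized[cultivars]
  missing <- cultivars[!cultivars %in% names(stylized)]
  for (m in missing) out[[m]] <- fatty_acid_profile(0.72, 0.10, 0.015, 0.165)
  names(out) <- cultivars
  out
}

#' @rdname cohort_design
#' @export
default_year_effects <- function(cultivars) {
  zero <- stats::setNames(numeric(length(ACYL_COMPONENTS)), ACYL_COMPONENTS)
  eff <- function(...) {
    v <- zero
    d <- c(...)
    v[names(d)] <- d
    v
  }
  stylized <- list(
    # second-harvest shifts in acyl-proportion units; magnitudes ordered
    # Coratina < Peranzana < Ogliarola ~ CimaDiMola
    Coratina   = eff(saturated = -0.004, oleic = +0.004),
    Peranzana  = eff(linolenic = -0.012, saturated = +0.010,
                     oleic = +0.002),
    Ogliarola  = eff(linolenic = -0.010, saturated = +0.022,
                     oleic = -0.012),
    CimaDiMola = eff(saturated = -0.025, oleic = +0.020,
                     linoleic = +0.005)
  )
  out <- stylized[cultivars]
  missing <- cultivars[!cultivars %in% names(stylized)]
  for (m in missing) out[[m]] <- eff(saturated = 0.02, oleic = -0.02)
  names(out) <- cultivars
  out
}

#' Realize the fatty-acid profile of one oil sample
#'
#' Adds the cultivar's harvest-year effect (second harvest only) and the
#' tree's random effect to the cultivar base profile, clips negative acyl
#' fractions at zero, and renormalizes the acyl fractions to sum to one.
#' The glycerol backbone proportion is passed through unchanged.
#'
#' @param design a [cohort_design()].
#' @param cultivar,harvest labels present in the design.
#' @param plant_effect named numeric vector of per-acyl-component shifts.
#' @return A fatty-acid profile vector.
#' @export
sample_profile <- function(design, cultivar, harvest,
                           plant_effect = stats::setNames(
                             numeric(length(ACYL_COMPONENTS)),
                             ACYL_COMPONENTS)) {
  if (!cultivar %in% design$cultivars)
    stop2("unknown cultivar '%s'", cultivar)
  if (!harvest %in% design$harvests)
    stop2("unknown harvest '%s'", harvest)
  base <- design$base_profile[[cultivar]]
  acyl <- base[ACYL_COMPONENTS]
  if (harvest == design$harvests[2])
    acyl <- acyl + design$year_effect[[cultivar]][ACYL_COMPONENTS]
  acyl <- acyl + plant_effect[ACYL_COMPONENTS]
  acyl <- pmax(acyl, 0)
  s <- sum(acyl)
  if (s <= 0) stop2("profile degenerated to all-zero acyl fractions")
  acyl <- acyl / s
  c(acyl, base["glycerol_backbone"])
}

#' Render one synthetic spectrum
#'
#' Sums, over all library lines, `fraction(component) * relative_area` times
#' a unit-area Lorentzian centred at the (jittered) chemical shift, then
#' adds white Gaussian noise.  Deterministic for a fixed seed.
#'
#' @param profile fatty-acid profile (named proportions).
#' @param library line library from [build_component_library()].
#' @param design a [cohort_design()] supplying the ppm grid, jitter and
#'   noise levels.
#' @param seed integer seed for jitter and noise.
#' @param sample_id identifier stored on the spectrum.
#' @return A `spectrum` object: list with `ppm`, `intensity`, `sample_id`.
#' @export
render_spectrum <- function(profile, library, design, seed,
                            sample_id = "synthetic") {
  validate_component_library(library)
  if (length(profile) == 0) stop2("empty profile")
  if (length(design$ppm_grid) == 0) stop2("empty ppm grid")
  frac <- profile[library$component]
  frac[is.na(frac)] <- 0
  with_seed(seed, {
    jitter <- stats::rnorm(nrow(library), 0, design$shift_jitter_sd)
    centers <- library$center_shift + jitter
    intensity <- numeric(length(design$ppm_grid))
    for (i in seq_len(nrow(library))) {
      a <- frac[[i]] * library$relative_area[i]
      if (a == 0) next
      hw <- library$halfwidth[i]
      # unit-area Lorentzian: (1/pi) * hw / ((x - c)^2 + hw^2)
      intensity <- intensity +
        a * (hw / pi) / ((design$ppm_grid - centers[i])^2 + hw^2)
    }
    if (design$noise_sd > 0)
      intensity <- intensity +
        stats::rnorm(length(intensity), 0, design$noise_sd)
    new_spectrum(design$ppm_grid, intensity, sample_id)
  })
}

new_spectrum <- function(ppm, intensity, sample_id) {
  if (length(ppm) != length(intensity))
    stop2("ppm and intensity lengths differ")
  if (any(!is.finite(intensity))) stop2("non-finite intensities")
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, %.2f..%.2f ppm>\n",
              x$sample_id, length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Generate a paired two-harvest cohort of synthetic spectra
#'
#' Draws one random effect per tree (shared across both harvests, encoding
#' the paired cohort structure), realizes the per-sample fatty-acid
#' profiles, and renders one spectrum per tree per harvest.
#'
#' @param design a [cohort_design()].
#' @return A `synthetic_cohort`: list with `spectra` (list of spectra),
#'   `metadata` (data frame: sample_id, cultivar, harvest, plant_id) and
#'   `truth` (realized profiles and plant effects).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n_plants <- design$plants_per_cultivar
  if (n_plants < 2) stop2("plants_per_cultivar must be >= 2")
  n_cult <- length(design$cultivars)
  n_spec <- n_cult * n_plants * 2L

  plant_fx <- with_seed(design$seed, {
    lapply(seq_len(n_cult * n_plants), function(i)
      stats::setNames(stats::rnorm(length(ACYL_COMPONENTS), 0,
                                   design$plant_effect_sd),
                      ACYL_COMPONENTS))
  })
  seeds <- derive_seeds(design$seed + 1L, n_spec)

  spectra <- vector("list", n_spec)
  meta <- data.frame(sample_id = character(n_spec),
                     cultivar = character(n_spec),
                     harvest = character(n_spec),
                     plant_id = character(n_spec),
                     stringsAsFactors = FALSE)
  profiles <- vector("list", n_spec)
  k <- 0L
  p <- 0L
  for (cv in design$cultivars) {
    for (pl in seq_len(n_plants)) {
      p <- p + 1L
      plant_id <- sprintf("%s_p%03d", cv, pl)
      for (h in design$harvests) {
        k <- k + 1L
        sid <- sprintf("%s_%s", plant_id, h)
        prof <- sample_profile(design, cv, h, plant_fx[[p]])
        spectra[[k]] <- render_spectrum(prof, build_component_library(),
                                        design, seeds[k], sid)
        meta[k, ] <- list(sid, cv, h, plant_id)
        profiles[[k]] <- prof
      }
    }
  }
  names(profiles) <- meta$sample_id
  structure(list(spectra = spectra,
                 metadata = meta,
                 truth = list(profiles = profiles,
                              plant_effects = plant_fx,
                              design = design)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d spectra, %d cultivars x %d plants x %d harvests>\n",
              length(x$spectra), length(unique(x$metadata$cultivar)),
              length(unique(x$metadata$plant_id)) /
                length(unique(x$metadata$cultivar)),
              length(unique(x$metadata$harvest))))
  invisible(x)
}
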