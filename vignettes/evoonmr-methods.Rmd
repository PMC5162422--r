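---
title: "Methods: NMR bucket chemometrics for paired single-tree olive-oil cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR bucket chemometrics for paired single-tree olive-oil cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoonmr)
```

`evoonmr` analyses frequency-domain ¹H NMR spectra of extra-virgin olive
oils pressed from individual trees of several cultivars in two
consecutive harvests. This vignette is the package's account of the
models it implements, the numerical conventions it fixes where several
are defensible, and what its synthetic data do and do not establish.

## The data model

An olive-oil ¹H NMR spectrum is dominated by triacylglycerol signals:
olefinic protons at 5.3–5.4 ppm, the glycerol backbone at 4.1–4.3 and
5.26 ppm, bis-allylic CH₂ at 2.74 (linoleic) and 2.78 ppm (linolenic),
allylic CH₂ near 2.0 ppm, the long methylene envelope at 1.2–1.3 ppm and
terminal methyls near 0.9 ppm. The relative areas of these signals carry
the acyl composition — the quantity that distinguishes cultivars and
drifts between harvest years.

The package consumes spectra already Fourier-transformed, phased and
referenced (two-column ppm/intensity text). FID-domain processing is out
of scope.

## The synthetic cohort generator

Because single-tree cohorts are not publicly deposited, the package
ships a generator that emulates the variance structure such a study
assumes, and every downstream stage is tested against it.

Each sample's acyl composition is

> profile = base(cultivar) + year_effect(cultivar) · 1{second harvest}
>           + plant_effect(tree),

clipped at zero and renormalized to sum 1. The plant effect is drawn
once per tree from a zero-mean Gaussian (sd `plant_effect_sd`, default
0.010 in proportion units) and reused in both harvests — this is the
paired structure the plant-level analysis exploits. Spectra are sums of
unit-area Lorentzian lines (half-width at half-maximum 0.01 ppm, well
below the 0.04 ppm bucket so bucketing is meaningful), with line areas
proportional to proton counts, per-line chemical-shift jitter (sd
0.0015 ppm, a fraction of a bucket, as expected after good referencing)
and additive white noise (sd 0.02 intensity units, small against peak
heights — oil spectra have high signal-to-noise). The default grid runs
10.2 to 0.3 ppm in 16,384 points, descending as NMR spectra are
conventionally plotted.

The default design is four cultivars × 112 trees × 2 harvests (≈ 900
spectra, the scale of a large regional study). The stylized base
profiles make the Coratina-like class oleic-rich, the Peranzana-like
class PUFA-rich, and the other two saturated-leaning; year-effect
magnitudes are ordered Coratina < Peranzana < Ogliarola ≈ Cima di Mola.
No quantitative per-cultivar fatty-acid fractions are established for
the emulated setting, so these defaults are stylized, user-overridable
values whose purpose is to plant a known ordering that recovery tests
can verify. Analyses at reduced scale (tests use 2–20 trees per
cultivar; the acceptance script uses 20) keep the same structure.

What the generator does *not* emulate: minor components (polyphenols,
sterols, squalene), baseline distortions, peak-shape asymmetry,
misreferencing larger than jitter, and correlated (coloured) noise.
Passing tests therefore show the pipeline recovers structure faithfully
under the stated variance model — not that it is robust to artifacts the
model omits, which is why the preprocessing keeps an outlier screen.

## Bucketing conventions

Buckets are anchored at the high edge (10.00 ppm) and step down in fixed
0.04 ppm widths; the trailing bucket is truncated at 0.50 ppm and kept;
a bucket is dropped only if *fully contained* in the exclusion interval
(7.60–6.90 ppm, the residual CHCl₃ and satellite region). This
convention yields 238 anchored buckets minus 17 excluded = 221
variables. Bucket values are trapezoidal integrals on the native grid
(robust to grid resolution, unlike midpoint sums), implemented as exact
differences of a cumulative trapezoid. Labels are the 2-decimal central
shifts of the possibly-truncated buckets.

## Pretreatment

Rows are scaled to a common sum (100 — arbitrary but fixed; only
relative values matter downstream), removing global concentration and
receiver-gain differences. Pareto scaling then centers each bucket and
divides by the square root of its standard deviation — the standard
compromise for NMR data between no scaling (intense signals dominate)
and unit-variance scaling (noise buckets inflated). The sample standard
deviation (denominator n − 1) is used everywhere in the package.

Outlier screening computes Hotelling's T² on the first 2 PCA scores
with the F-distribution control limit at 95% — the conventional
score-plot ellipse — in a single pass before the final model fit. The
screen is a stand-in for whatever rule an original instrument workflow
might apply; its parameters (`alpha`, `n_components`) are exposed.

## Latent-variable models

**PCA** is computed by SVD of the column-centered matrix; the explained
fraction of component *i* is σᵢ²/Σσ². Note that total-sum-normalized
tables have centered rank ≤ p − 1 (one linear constraint), so
`fit_pca()` defaults to keeping all components up to the numerical rank.
Every loading vector is oriented so its largest-magnitude entry is
positive, making signs reproducible.

**PLS-DA** encodes classes as a 0/1 indicator matrix (columns in sorted
class order) and runs NIPALS with deflation of both blocks. The start
vector is the response column of maximal variance, making the fit
deterministic; tolerance 1e-10 on the relative score change, at most
500 iterations, then a labelled error. Multi-class contrasts use PLS-DA
on the full indicator matrix.

**OPLS-DA** is restricted to binary contrasts (here, the two harvests
within a cultivar): the predictive weight is the normalized covariance
direction X'y; each orthogonal component removes the part of the
loading orthogonal to that weight; one predictive component is fitted
on the filtered matrix. With zero orthogonal components the model
coincides with 1-component PLS-DA (tested to 1e-6). Per-component
variance fractions are reported for the predictive and each orthogonal
component. The S-line reports, per bucket, covariance (magnitude) and
correlation (reliability) with the predictive score; zero-variance
buckets get `NA` correlations.

**Q²** is 1 − PRESS/TSS accumulated over held-out folds of a 7-fold
cross-validation (a seeded shuffle followed by contiguous blocks;
`folds = n` reproduces leave-one-out exactly). Column means — and Pareto
divisors when `scale = "pareto"` — are re-estimated inside each training
fold, so no scaling information leaks from held-out samples. PRESS and
TSS are pooled over response columns; a class-wise weighting would be an
alternative but is not implemented. The **permutation test** refits the
model on row-permuted responses and reports
p = (1 + #{permuted Q² ≥ observed}) / (n_perm + 1), so the smallest
attainable p with 100 permutations is 1/101. Permuted indicator
responses can leave the NIPALS iteration with nearly degenerate
covariance directions where convergence to 1e-10 is slow; since a rank
statistic needs no such precision, `q2_crossval()` and
`permutation_test()` forward `tol`/`max_iter` so drivers can relax them
for permutation sweeps.

An automatic model-order rule (stop when Q² decreases on adding a
component) is deliberately left to the user: the package reports
per-component statistics and the caller chooses.

## Cluster metrics in score space

Scatter matrices are *unnormalized* sums — S_w adds outer products of
member deviations from class means, S_b adds size-weighted outer
products of class-mean deviations from the grand mean; their sum is the
total scatter (tested identity). J₂ = |S_w + S_b|/|S_w| is computed via
log-determinants for stability; it is ≥ 1, equals 1 exactly when class
means coincide, and is invariant under any invertible linear map of the
scores (determinant factors cancel), so the choice of normalization is
immaterial. A fixed normalization was still chosen to keep oracle
comparisons exact. S_w conditioning below 1e-12 raises an error
suggesting fewer PCs or a ridge.

Group Mahalanobis distances use the two-class pooled within-class
covariance with divisor n_a + n_b − 2; singular covariances get one
ridge attempt (1e-8 × mean diagonal) before a labelled error, since
99%-variance component selections can approach rank deficiency. The
`quality_report()` computes both the partition J₂ and per-class
one-vs-rest J₂ for every configuration — whether a published per-class
J₂ means one-vs-rest or a full-partition value is genuinely ambiguous,
so both are exposed and tagged rather than resolved.

Component selection supports both conventions in the field: a fixed
number of PCs (2, 3, 4 …) and the smallest number reaching a cumulative
explained-variance threshold (default 0.99); reports carry the variance
actually covered, because distances computed on unequal covered
variance are not comparable.

## Paired plant-level analysis

Trees present in both harvests are paired; all other samples are listed
as excluded. For each cultivar, a PCA of that cultivar's two-harvest
data is truncated by the 99% rule (configurable to fixed k), and
pairwise Mahalanobis distances between the harvest cohorts are computed
under the pooled within-harvest covariance of the retained scores —
the covariance convention is recorded in `covariance_meta` on every
result, since class-specific or whitened-score alternatives exist. The
distances are square roots of squared Mahalanobis distances; an absolute
value is applied defensively although the square root is already
nonnegative. The *plant–cultivar* set includes each sample's own matched
pair (an `exclude_own_pair` switch exists, default off).

With shared plant effects, matched pairs differ only by year effect,
jitter and noise, while cross-plant distances add the plant-effect
difference — so the plant–plant mean falls below the plant–cultivar
mean; with plant effects off the two sets share a generating
distribution and their means coincide up to the diagonal's inclusion.
Both behaviors are asserted in the test suite over replicate seeds.

Kernel densities use exact Gaussian kernel sums on a 512-point grid
spanning the data ± 3 bandwidths (no FFT binning, so closed-form checks
hold to 1e-9), with Silverman's rule-of-thumb bandwidth by default;
zero-variance sets require an explicit bandwidth.

## Degenerate inputs and tie-breaks

* Zero-variance buckets: Pareto scaling maps them to zero with a
  warning; S-lines report `NA` correlation.
* Nonpositive row sums abort normalization with the offending sample id.
* Singleton classes are rejected by the encoders and scatter builders.
* Cross-validation folds that would empty a class in training raise a
  labelled error rather than silently skewing PRESS.
* All sign indeterminacies (SVD, NIPALS) are fixed by the
  largest-entry-positive convention; score comparisons in tests are
  up-to-sign where the convention does not apply.

## Problem sizes

The bundled analysis drivers use the full default design (896 spectra);
the test suite and the acceptance script use cohorts of 2–20 trees per
cultivar on a 4,096-point grid where the full grid adds nothing to the
property under test, with replicate-seed counts of 6–20 for
distributional claims. These sizes were chosen so each claim is
decidable with comfortable margins at interactive runtimes.

## Known limitations

* No baseline correction, peak alignment/warping or
  probabilistic-quotient normalization — spectra are assumed referenced
  and flat-baselined.
* OPLS-DA is binary-only; multi-class orthogonal filtering (O2PLS-style)
  is out of scope.
* The J₂ and distance metrics assume scores from a *single* PCA; values
  from differently-truncated or differently-scaled models are not
  comparable, and the reports tag covered variance to make this visible.
* Proprietary software reproduces none of these numerics bit-for-bit;
  agreement is structural (same formulas, same conventions), not
  numerical emulation of any particular product.
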