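# Bucket segmentation of frequency-domain spectra.
#
# The analysis grid is anchored at the high-ppm edge and steps down in
# fixed-width buckets; a trailing partial bucket truncated at the low edge
# is kept, and buckets fully contained in an exclusion interval (residual
# solvent region) are dropped.  With the conventional olive-oil scheme
# (10.00-0.50 ppm, 0.04 ppm width, 7.6-6.9 ppm excluded) this yields 221
# bucket variables.

#' Bucket scheme
#'
#' @param region_high,region_low bucketing region bounds (ppm),
#'   `region_high > region_low`.
#' @param width bucket width (ppm).
#' @param exclusions list of `c(high, low)` ppm intervals; buckets fully
#'   contained in an exclusion are dropped.
#' @return A `bucket_scheme` list.
#' @export
bucket_scheme <- function(region_high = 10.00, region_low = 0.50,
                          width = 0.04,
                          exclusions = list(c(7.6, 6.9))) {
  if (region_high <= region_low) stop2("region_high must exceed region_low")
  if (width <= 0) stop2("width must be > 0")
  if (width >= region_high - region_low)
    stop2("width must be smaller than the region span")
  for (ex in exclusions) {
    if (length(ex) != 2 || ex[1] <= ex[2])
      stop2("each exclusion must be c(high, low) with high > low")
    if (ex[1] > region_high + 1e-12 || ex[2] < region_low - 1e-12)
      stop2("exclusions must lie inside the bucketing region")
  }
  structure(list(region_high = region_high, region_low = region_low,
                 width = width, exclusions = exclusions),
            class = "bucket_scheme")
}

#' Lay out the bucket grid of a scheme
#'
#' Buckets are anchored at `region_high` and step down by `width`; the
#' trailing bucket is truncated at `region_low` and kept.  A bucket is
#' dropped only when it lies fully inside an exclusion interval.  Centers
#' are the midpoints of the (possibly truncated) buckets.
#'
#' @param scheme a [bucket_scheme()].
#' @return Data frame with columns `high`, `low`, `center` in descending
#'   ppm order.
#' @export
make_bucket_grid <- function(scheme) {
  stopifnot(inherits(scheme, "bucket_scheme"))
  span <- scheme$region_high - scheme$region_low
  n_full <- floor(span / scheme$width + 1e-9)
  highs <- scheme$region_high - scheme$width * (seq_len(n_full) - 1L)
  lows <- highs - scheme$width
  # trailing partial bucket truncated at region_low
  if (scheme$region_low < min(lows) - 1e-9) {
    highs <- c(highs, min(lows))
    lows <- c(lows, scheme$region_low)
  }
  lows[length(lows)] <- scheme$region_low
  keep <- rep(TRUE, length(highs))
  tol <- 1e-9
  for (ex in scheme$exclusions) {
    contained <- highs <= ex[1] + tol & lows >= ex[2] - tol
    keep <- keep & !contained
  }
  data.frame(high = highs[keep], low = lows[keep],
             center = (highs[keep] + lows[keep]) / 2)
}

#' Integrate a spectrum over a bucket grid
#'
#' Each bucket value is the trapezoidal integral of intensity over the
#' bucket's ppm span on the native grid, with linear interpolation at the
#' bucket boundaries.
#'
#' @param spectrum a `spectrum` (descending ppm).
#' @param scheme a [bucket_scheme()].
#' @return Numeric vector aligned with [make_bucket_grid()] order.
#' @export
integrate_buckets <- function(spectrum, scheme) {
  stopifnot(inherits(spectrum, "spectrum"))
  grid <- make_bucket_grid(scheme)
  ppm <- rev(spectrum$ppm)            # ascending for integration
  intens <- rev(spectrum$intensity)
  lo <- min(ppm); hi <- max(ppm)
  if (lo > scheme$region_low + 1e-9 || hi < scheme$region_high - 1e-9)
    stop2("spectrum covers %.3f..%.3f ppm but the scheme needs %.3f..%.3f",
          lo, hi, scheme$region_low, scheme$region_high)
  # cumulative trapezoid over the native grid; the integral to an
  # arbitrary boundary adds the partial trapezoid of its segment, so each
  # bucket is an exact difference of two boundary integrals
  cum <- c(0, cumsum(diff(ppm) * (intens[-1] + intens[-length(intens)]) / 2))
  integral_to <- function(t) {
    j <- findInterval(t, ppm, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), length(ppm) - 1L)
    yt <- intens[j] + (intens[j + 1L] - intens[j]) *
      (t - ppm[j]) / (ppm[j + 1L] - ppm[j])
    cum[j] + (t - ppm[j]) * (intens[j] + yt) / 2
  }
  integral_to(grid$high) - integral_to(grid$low)
}

#' Assemble a bucket table from spectra
#'
#' @param spectra list of `spectrum` objects.
#' @param scheme a [bucket_scheme()].
#' @param metadata data frame with one row per spectrum carrying
#'   `sample_id`, `cultivar`, `harvest`, `plant_id` (matched by order).
#' @return A `bucket_table`: samples x buckets matrix of raw integrals plus
#'   metadata, with bucket labels at the 2-decimal central shifts.
#' @export
bucket_spectra <- function(spectra, scheme, metadata = NULL) {
  grid <- make_bucket_grid(scheme)
  values <- t(vapply(spectra, integrate_buckets, numeric(nrow(grid)),
                     scheme = scheme))
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = ids,
                           cultivar = NA_character_,
                           harvest = NA_character_,
                           plant_id = NA_character_,
                           stringsAsFactors = FALSE)
  }
  new_bucket_table(values, sprintf("%.2f", grid$center), metadata,
                   state = "raw", scheme = scheme)
}

#' Bucket a synthetic cohort
#'
#' Convenience wrapper running [bucket_spectra()] on a
#' [generate_cohort()] result.
#' @param cohort a `synthetic_cohort`.
#' @param scheme a [bucket_scheme()].
#' @return A `bucket_table`.
#' @export
bucket_cohort <- function(cohort, scheme = bucket_scheme()) {
  bucket_spectra(cohort$spectra, scheme, cohort$metadata)
}

new_bucket_table <- function(values, labels, metadata, state = "raw",
                             scheme = NULL, normalization_constant = NA_real_,
                             scaling_params = NULL) {
  values <- as.matrix(values)
  if (length(labels) != ncol(values))
    stop2("label count (%d) != column count (%d)", length(labels),
          ncol(values))
  num <- as.numeric(labels)
  if (any(diff(num) >= 0)) stop2("bucket labels must be strictly decreasing")
  if (anyDuplicated(metadata$sample_id))
    stop2("duplicate sample_id in metadata")
  if (nrow(metadata) != nrow(values))
    stop2("metadata rows != sample rows")
  colnames(values) <- labels
  rownames(values) <- metadata$sample_id
  structure(list(values = values, bucket_labels = labels,
                 metadata = metadata, state = state, scheme = scheme,
                 normalization_constant = normalization_constant,
                 scaling_params = scaling_params),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table: %d samples x %d buckets, state = %s>\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.bucket_table <- function(x) dim(x$values)
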