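# End-to-end pipeline: simulate or read spectra, bucket, normalize,
# outlier-screen, scale, model, and report cluster and paired-distance
# metrics, writing every artifact with a manifest.

#' Pipeline configuration
#'
#' Exactly one of `input_paths` (two-column spectrum files plus a metadata
#' CSV) or `design` (a [cohort_design()] to simulate) must be given.
#'
#' @param design a [cohort_design()], or NULL.
#' @param input_paths character vector of spectrum file paths, or NULL.
#' @param metadata_path CSV with sample_id, cultivar, harvest, plant_id
#'   (required with `input_paths`).
#' @param scheme a [bucket_scheme()].
#' @param normalization_constant row-sum target.
#' @param outlier_alpha,outlier_ncomp Hotelling T2 screen settings; set
#'   `outlier_alpha = NULL` to skip screening.
#' @param models character subset of `c("pca", "plsda", "oplsda")`.
#' @param plsda_ncomp,oplsda_northo model orders.
#' @param cv_folds,n_permutations validation settings; `n_permutations = 0`
#'   skips the permutation test.
#' @param quality_configurations configurations for [quality_report()].
#' @param paired_cumvar cumulative-variance rule of [paired_analysis()].
#' @param seed integer seed (default 0).
#' @param out_dir output directory, or NULL to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, input_paths = NULL,
                            metadata_path = NULL,
                            scheme = bucket_scheme(),
                            normalization_constant = 100,
                            outlier_alpha = 0.05, outlier_ncomp = 2,
                            models = c("pca", "plsda", "oplsda"),
                            plsda_ncomp = 3, oplsda_northo = 2,
                            cv_folds = 7, n_permutations = 0,
                            quality_configurations = list(
                              list(rule = "fixed_k", value = 2),
                              list(rule = "fixed_k", value = 3),
                              list(rule = "cumvar", value = 0.99)),
                            paired_cumvar = 0.99,
                            seed = 0L, out_dir = NULL) {
  if (is.null(design) == is.null(input_paths))
    stop2("exactly one of design / input_paths must be given")
  if (!is.null(input_paths) && is.null(metadata_path))
    stop2("input_paths requires metadata_path")
  structure(as.list(environment()), class = "pipeline_config")
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read, bucketing, total-sum normalization, Hotelling
#' T2 outlier screening, Pareto scaling, PCA, optional PLS-DA/OPLS-DA with
#' cross-validation and permutation testing, the cluster-quality report,
#' and the paired plant-level distance analysis.  All tabular artifacts
#' are written as CSV and summaries as JSON under `out_dir` (when set),
#' with a manifest recording the seed and configuration.
#'
#' @param config a [pipeline_config()].
#' @param verbose log one line per stage (default TRUE).
#' @return A report bundle (list) with the bucket tables, models, reports
#'   and the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("[%s] %s", name, conditionMessage(e)))
  }

  if (!is.null(config$design)) {
    cohort <- stage("simulate", generate_cohort(config$design))
    spectra <- cohort$spectra
    metadata <- cohort$metadata
  } else {
    spectra <- stage("read", lapply(config$input_paths, read_spectrum))
    metadata <- stage("read", utils::read.csv(config$metadata_path,
                                              colClasses = "character"))
    cohort <- NULL
  }
  log_stage(verbose, "input: %d spectra x %d points", length(spectra),
            length(spectra[[1]]$ppm))

  raw <- stage("bucket", bucket_spectra(spectra, config$scheme, metadata))
  log_stage(verbose, "bucket: %d x %d (state %s)", nrow(raw$values),
            ncol(raw$values), raw$state)

  norm <- stage("normalize",
                normalize_total_sum(raw, config$normalization_constant))

  outliers <- NULL
  if (!is.null(config$outlier_alpha)) {
    scaled0 <- stage("scale", pareto_scale(norm))
    outliers <- stage("outliers",
                      detect_outliers(scaled0, config$outlier_alpha,
                                      config$outlier_ncomp))
    log_stage(verbose, "outliers: %d of %d flagged",
              length(outliers$flagged_ids), nrow(norm$values))
    if (length(outliers$flagged_ids))
      norm <- drop_samples(norm, outliers$flagged_ids)
  }
  scaled <- stage("scale", pareto_scale(norm))
  log_stage(verbose, "scale: %d x %d (state %s)", nrow(scaled$values),
            ncol(scaled$values), scaled$state)

  X <- scaled$values
  meta <- scaled$metadata
  models <- list()
  if ("pca" %in% config$models) {
    models$pca <- stage("pca", fit_pca(X))
    log_stage(verbose, "pca: %d components, R2X(cum 2) = %.3f",
              models$pca$k,
              models$pca$cumulative_R2X[2])
  }
  if ("plsda" %in% config$models) {
    Y <- stage("plsda", encode_classes(meta$cultivar))
    fit <- stage("plsda", fit_plsda(X, Y, config$plsda_ncomp))
    fit$Q2 <- stage("plsda", q2_crossval(X, Y, k = config$plsda_ncomp,
                                         folds = config$cv_folds,
                                         seed = config$seed))
    if (config$n_permutations > 0)
      fit$permutation <- stage("plsda",
        permutation_test(X, Y, k = config$plsda_ncomp,
                         n_perm = config$n_permutations,
                         folds = config$cv_folds, seed = config$seed))
    models$plsda <- fit
    log_stage(verbose, "plsda: R2Y = %.3f, Q2 = %.3f", fit$R2Y, fit$Q2)
  }
  if ("oplsda" %in% config$models) {
    # per-cultivar binary two-harvest contrasts
    models$oplsda <- list()
    for (cv in sort(unique(meta$cultivar))) {
      sel <- meta$cultivar == cv
      Ycv <- encode_classes(meta$harvest[sel])
      fit <- stage("oplsda",
                   fit_oplsda(X[sel, , drop = FALSE], Ycv,
                              config$oplsda_northo))
      fit$Q2 <- stage("oplsda",
                      q2_crossval(X[sel, , drop = FALSE], Ycv,
                                  n_ortho = config$oplsda_northo,
                                  folds = config$cv_folds,
                                  seed = config$seed))
      fit$sline <- sline(fit, X[sel, , drop = FALSE])
      models$oplsda[[cv]] <- fit
      log_stage(verbose, "oplsda[%s]: R2Y = %.3f, Q2 = %.3f", cv,
                fit$R2Y, fit$Q2)
    }
  }

  quality <- NULL
  if (!is.null(models$pca) && length(config$quality_configurations)) {
    lab <- paste(meta$cultivar, meta$harvest, sep = ":")
    quality <- stage("quality",
                     quality_report(models$pca, lab,
                                    config$quality_configurations))
  }

  paired <- stage("paired",
                  paired_analysis(scaled, cumvar = config$paired_cumvar))
  log_stage(verbose, "paired: %d cultivars analysed", length(paired))

  manifest <- list(
    package_version = as.character(utils::packageVersion("evoonmr")),
    seed = config$seed,
    n_samples = nrow(X),
    n_buckets = ncol(X),
    bucket_labels = scaled$bucket_labels,
    normalization_constant = config$normalization_constant,
    config_hash = digest_config(config),
    flagged_outliers = if (is.null(outliers)) character(0)
                       else outliers$flagged_ids)

  bundle <- list(bucket_table_raw = raw, bucket_table_scaled = scaled,
                 outliers = outliers, models = models, quality = quality,
                 paired = paired, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

digest_config <- function(config) {
  keep <- config[setdiff(names(config), c("out_dir"))]
  txt <- paste(utils::capture.output(utils::str(keep, digits.d = 12)),
               collapse = "\n")
  # small stable checksum without external digest dependencies
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)) %% 1e9
}

write_bundle <- function(bundle, out_dir) {
  write_bucket_table(bundle$bucket_table_scaled,
                     file.path(out_dir, "bucket_table_scaled.csv"))
  if (!is.null(bundle$models$pca)) {
    utils::write.csv(bundle$models$pca$scores,
                     file.path(out_dir, "pca_scores.csv"))
    utils::write.csv(bundle$models$pca$loadings,
                     file.path(out_dir, "pca_loadings.csv"))
  }
  if (!is.null(bundle$quality)) {
    utils::write.csv(bundle$quality$j2,
                     file.path(out_dir, "quality_j2.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$quality$mahalanobis,
                     file.path(out_dir, "quality_mahalanobis.csv"),
                     row.names = FALSE)
  }
  if (length(bundle$paired)) {
    summ <- do.call(rbind, lapply(bundle$paired, function(ds)
      cbind(cultivar = ds$cultivar,
            set = c("plant_plant", "plant_cultivar"),
            rbind(summarize_distances(ds$plant_plant),
                  summarize_distances(ds$plant_cultivar)))))
    utils::write.csv(summ, file.path(out_dir, "paired_summaries.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
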