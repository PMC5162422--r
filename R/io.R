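# Plain-text I/O: two-column spectrum files and the bucket-table CSV
# dialect (metadata columns, then bucket columns headed by 2-decimal
# central shifts), with a sidecar JSON recording scheme and state.

#' Read a spectrum from a two-column text file
#'
#' The file holds one `ppm intensity` pair per line (whitespace or tab
#' separated); ascending input is re-sorted to descending ppm.  The sample
#' id is the file name stem.
#'
#' @param path file path.
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop2("%s: need >= 2 data points", path)
  parts <- strsplit(trimws(lines), "[ \t,]+")
  bad <- which(vapply(parts, function(p)
    length(p) != 2 || anyNA(suppressWarnings(as.numeric(p))), logical(1)))
  if (length(bad))
    stop2("%s: non-numeric or malformed row at line %d", path, bad[1])
  m <- do.call(rbind, lapply(parts, as.numeric))
  ord <- order(m[, 1], decreasing = TRUE)
  new_spectrum(m[ord, 1], m[ord, 2],
               sub("\\.[^.]*$", "", basename(path)))
}

#' Write a spectrum as two-column text
#'
#' @param spectrum a `spectrum`.
#' @param path output path (tab-separated, descending ppm).
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  utils::write.table(
    data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity),
    path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

META_COLS <- c("sample_id", "cultivar", "harvest", "plant_id")

#' Write a bucket table as CSV plus a JSON sidecar
#'
#' Columns are `sample_id, cultivar, harvest, plant_id`, then one column
#' per bucket headed by its 2-decimal central chemical shift.  A sidecar
#' `<path>.meta.json` records the scheme, state and normalization
#' constant so a read round-trips losslessly.
#'
#' @param table a `bucket_table`.
#' @param path CSV output path.
#' @export
write_bucket_table <- function(table, path) {
  stopifnot(inherits(table, "bucket_table"))
  df <- cbind(table$metadata[META_COLS],
              as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(state = table$state,
                  normalization_constant = table$normalization_constant,
                  bucket_labels = table$bucket_labels)
  if (!is.null(table$scheme))
    sidecar$scheme <- list(region_high = table$scheme$region_high,
                           region_low = table$scheme$region_low,
                           width = table$scheme$width,
                           exclusions = table$scheme$exclusions)
  if (!is.null(table$scaling_params))
    sidecar$scaling_params <- table$scaling_params
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bucket table written by [write_bucket_table()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read if present.
#' @return A `bucket_table`.
#' @export
read_bucket_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(META_COLS, names(df))
  if (length(missing))
    stop2("missing metadata column(s): %s", paste(missing, collapse = ", "))
  for (cc in META_COLS) df[[cc]] <- as.character(df[[cc]])
  labels <- setdiff(names(df), META_COLS)
  num <- suppressWarnings(as.numeric(labels))
  if (anyNA(num)) stop2("non-numeric bucket label(s): %s",
                        paste(labels[is.na(num)], collapse = ", "))
  if (any(diff(num) >= 0)) stop2("bucket labels must be strictly decreasing")
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample_id: %s",
          df$sample_id[duplicated(df$sample_id)][1])
  values <- as.matrix(df[labels])
  meta_path <- paste0(path, ".meta.json")
  state <- "raw"; norm_const <- NA_real_; scheme <- NULL; scaling <- NULL
  if (file.exists(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    state <- side$state %||% "raw"
    norm_const <- side$normalization_constant %||% NA_real_
    if (!is.null(side$scheme))
      scheme <- bucket_scheme(side$scheme$region_high, side$scheme$region_low,
                              side$scheme$width,
                              if (is.matrix(side$scheme$exclusions))
                                asplit(side$scheme$exclusions, 1)
                              else side$scheme$exclusions)
    scaling <- side$scaling_params
  }
  new_bucket_table(values, labels, df[META_COLS], state = state,
                   scheme = scheme, normalization_constant = norm_const,
                   scaling_params = scaling)
}
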