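#' @keywords internal
"_PACKAGE"

# shared internal helpers

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x)

# sample sd columnwise (denominator n - 1), kept explicit so every module
# uses the same convention
col_sds <- function(x) apply(x, 2L, stats::sd)

# Orient each column of a loading-like matrix so its largest-magnitude
# entry is positive; returns the sign vector applied.
orient_columns <- function(mat) {
  signs <- apply(mat, 2L, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  list(mat = sweep(mat, 2L, signs, `*`), signs = signs)
}

# draw a sub-seed stream deterministically from one integer seed
derive_seeds <- function(seed, n) {
  stopifnot(is_count(seed), is_count(n))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
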