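# Internal helpers shared across modules.

# stop() wrapper giving consistent classed errors so callers/tests can match
# on class rather than message text.
sd_abort <- function(msg, class = "sexdimorph_error") {
  rlang::abort(msg, class = class)
}

sd_validation_error <- function(msg) {
  rlang::abort(msg, class = c("sexdimorph_validation_error", "sexdimorph_error"))
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    sd_validation_error(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    sd_validation_error("counts must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    sd_validation_error("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) sd_validation_error("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) sd_validation_error("duplicate sample ids in counts")
  if (any(counts < 0) || any(!is.finite(counts))) {
    sd_validation_error("counts must be finite and non-negative")
  }
  invisible(counts)
}

# Geometric mean, guarding zeros out (used for TMM rescaling checks).
geo_mean <- function(x) exp(mean(log(x)))

`%||%` <- rlang::`%||%`
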