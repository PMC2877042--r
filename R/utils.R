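# Internal helpers shared across modules.

PROBE_LENGTH <- 25L

abort_validation <- function(message, ...) {
  abort(message, class = c("xsmm_validation_error", "xsmm_error"), ...)
}

abort_sizing <- function(message, ...) {
  abort(message, class = c("xsmm_sizing_error", "xsmm_error"), ...)
}

abort_ambiguity <- function(message, ...) {
  abort(message, class = c("xsmm_ambiguity_error", "xsmm_error"), ...)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_validation(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_data_frame <- function(x, name, columns = NULL) {
  if (!is.data.frame(x)) {
    abort_validation(sprintf("`%s` must be a data frame", name))
  }
  missing_cols <- setdiff(columns, names(x))
  if (length(missing_cols) > 0L) {
    abort_validation(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(x)
}

# Derive a per-stage seed from a global one; stays below .Machine$integer.max.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483587)
}
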