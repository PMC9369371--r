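# Internal helpers shared across modules.

# classed conditions so callers/tests can distinguish bad files from bad usage
stop_format <- function(msg) abort(msg, class = "cernet_format_error")
stop_validation <- function(msg) abort(msg, class = "cernet_validation_error")
stop_usage <- function(msg) abort(msg, class = "cernet_usage_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_choice <- function(x, choices, what) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices) {
    stop_usage(sprintf("`%s` must be one of: %s", what,
                       paste(choices, collapse = ", ")))
  }
  x
}

# uppercase a nucleotide string and map U -> T; reject anything non-nucleotide
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  if (grepl("[^ACGT]", x)) {
    stop_validation(sprintf("%s contains non-nucleotide characters", what))
  }
  x
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# midpoint-rule median on a numeric vector (stats::median already does this;
# kept as a named wrapper so the hub rule reads like its definition)
midpoint_median <- function(x) stats::median(x)
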