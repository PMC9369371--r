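# Library-size normalization and per-feature standardization.

#' Transcripts-per-million normalization
#'
#' Converts raw counts to TPM: per sample, each feature's count is divided by
#' its transcript length, and the length-normalized rates are rescaled to sum
#' to one million. TPM is the unit of choice for lncRNA/mRNA comparisons
#' because it corrects for both sequencing depth and transcript length.
#'
#' @param counts An [expr_matrix] with `unit = "counts"`.
#' @param lengths Named numeric vector of transcript lengths in bp, covering
#'   every feature.
#' @return An [expr_matrix] with `unit = "TPM"`; column sums equal 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  if (counts$unit != "counts") stop_usage("compute_tpm expects unit = 'counts'")
  ids <- rownames(counts$values)
  miss <- setdiff(ids, names(lengths))
  if (length(miss)) {
    stop_usage(sprintf("no length for feature: %s", miss[1]))
  }
  len <- lengths[ids]
  if (any(len <= 0)) stop_validation("transcript lengths must be positive")
  rate <- counts$values / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop_validation(sprintf("sample %s has zero total length-normalized rate",
                            colnames(counts$values)[which(tot == 0)[1]]))
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expr_matrix(tpm, setNames(counts$samples$group, counts$samples$sample_id),
              counts$rna_class, counts$region, unit = "TPM")
}

#' Counts-per-million normalization
#'
#' Converts raw counts to CPM: each sample is rescaled so its counts sum to
#' one million. Used for miRNAs, where transcript length does not vary enough
#' to warrant length correction.
#'
#' @param counts An [expr_matrix] with `unit = "counts"`.
#' @return An [expr_matrix] with `unit = "CPM"`; column sums equal 1e6.
#' @export
compute_cpm <- function(counts) {
  if (counts$unit != "counts") stop_usage("compute_cpm expects unit = 'counts'")
  tot <- colSums(counts$values)
  if (any(tot == 0)) {
    stop_validation(sprintf("sample %s has zero total counts",
                            colnames(counts$values)[which(tot == 0)[1]]))
  }
  cpm <- sweep(counts$values, 2, tot, "/") * 1e6
  expr_matrix(cpm, setNames(counts$samples$group, counts$samples$sample_id),
              counts$rna_class, counts$region, unit = "CPM")
}

#' Per-feature z-score standardization
#'
#' Standardizes each feature across samples to mean 0 and sample standard
#' deviation 1 (n - 1 denominator), the transform used before hierarchical
#' clustering displays.
#'
#' @param norm An [expr_matrix] (any non-zscore unit).
#' @return An [expr_matrix] with `unit = "zscore"`.
#' @export
zscore_rows <- function(norm) {
  v <- norm$values
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    stop_validation(sprintf("feature %s is constant across samples; cannot z-score",
                            rownames(v)[which(sds == 0)[1]]))
  }
  z <- (v - rowMeans(v)) / sds
  expr_matrix(z, setNames(norm$samples$group, norm$samples$sample_id),
              norm$rna_class, norm$region, unit = "zscore")
}
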