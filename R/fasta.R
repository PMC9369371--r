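# Thin FASTA wrappers (Biostrings-backed) used for the seed-site inputs.

#' Read and write FASTA sequence sets
#'
#' Sequences are handled as named character vectors throughout the package;
#' these wrappers convert to and from FASTA via Biostrings.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
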