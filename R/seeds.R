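# Seed-match site finding: a transparent stand-in for database target
# prediction, using the canonical site hierarchy (8mer > 7mer-m8 > 7mer-A1 >
# 6mer). Coordinates are 0-based, half-open, on the transcript sense strand.

#' Find miRNA seed-match sites on a transcript
#'
#' Scans a transcript (5'->3') for matches to the reverse complement of the
#' miRNA seed. miRNA position 1 is the 5' nucleotide. Site classes, written
#' as they appear on the transcript:
#' * `6mer` - reverse complement of miRNA nt 2-7;
#' * `7mer-m8` - reverse complement of nt 2-8 (an extra match opposite nt 8,
#'   immediately 5' of the 6mer core);
#' * `7mer-A1` - the 6mer core followed by an `A` opposite miRNA nt 1;
#' * `8mer` - both the m8 match and the A1 anchor.
#'
#' Each 6mer-core occurrence is reported once, at the strongest supported
#' class. T and U are equivalent on input.
#'
#' @param mirna_seq miRNA sequence, 5'->3', length >= 8.
#' @param transcript_seq Transcript sequence, 5'->3'.
#' @param transcript_id,mirna_id Optional IDs carried into the result.
#' @param site_types Site classes to report (default all four).
#' @return A tibble with `transcript_id`, `mirna_id`, `start`, `end`
#'   (0-based half-open), `site_type`; zero rows when nothing matches.
#' @examples
#' # an 8mer site: core match + m8 match + A anchor
#' mir <- "UGGAAUGUAAAGAAGUAUGUAU"
#' find_seed_sites(mir, paste0("CCCCC", "ACATTCCA", "GGGGG"))
#' @export
find_seed_sites <- function(mirna_seq, transcript_seq,
                            transcript_id = "transcript", mirna_id = "miRNA",
                            site_types = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  mir <- normalize_seq(mirna_seq, "miRNA sequence")
  tx <- normalize_seq(transcript_seq, "transcript sequence")
  if (nchar(mir) < 8) stop_usage("miRNA sequence must be at least 8 nt")
  site_types <- match.arg(site_types, several.ok = TRUE)

  core <- revcomp(substr(mir, 2, 7))        # 6 nt, matches opposite nt 2-7
  m8 <- revcomp(substr(mir, 8, 8))          # 1 nt immediately 5' of the core

  empty <- tibble(transcript_id = character(), mirna_id = character(),
                  start = integer(), end = integer(), site_type = character())
  if (nchar(tx) < 6) return(empty)

  starts <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(core, substr(tx, from, nchar(tx)), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  if (!length(starts)) return(empty)

  rows <- lapply(starts, function(s) {     # s: 1-based core start
    has_m8 <- s > 1 && substr(tx, s - 1, s - 1) == m8
    has_a1 <- s + 6 <= nchar(tx) && substr(tx, s + 6, s + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    if (!type %in% site_types) return(NULL)
    start0 <- s - 1L - (has_m8)            # extend 5' for the m8 match
    end0 <- s + 5L + (has_a1)              # extend 3' for the A anchor
    tibble(transcript_id = transcript_id, mirna_id = mirna_id,
           start = as.integer(start0), end = as.integer(end0),
           site_type = type)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}
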