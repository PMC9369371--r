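# Readers/writers for target tables, transcript metadata and network exports.

#' Normalize miRNA identifiers
#'
#' Canonicalizes the "miR" capitalization and optionally strips a
#' three-letter species prefix (e.g. `mmu-`), so identifiers from different
#' databases merge on the same key.
#'
#' @param x Character vector of miRNA IDs.
#' @param strip_species_prefix Drop a leading `xxx-` species tag?
#' @return Character vector of normalized IDs.
#' @examples
#' normalize_mirna_id("mmu-miR-329-3p", strip_species_prefix = TRUE)
#' @export
normalize_mirna_id <- function(x, strip_species_prefix = FALSE) {
  if (strip_species_prefix) {
    x <- sub("^[A-Za-z]{3}-(?=[Mm]i[Rr])", "", x, perl = TRUE)
  }
  sub("^mir(?=-)", "miR", x, ignore.case = TRUE, perl = TRUE)
}

#' Read a target-interaction table
#'
#' Loads a TSV of predicted interactions (columns `source`, `target`,
#' `provenance`) as exported from target-prediction databases, types the
#' edges, normalizes miRNA IDs, and collapses duplicated rows.
#'
#' @param path Path to the TSV file.
#' @param edge_type `"lnc_mi"` (lncRNA to miRNA) or `"mi_m"` (miRNA to mRNA).
#' @param strip_species_prefix Passed to [normalize_mirna_id()].
#' @return A tibble of edges: `source_id`, `target_id`, `edge_type`,
#'   `provenance` (sorted, `;`-joined source tags).
#' @export
read_target_table <- function(path, edge_type, strip_species_prefix = FALSE) {
  assert_scalar_choice(edge_type, c("lnc_mi", "mi_m"), "edge_type")
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  need <- c("source", "target", "provenance")
  if (!all(need %in% names(df))) {
    stop_format(sprintf("target TSV %s must have columns: %s", path,
                        paste(need, collapse = ", ")))
  }
  edges <- tibble(
    source_id = df$source, target_id = df$target,
    edge_type = edge_type, provenance = df$provenance
  )
  mi_col <- if (edge_type == "lnc_mi") "target_id" else "source_id"
  edges[[mi_col]] <- normalize_mirna_id(edges[[mi_col]], strip_species_prefix)
  merge_predictions(list(edges))
}

#' Filter transcripts to credible novel-lncRNA candidates
#'
#' Applies the standard lncRNA discovery filters: at least two exons, length
#' above 200 bp, expression at or above 1 FPKM, and no coding-potential tool
#' calling the transcript coding. Transcripts already annotated as known
#' lncRNAs bypass only the coding-potential test; the numeric filters still
#' apply.
#'
#' @param metas Data frame with columns `feature_id`, `length_bp`,
#'   `exon_count`, `fpkm`, four logical coding verdicts (`coding_cpc2`,
#'   `coding_cnci`, `coding_pfam`, `coding_plek`; `TRUE` = coding) and
#'   `annotation_status` (`"known"`/`"novel"`).
#' @return Character vector of retained `feature_id`s, in input order.
#' @export
filter_lncrna_candidates <- function(metas) {
  metas <- as_tibble(metas)
  need <- c("feature_id", "length_bp", "exon_count", "fpkm", "coding_cpc2",
            "coding_cnci", "coding_pfam", "coding_plek", "annotation_status")
  miss <- setdiff(need, names(metas))
  if (length(miss)) {
    stop_usage(sprintf("metas is missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (any(metas$length_bp <= 0) || any(metas$exon_count < 1)) {
    stop_validation("length_bp must be > 0 and exon_count >= 1")
  }
  noncoding <- !(metas$coding_cpc2 | metas$coding_cnci |
                   metas$coding_pfam | metas$coding_plek)
  keep <- metas$exon_count >= 2 &
    metas$length_bp > 200 &
    metas$fpkm >= 1 &
    (metas$annotation_status == "known" | noncoding)
  metas$feature_id[keep]
}

sif_network_lines <- function(edges) {
  edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
  sprintf("%s\t%s\t%s", edges$source_id, edges$edge_type, edges$target_id)
}

#' Export a ceRNA network
#'
#' Writes a [cerna_graph] in SIF, GraphML, or edge-list TSV form with
#' lexicographically sorted nodes and edges, so repeated exports of the same
#' graph are byte-identical. Edges are written with the lncRNA (or miRNA)
#' endpoint first, so node classes are recoverable from the relation type.
#'
#' @param graph A [cerna_graph].
#' @param path Output path.
#' @param format `"sif"`, `"graphml"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "tsv")) {
  if (!inherits(graph, "cerna_graph")) stop_usage("`graph` must be a cerna_graph")
  format <- assert_scalar_choice(format[1], c("sif", "graphml", "tsv"), "format")
  nodes <- network_nodes(graph)
  edges <- network_edges(graph)
  # orient edges source = upstream class (lnc for lnc_mi, mi for mi_m)
  if (format == "sif") {
    lines <- sif_network_lines(edges)
    isolated <- sort(setdiff(nodes$node_id, c(edges$source_id, edges$target_id)))
    writeLines(c(lines, isolated), path)
  } else if (format == "tsv") {
    edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    g <- igraph_from_parts(nodes[order(nodes$node_id), , drop = FALSE],
                           edges[order(edges$source_id, edges$target_id), ,
                                 drop = FALSE])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a ceRNA network export
#'
#' Inverse of [write_network()]. For SIF and TSV exports, node classes are
#' reconstructed from the edge relation (`lnc_mi`, `mi_m`); GraphML preserves
#' all node attributes directly. Round trips preserve the node set, edge set,
#' and node-class map.
#'
#' @inheritParams write_network
#' @return A [cerna_graph].
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- assert_scalar_choice(format[1], c("sif", "graphml", "tsv"), "format")
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      node_id = igraph::V(g)$name,
      node_class = igraph::V(g)$node_class,
      regulation = igraph::V(g)$regulation %||% NA_character_
    )
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble(source_id = ed$from, target_id = ed$to,
                    edge_type = ed$edge_type,
                    provenance = ed$provenance %||% NA_character_)
    return(cerna_graph(nodes, edges))
  }
  if (format == "tsv") {
    edges <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    isolated <- character()
  } else {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    n_tok <- lengths(parts)
    if (any(!n_tok %in% c(1L, 3L))) stop_format("malformed SIF line")
    ep <- parts[n_tok == 3L]
    edges <- tibble(source_id = vapply(ep, `[[`, "", 1),
                    edge_type = vapply(ep, `[[`, "", 2),
                    target_id = vapply(ep, `[[`, "", 3),
                    provenance = NA_character_)
    isolated <- as.character(unlist(parts[n_tok == 1L]))
  }
  class_of <- function(end, type) {
    ifelse(type == "lnc_mi", if (end == "source") "lncRNA" else "miRNA",
           if (end == "source") "miRNA" else "mRNA")
  }
  nodes <- bind_rows(
    tibble(node_id = edges$source_id,
           node_class = class_of("source", edges$edge_type)),
    tibble(node_id = edges$target_id,
           node_class = class_of("target", edges$edge_type)),
    tibble(node_id = isolated, node_class = NA_character_)
  ) |> distinct(.data$node_id, .keep_all = TRUE)
  nodes$regulation <- NA_character_
  cerna_graph(nodes, as_tibble(edges)[, c("source_id", "target_id",
                                          "edge_type", "provenance")])
}
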