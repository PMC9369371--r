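# Packaged worked-example tables: the published per-region SDEL lists, the
# core (both-region) lncRNAs, the final L-M-T interaction groupings, and the
# qPCR primer panel. Shipped as plain TSV under extdata and checksummed so a
# corrupted install is caught at load time.

fixture_md5 <- c(
  sdel_cortex.tsv = "4ffae687c445293b54d12008163b3a7a",
  sdel_hippocampus.tsv = "0d67730827060d1577abf892bfa4323c",
  core_lncrnas.tsv = "fbb871e96e4f4e5693e93b9b23e321c8",
  lmt_interactions.tsv = "e4a403814c6be574f168a08dc58a7285",
  qpcr_primers.tsv = "db93f9ba304a8b5296c4fcf9035bfde6"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cernet", mustWork = TRUE)
  got <- unname(tools::md5sum(p))
  if (got != fixture_md5[[file]]) {
    abort(sprintf("fixture %s failed its checksum (packaging error)", file),
          class = "cernet_packaging_error")
  }
  p
}

#' Packaged worked-example tables
#'
#' Returns the published tables shipped with the package: the significantly
#' differentially expressed lncRNA (SDEL) lists for cortex and hippocampus
#' (group-mean TPM, log2 fold change, p, q, regulation), the seven core
#' lncRNAs shared by both regions, the lncRNA-miRNA-mRNA (L-M-T) interaction
#' groupings of the final network, and the qPCR primer panel. Files are
#' checksum-verified on load.
#'
#' @return A named list of tibbles: `sdel_cortex` (53 rows),
#'   `sdel_hippocampus` (51 rows), `core_lncrnas` (7 rows),
#'   `lmt_interactions` (5 row groups), `qpcr_primers`.
#' @examples
#' fx <- fixtures()
#' nrow(fx$sdel_cortex)
#' @export
fixtures <- function() {
  read_fx <- function(f, types) {
    readr::read_tsv(fixture_path(f), col_types = types, progress = FALSE)
  }
  list(
    sdel_cortex = read_fx("sdel_cortex.tsv", "ccddddd"),
    sdel_hippocampus = read_fx("sdel_hippocampus.tsv", "ccddddd"),
    core_lncrnas = read_fx("core_lncrnas.tsv", "cdddcdddc"),
    lmt_interactions = read_fx("lmt_interactions.tsv", "ccc"),
    qpcr_primers = read_fx("qpcr_primers.tsv", "cc")
  )
}

#' Edge list of the packaged L-M-T network
#'
#' Expands the grouped interaction table into an edge list. Each lncRNA is
#' connected to the miRNAs listed for its row group; miRNA-mRNA edges are
#' row-complete by default (every miRNA in a row group paired with every
#' mRNA in that group), since the published groupings list mRNAs per row
#' rather than per miRNA. A custom assignment of mRNAs to miRNAs within row
#' groups can be supplied to explore alternative wirings.
#'
#' @param mi_m_assignment Optional tibble (`source_id` miRNA, `target_id`
#'   mRNA) replacing the row-complete miRNA-mRNA edges; every mRNA of a row
#'   group must stay adjacent to at least one of its row's miRNAs.
#' @return A list with `edges` (combined edge tibble) and `nodes` (tibble
#'   with `node_id`, `node_class`).
#' @export
lmt_fixture_edges <- function(mi_m_assignment = NULL) {
  tab <- fixtures()$lmt_interactions
  rows <- purrr::pmap(tab, function(lncrna_id, mirna_ids, mrna_ids) {
    mis <- strsplit(mirna_ids, ";")[[1]]
    ms <- strsplit(mrna_ids, ";")[[1]]
    list(
      lnc_mi = tibble(source_id = lncrna_id, target_id = mis,
                      edge_type = "lnc_mi", provenance = "published"),
      mi_m = tidyr::expand_grid(source_id = mis, target_id = ms) |>
        mutate(edge_type = "mi_m", provenance = "published")
    )
  })
  lnc_mi <- distinct(bind_rows(purrr::map(rows, "lnc_mi")))
  mi_m <- if (is.null(mi_m_assignment)) {
    distinct(bind_rows(purrr::map(rows, "mi_m")))
  } else {
    as_tibble(mi_m_assignment) |>
      mutate(edge_type = "mi_m", provenance = "assigned")
  }
  nodes <- bind_rows(
    tibble(node_id = unique(lnc_mi$source_id), node_class = "lncRNA"),
    tibble(node_id = unique(lnc_mi$target_id), node_class = "miRNA"),
    tibble(node_id = unique(unlist(strsplit(tab$mrna_ids, ";"))),
           node_class = "mRNA")
  )
  list(edges = bind_rows(lnc_mi, mi_m), nodes = nodes)
}

#' The packaged L-M-T network as a ranked graph
#'
#' Builds the final tripartite network from the packaged interaction
#' groupings via [build_lmt_network()], so its centralities and node ranking
#' can be inspected directly.
#'
#' @inheritParams lmt_fixture_edges
#' @return A [cerna_graph] with centralities and ranks.
#' @export
lmt_fixture_graph <- function(mi_m_assignment = NULL) {
  fx <- lmt_fixture_edges(mi_m_assignment)
  nd <- fx$nodes
  build_lmt_network(nd$node_id[nd$node_class == "lncRNA"],
                    nd$node_id[nd$node_class == "miRNA"],
                    nd$node_id[nd$node_class == "mRNA"],
                    fx$edges)
}
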