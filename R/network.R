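# Tripartite ceRNA graphs: construction, Cytoscape-convention centralities,
# hub selection, and sign-consistent triad assembly.

#' Construct a ceRNA graph
#'
#' A typed undirected graph whose nodes are lncRNAs, miRNAs and mRNAs and
#' whose edges are restricted to lncRNA-miRNA and miRNA-mRNA pairs. Parallel
#' edges, self loops and same-layer edges are rejected.
#'
#' @param nodes Tibble with `node_id`, `node_class`
#'   (`"lncRNA"`/`"miRNA"`/`"mRNA"`), and optionally `regulation`
#'   (`"up"`/`"down"`/`NA`).
#' @param edges Tibble with `source_id`, `target_id`, `edge_type`
#'   (`"lnc_mi"`/`"mi_m"`), and optionally `provenance`.
#' @return An object of class `cerna_graph`.
#' @export
cerna_graph <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"regulation" %in% names(nodes)) nodes$regulation <- NA_character_
  if (!"provenance" %in% names(edges)) edges$provenance <- NA_character_
  if (anyDuplicated(nodes$node_id)) {
    stop_validation(sprintf("duplicate node: %s",
                            nodes$node_id[duplicated(nodes$node_id)][1]))
  }
  known_class <- !is.na(nodes$node_class)
  if (!all(nodes$node_class[known_class] %in% c("lncRNA", "miRNA", "mRNA"))) {
    stop_validation("node_class must be lncRNA, miRNA or mRNA")
  }
  if (nrow(edges)) {
    if (any(edges$source_id == edges$target_id)) {
      stop_validation("self loops are not allowed")
    }
    miss <- setdiff(c(edges$source_id, edges$target_id), nodes$node_id)
    if (length(miss)) {
      stop_validation(sprintf("edge endpoint not declared as node: %s", miss[1]))
    }
    key <- paste(pmin(edges$source_id, edges$target_id),
                 pmax(edges$source_id, edges$target_id))
    if (anyDuplicated(key)) stop_validation("parallel edges are not allowed")
    cls <- setNames(nodes$node_class, nodes$node_id)
    sc <- cls[edges$source_id]; tc <- cls[edges$target_id]
    # normalize orientation: upstream class (lncRNA, resp. miRNA) first
    flip <- (edges$edge_type == "lnc_mi" & sc == "miRNA" & tc == "lncRNA") |
      (edges$edge_type == "mi_m" & sc == "mRNA" & tc == "miRNA")
    flip[is.na(flip)] <- FALSE
    if (any(flip)) {
      tmp <- edges$source_id[flip]
      edges$source_id[flip] <- edges$target_id[flip]
      edges$target_id[flip] <- tmp
      sc <- cls[edges$source_id]; tc <- cls[edges$target_id]
    }
    ok <- ifelse(edges$edge_type == "lnc_mi",
                 sc == "lncRNA" & tc == "miRNA",
                 ifelse(edges$edge_type == "mi_m",
                        sc == "miRNA" & tc == "mRNA", FALSE))
    ok[is.na(ok)] <- TRUE  # endpoints of unknown class pass through
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop_validation(sprintf("edge %s-%s violates the %s layer restriction",
                              edges$source_id[bad], edges$target_id[bad],
                              edges$edge_type[bad]))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_graph")
}

#' @export
print.cerna_graph <- function(x, ...) {
  cls <- table(factor(x$nodes$node_class, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("<cerna_graph> %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), cls["lncRNA"], cls["miRNA"], cls["mRNA"],
              nrow(x$edges)))
  invisible(x)
}

#' Node and edge tables of a ceRNA graph
#' @param graph A [cerna_graph].
#' @return A tibble of nodes (with centralities when computed) or edges.
#' @export
network_nodes <- function(graph) graph$nodes

#' @rdname network_nodes
#' @export
network_edges <- function(graph) graph$edges

igraph_from_parts <- function(nodes, edges) {
  igraph::graph_from_data_frame(
    d = edges[, c("source_id", "target_id",
                  intersect(c("edge_type", "provenance"), names(edges)))],
    directed = FALSE,
    vertices = as.data.frame(nodes[, c("node_id", "node_class", "regulation")])
  )
}

as_igraph <- function(graph) igraph_from_parts(graph$nodes, graph$edges)

#' Build a bipartite lncRNA-miRNA graph
#'
#' Keeps only edges whose endpoints are in the declared node sets; edges with
#' a missing endpoint are dropped with a warning. Declared nodes without
#' edges remain as isolated nodes.
#'
#' @param lnc_nodes Tibble with `node_id` and `regulation` for the lncRNAs.
#' @param edges lnc_mi edge tibble ([read_target_table()] format).
#' @param mirna_nodes Tibble with `node_id` (and optionally `regulation`)
#'   for the miRNAs, or a character vector of IDs.
#' @return A [cerna_graph].
#' @export
build_bipartite <- function(lnc_nodes, edges, mirna_nodes) {
  if (is.character(mirna_nodes)) mirna_nodes <- tibble(node_id = mirna_nodes)
  if (!"regulation" %in% names(mirna_nodes)) mirna_nodes$regulation <- NA_character_
  edges <- as_tibble(edges)
  keep <- edges$source_id %in% lnc_nodes$node_id &
    edges$target_id %in% mirna_nodes$node_id
  if (any(!keep)) {
    warn(sprintf("dropping %d edge(s) with endpoints outside the declared sets",
                 sum(!keep)))
    edges <- edges[keep, , drop = FALSE]
  }
  nodes <- bind_rows(
    tibble(node_id = lnc_nodes$node_id, node_class = "lncRNA",
           regulation = lnc_nodes$regulation),
    tibble(node_id = mirna_nodes$node_id, node_class = "miRNA",
           regulation = mirna_nodes$regulation)
  )
  cerna_graph(nodes, edges)
}

#' Node centralities under Cytoscape NetworkAnalyzer conventions
#'
#' Degree, closeness and betweenness for every node. Closeness is computed
#' within a node's connected component as (number of other reachable nodes) /
#' (sum of shortest-path distances to them); isolated nodes get 0.
#' Betweenness is the shortest-path pair-dependency sum normalized by
#' (N-1)(N-2)/2 where N is the node count of the whole graph.
#'
#' @param graph A [cerna_graph].
#' @return The graph, with `degree`, `betweenness`, `closeness` columns
#'   added to its node table (retrieve with [network_nodes()]).
#' @export
centralities <- function(graph) {
  if (nrow(graph$nodes) == 0) return(graph)
  g <- as_igraph(graph)
  deg <- igraph::degree(g)
  btw <- if (igraph::vcount(g) > 2) {
    igraph::betweenness(g, normalized = TRUE)
  } else {
    setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  }
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  ord <- match(graph$nodes$node_id, igraph::V(g)$name)
  graph$nodes$degree <- as.integer(deg[ord])
  graph$nodes$betweenness <- unname(btw[ord])
  graph$nodes$closeness <- unname(cls[ord])
  graph
}

#' Select hub miRNAs by the twice-the-median degree rule
#'
#' Returns the miRNAs whose degree strictly exceeds twice the median degree
#' over all miRNA nodes (median by the midpoint rule).
#'
#' @param graph A [cerna_graph].
#' @return Sorted character vector of hub miRNA IDs.
#' @export
select_hub_mirnas <- function(graph) {
  g <- if ("degree" %in% names(graph$nodes)) graph else centralities(graph)
  mi <- g$nodes[g$nodes$node_class == "miRNA", , drop = FALSE]
  if (nrow(mi) == 0) stop_usage("graph has no miRNA nodes")
  thr <- 2 * midpoint_median(mi$degree)
  sort(mi$node_id[mi$degree > thr])
}

#' Assemble sign-consistent ceRNA triads
#'
#' Enumerates every (lncRNA, miRNA, mRNA) triple connected by both a lnc_mi
#' and a mi_m edge and splits it by the ceRNA sign rule: the lncRNA and the
#' mRNA must share a regulation direction opposite to the miRNA's.
#'
#' @param graph A tripartite [cerna_graph] whose nodes carry regulation
#'   calls.
#' @return A list with tibbles `retained` (columns `lncrna_id`, `mirna_id`,
#'   `mrna_id`, the three regulations, `evidence`) and `rejected` (same
#'   columns plus `violation` naming the failed rule).
#' @export
assemble_triads <- function(graph) {
  nodes <- graph$nodes
  reg <- setNames(nodes$regulation, nodes$node_id)
  ed <- graph$edges
  lm <- ed[ed$edge_type == "lnc_mi", , drop = FALSE]
  mm <- ed[ed$edge_type == "mi_m", , drop = FALSE]
  triples <- inner_join(
    lm |> rename(lncrna_id = "source_id", mirna_id = "target_id",
                 lnc_prov = "provenance") |> select(-"edge_type"),
    mm |> rename(mirna_id = "source_id", mrna_id = "target_id",
                 m_prov = "provenance") |> select(-"edge_type"),
    by = "mirna_id", relationship = "many-to-many"
  )
  empty <- tibble(lncrna_id = character(), mirna_id = character(),
                  mrna_id = character(), lnc_regulation = character(),
                  mirna_regulation = character(), mrna_regulation = character(),
                  evidence = character())
  if (nrow(triples) == 0) {
    return(list(retained = empty,
                rejected = mutate(empty, violation = character())))
  }
  triples <- triples |>
    mutate(lnc_regulation = unname(reg[.data$lncrna_id]),
           mirna_regulation = unname(reg[.data$mirna_id]),
           mrna_regulation = unname(reg[.data$mrna_id]),
           evidence = paste0("lnc_mi:", .data$lnc_prov, "|mi_m:", .data$m_prov),
           violation = dplyr::case_when(
             is.na(lnc_regulation) | is.na(mirna_regulation) |
               is.na(mrna_regulation) ~ "missing regulation call",
             lnc_regulation != mrna_regulation ~ "lncRNA and mRNA not co-regulated",
             lnc_regulation == mirna_regulation ~ "miRNA not anti-correlated",
             TRUE ~ NA_character_
           )) |>
    select(-"lnc_prov", -"m_prov") |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  list(
    retained = triples |> filter(is.na(.data$violation)) |> select(-"violation"),
    rejected = triples |> filter(!is.na(.data$violation))
  )
}

#' Build the final lncRNA-miRNA-mRNA network
#'
#' Restricts a tripartite edge set to the given node pools, drops nodes with
#' no retained edge, computes centralities, and ranks nodes by
#' (degree, betweenness, closeness) descending with a lexicographic ID
#' tie-break.
#'
#' @param lnc_nodes,mirna_nodes,mrna_nodes Tibbles with `node_id` and
#'   optionally `regulation`, or character ID vectors.
#' @param edges Edge tibble mixing `lnc_mi` and `mi_m` rows.
#' @return A [cerna_graph] whose node table carries centralities and a
#'   `rank` column.
#' @export
build_lmt_network <- function(lnc_nodes, mirna_nodes, mrna_nodes, edges) {
  as_node_tbl <- function(x, cls) {
    if (is.character(x)) x <- tibble(node_id = x)
    if (!"regulation" %in% names(x)) x$regulation <- NA_character_
    tibble(node_id = x$node_id, node_class = cls, regulation = x$regulation)
  }
  nodes <- bind_rows(as_node_tbl(lnc_nodes, "lncRNA"),
                     as_node_tbl(mirna_nodes, "miRNA"),
                     as_node_tbl(mrna_nodes, "mRNA"))
  edges <- as_tibble(edges)
  keep <- edges$source_id %in% nodes$node_id & edges$target_id %in% nodes$node_id
  edges <- edges[keep, , drop = FALSE]
  used <- unique(c(edges$source_id, edges$target_id))
  nodes <- nodes[nodes$node_id %in% used, , drop = FALSE]
  g <- centralities(cerna_graph(nodes, edges))
  g$nodes <- g$nodes |>
    arrange(desc(.data$degree), desc(.data$betweenness),
            desc(.data$closeness), .data$node_id) |>
    mutate(rank = row_number())
  g
}
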