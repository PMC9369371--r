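test_that("graph construction rejects invalid structures", {
  nodes <- tibble::tibble(node_id = c("L1", "I1", "M1"),
                          node_class = c("lncRNA", "miRNA", "mRNA"))
  ok <- tibble::tibble(source_id = "L1", target_id = "I1", edge_type = "lnc_mi")
  expect_s3_class(cerna_graph(nodes, ok), "cerna_graph")
  bad_layer <- tibble::tibble(source_id = "L1", target_id = "M1",
                              edge_type = "lnc_mi")
  expect_error(cerna_graph(nodes, bad_layer), class = "cernet_validation_error")
  loop <- tibble::tibble(source_id = "I1", target_id = "I1", edge_type = "mi_m")
  expect_error(cerna_graph(nodes, loop), class = "cernet_validation_error")
  par <- dplyr::bind_rows(ok, ok)
  expect_error(cerna_graph(nodes, par), class = "cernet_validation_error")
})

test_that("bipartite builder keeps declared isolates and drops stray edges", {
  lncs <- tibble::tibble(node_id = c("L1", "L2"), regulation = "up")
  edges <- tibble::tibble(
    source_id = c("L1", "L1", "L1", "L2", "L2", "L2", "L9"),
    target_id = c("I1", "I2", "I3", "I1", "I2", "I3", "I1"),
    edge_type = "lnc_mi", provenance = "db")
  expect_warning(g <- build_bipartite(lncs, edges, paste0("I", 1:3)),
                 "dropping 1")
  expect_equal(nrow(network_nodes(g)), 5)
  expect_equal(nrow(network_edges(g)), 6)

  g2 <- build_bipartite(lncs, edges[0, ], paste0("I", 1:3))
  expect_equal(nrow(network_nodes(g2)), 5)
  expect_equal(nrow(network_edges(g2)), 0)
})

test_that("centralities match closed forms on path and star graphs", {
  path3 <- cerna_graph(
    tibble::tibble(node_id = c("a", "b", "c"),
                   node_class = c("lncRNA", "miRNA", "mRNA")),
    tibble::tibble(source_id = c("a", "b"), target_id = c("b", "c"),
                   edge_type = c("lnc_mi", "mi_m")))
  nd <- tidy(centralities(path3))
  b <- nd[nd$node_id == "b", ]
  expect_equal(b$degree, 2L)
  expect_equal(b$closeness, 1)
  expect_equal(b$betweenness, 1)

  # star with 4 leaves: center closeness 1, leaf closeness 4/(1+2+2+2)
  star <- cerna_graph(
    tibble::tibble(node_id = c("hub", paste0("L", 1:4)),
                   node_class = c("miRNA", rep("lncRNA", 4))),
    tibble::tibble(source_id = paste0("L", 1:4), target_id = "hub",
                   edge_type = "lnc_mi"))
  ns <- tidy(centralities(star))
  expect_equal(ns$closeness[ns$node_id == "hub"], 1)
  expect_equal(ns$closeness[ns$node_id == "L1"], 4 / 7)
})

test_that("centralities agree with a brute-force all-pairs oracle", {
  set.seed(13)
  sizes <- rbind(c(1, 1, 1), c(1, 2, 1), c(2, 2, 2), c(2, 3, 2), c(3, 3, 3),
                 c(3, 4, 3), c(4, 4, 4))
  for (rep in 1:4) {
    for (i in seq_len(nrow(sizes))) {
      rg <- random_cerna_graph(sizes[i, 1], sizes[i, 2], sizes[i, 3],
                               p = runif(1, 0.2, 0.8))
      nd <- tidy(centralities(rg$graph))
      oc <- oracle_centralities(rg$adj)
      ord <- match(nd$node_id, rownames(rg$adj))
      expect_equal(nd$degree, as.integer(oc$degree[ord]))
      expect_equal(nd$closeness, oc$closeness[ord], tolerance = 1e-12)
      expect_equal(nd$betweenness, oc$betweenness[ord], tolerance = 1e-12)
    }
  }
})

test_that("hub selection follows the strict twice-the-median degree rule", {
  star_graph <- function(degrees) {
    # one miRNA per degree, each connected to its own set of lncRNAs
    edges <- list(); nodes <- list()
    for (i in seq_along(degrees)) {
      mi <- sprintf("I%d", i)
      ls <- sprintf("L%d_%d", i, seq_len(degrees[i]))
      nodes[[i]] <- tibble::tibble(node_id = c(mi, ls),
                                   node_class = c("miRNA", rep("lncRNA", length(ls))))
      edges[[i]] <- tibble::tibble(source_id = ls, target_id = mi,
                                   edge_type = "lnc_mi")
    }
    cerna_graph(dplyr::bind_rows(nodes), dplyr::bind_rows(edges))
  }
  # homogeneous degrees: threshold 2d never strictly exceeded
  expect_length(select_hub_mirnas(star_graph(c(3, 3, 3))), 0)
  # degrees {1,1,1,2,5,9}: median 1.5, threshold 3 -> the 5 and the 9
  hubs <- select_hub_mirnas(star_graph(c(1, 1, 1, 2, 5, 9)))
  expect_setequal(hubs, c("I5", "I6"))

  # hub selection depends only on the miRNA degree multiset
  hubs2 <- select_hub_mirnas(star_graph(c(9, 5, 2, 1, 1, 1)))
  expect_length(hubs2, 2)

  # adding an edge to a hub never removes it from the hub set
  set.seed(14)
  for (i in 1:20) {
    degs <- sample(1:10, 6, replace = TRUE)
    g <- star_graph(degs)
    h <- select_hub_mirnas(g)
    if (!length(h)) next
    target <- h[1]
    idx <- as.integer(sub("I", "", target))
    degs2 <- degs; degs2[idx] <- degs2[idx] + 1
    expect_true(target %in% select_hub_mirnas(star_graph(degs2)))
  }
})

test_that("triad assembly matches exhaustive enumeration and the sign rule", {
  # the canonical worked example: up lncRNA, down miRNA, up mRNA
  nodes <- tibble::tibble(
    node_id = c("L1", "I1", "M1"), node_class = c("lncRNA", "miRNA", "mRNA"),
    regulation = c("up", "down", "up"))
  edges <- tibble::tibble(source_id = c("L1", "I1"), target_id = c("I1", "M1"),
                          edge_type = c("lnc_mi", "mi_m"), provenance = "db")
  tri <- assemble_triads(cerna_graph(nodes, edges))
  expect_equal(nrow(tri$retained), 1)

  nodes$regulation <- c("up", "up", "up")
  tri2 <- assemble_triads(cerna_graph(nodes, edges))
  expect_equal(nrow(tri2$retained), 0)
  expect_equal(tri2$rejected$violation, "miRNA not anti-correlated")

  set.seed(15)
  for (i in 1:10) {
    rg <- random_cerna_graph(sample(3:8, 1), sample(3:8, 1), sample(3:8, 1),
                             p = runif(1, 0.2, 0.6))
    got <- assemble_triads(rg$graph)$retained
    key <- sort(paste(got$lncrna_id, got$mirna_id, got$mrna_id))
    expect_equal(key, oracle_triads(rg$graph))
    if (nrow(got)) {
      expect_true(all(got$lnc_regulation == got$mrna_regulation))
      expect_true(all(got$lnc_regulation != got$mirna_regulation))
    }
  }
})

test_that("the final network drops edgeless nodes and ranks deterministically", {
  edges <- tibble::tibble(
    source_id = c("L1", "L1", "I1"), target_id = c("I1", "I2", "M1"),
    edge_type = c("lnc_mi", "lnc_mi", "mi_m"), provenance = "db")
  g <- build_lmt_network(c("L1", "L9"), c("I1", "I2"), c("M1", "M9"), edges)
  expect_setequal(network_nodes(g)$node_id, c("L1", "I1", "I2", "M1"))
  nd <- tidy(g)
  expect_equal(nd$rank, seq_len(nrow(nd)))
  # L1 and I1 tie on degree 2; I1 wins on betweenness (it bridges to M1)
  expect_equal(nd$node_id[1:2], c("I1", "L1"))
})
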