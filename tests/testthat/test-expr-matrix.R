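test_that("expression matrix construction enforces its invariants", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  grp <- setNames(c("case", "case", "control", "control"), paste0("s", 1:4))
  em <- expr_matrix(m, grp, "mRNA", "cortex")
  expect_s3_class(em, "expr_matrix")
  expect_equal(dim(em), c(2L, 4L))

  dup <- m; rownames(dup) <- c("a", "a")
  expect_error(expr_matrix(dup, grp, "mRNA", "cortex"), class = "cernet_format_error")
  neg <- m; neg[1, 1] <- -1
  expect_error(expr_matrix(neg, grp, "mRNA", "cortex"),
               class = "cernet_validation_error")
  expect_error(expr_matrix(m, grp[1:3], "mRNA", "cortex"),
               class = "cernet_validation_error")
  expect_error(expr_matrix(m, setNames(rep("case", 4), paste0("s", 1:4)),
                           "mRNA", "cortex"),
               class = "cernet_validation_error")
  # z-scores may be negative
  expect_silent(expr_matrix(m - 4, grp, "mRNA", "cortex", unit = "zscore"))
})

test_that("expression TSVs parse, validate, and round-trip value-identically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ts3\ts4",
               "g1\t5\t7\t0\t1", "g2\t10\t0\t3\t8"), path)
  grp <- setNames(c("case", "case", "control", "control"), paste0("s", 1:4))
  em <- read_expression_matrix(path, "lncRNA", "cortex", grp)
  expect_equal(rownames(em$values), c("g1", "g2"))
  expect_equal(unname(em$values["g2", "s3"]), 3)
  expect_equal(table(em$samples$group)[["case"]], 2L)

  writeLines(c("feature_id\ts1\ts2\ts3\ts4",
               "g1\t5\t7\t0\t1", "g1\t1\t1\t1\t1"), path)
  expect_error(read_expression_matrix(path, "lncRNA", "cortex", grp),
               class = "cernet_format_error")

  set.seed(42)
  big <- matrix(as.double(rpois(500 * 6, 40)), 500, 6,
                dimnames = list(sprintf("f%03d", 1:500), sprintf("s%d", 1:6)))
  grp6 <- setNames(rep(c("case", "control"), each = 3), colnames(big))
  em2 <- expr_matrix(big, grp6, "mRNA", "hippocampus")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em2, out)
  back <- read_expression_matrix(out, "mRNA", "hippocampus", grp6)
  expect_identical(back$values, em2$values)
})

test_that("long-format view carries group, class and unit labels", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  em <- expr_matrix(m, c(s1 = "case", s2 = "control"), "miRNA", "cortex")
  tb <- tibble::as_tibble(em)
  expect_equal(nrow(tb), 4)
  expect_setequal(tb$group[tb$sample_id == "s1"], "case")
  expect_true(all(tb$rna_class == "miRNA" & tb$unit == "counts"))
})

test_that("lncRNA candidate filter applies all rules with known-annotation bypass", {
  meta <- function(id, exons, len, fpkm, coding = FALSE, status = "novel") {
    tibble::tibble(feature_id = id, length_bp = len, exon_count = exons,
                   fpkm = fpkm, coding_cpc2 = coding, coding_cnci = FALSE,
                   coding_pfam = FALSE, coding_plek = FALSE,
                   annotation_status = status)
  }
  metas <- dplyr::bind_rows(
    meta("boundary_ok", 2, 201, 1.0),            # just inside every threshold
    meta("one_exon", 1, 5000, 10),               # exon rule
    meta("short", 3, 200, 5),                    # length strictly > 200
    meta("low_expr", 3, 300, 0.5),               # FPKM >= 1
    meta("coding", 2, 500, 5, coding = TRUE),    # coding-potential veto
    meta("known_coding_flag", 2, 500, 5, coding = TRUE, status = "known"),
    meta("known_low_expr", 2, 500, 0.5, status = "known")
  )
  kept <- filter_lncrna_candidates(metas)
  expect_setequal(kept, c("boundary_ok", "known_coding_flag"))

  # monotonicity: relaxing one threshold never drops a retained transcript
  relaxed <- metas
  relaxed$fpkm <- relaxed$fpkm + 1
  expect_true(all(kept %in% filter_lncrna_candidates(relaxed)))
})

test_that("target tables load typed, normalized, and deduplicated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tprovenance",
               "lncA\tmmu-miR-329-3p\tdbX",
               "lncA\tmiR-329-3p\tdbY",
               "lncA\tmiR-329-3p\tdbY"), path)
  edges <- read_target_table(path, "lnc_mi", strip_species_prefix = TRUE)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$target_id, "miR-329-3p")
  expect_equal(edges$provenance, "dbX;dbY")
  expect_error(read_target_table(path, "lnc_m"), class = "cernet_usage_error")
})

test_that("miRNA ID normalization canonicalizes case and species prefixes", {
  expect_equal(normalize_mirna_id("mmu-miR-329-3p", TRUE), "miR-329-3p")
  expect_equal(normalize_mirna_id("MIR-124-3p"), "miR-124-3p")
  expect_equal(normalize_mirna_id("mmu-miR-1a", FALSE), "mmu-miR-1a")
})

test_that("network exports round-trip nodes, edges and classes", {
  set.seed(11)
  g <- random_cerna_graph(3, 4, 3, p = 0.5)$graph
  for (fmt in c("sif", "graphml", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(g, path, fmt)
    back <- read_network(path, fmt)
    expect_setequal(network_nodes(back)$node_id, network_nodes(g)$node_id)
    key <- function(x) paste(network_edges(x)$source_id,
                             network_edges(x)$target_id,
                             network_edges(x)$edge_type)
    expect_setequal(key(back), key(g))
    nb <- network_nodes(back); ng <- network_nodes(g)
    expect_equal(nb$node_class[match(ng$node_id, nb$node_id)], ng$node_class)
  }
  # byte-stable repeated export
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_network(g, p1, "sif"); write_network(g, p2, "sif")
  expect_identical(readLines(p1), readLines(p2))
  expect_error(write_network(g, p1, "gml"), class = "cernet_usage_error")
})

test_that("a three-node path exports as two SIF lines", {
  g <- cerna_graph(
    tibble::tibble(node_id = c("L1", "I1", "M1"),
                   node_class = c("lncRNA", "miRNA", "mRNA")),
    tibble::tibble(source_id = c("L1", "I1"), target_id = c("I1", "M1"),
                   edge_type = c("lnc_mi", "mi_m"))
  )
  path <- withr::local_tempfile(fileext = ".sif")
  write_network(g, path, "sif")
  expect_length(readLines(path), 2)
})
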