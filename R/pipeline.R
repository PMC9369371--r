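# Orchestration: the per-region workflow (normalize -> screen -> intersect ->
# network -> hubs -> triads) and the cross-region core workflow ending in the
# qPCR-validated ceRNA network.

opposite_dir <- function(d) c(up = "down", down = "up")[[d]]

normalize_region <- function(region_data) {
  list(
    lncRNA = compute_tpm(region_data$matrices$lncRNA, region_data$lengths$lncRNA),
    miRNA = compute_cpm(region_data$matrices$miRNA),
    mRNA = compute_tpm(region_data$matrices$mRNA, region_data$lengths$mRNA)
  )
}

region_input <- function(data, region) {
  list(matrices = data$matrices[[region]], lengths = data$lengths,
       targets = data$targets, region = region)
}

#' Run the per-region ceRNA inference workflow
#'
#' Executes, for one brain region: TPM/CPM normalization; SDEL calling for
#' lncRNAs and mRNAs and the permissive changed screen for miRNAs and
#' mRNAs; then per regulation direction: target prediction lookup,
#' anti-correlation intersection, bipartite lncRNA-miRNA network and hub
#' miRNA selection, concordant-mRNA intersection restricted to significant
#' mRNAs, ceRNA network construction with centralities, and sign-consistent
#' triad assembly. Every filter stage's before/after counts are logged.
#'
#' @param region_data A list with `matrices` (per-class [expr_matrix]),
#'   `lengths` (named vectors for lncRNA/mRNA), `targets` (list with
#'   `lnc_mi` and `mi_m` edge tibbles), and `region`.
#' @param cfg A [screening_config()].
#' @return A list of class `region_report`: `region`, `de` (per-class
#'   tibbles), `changed` (per-class up/down sets), `directions` (per
#'   direction: retained miRNA/mRNA sets, hub miRNAs, the [cerna_graph],
#'   triads), and `log` (stage-count tibble).
#' @export
run_region <- function(region_data, cfg = screening_config()) {
  region <- region_data$region %||% region_data$matrices$lncRNA$region
  norm <- normalize_region(region_data)
  de_lnc <- call_sdels(norm$lncRNA, cfg)
  de_m <- call_sdels(norm$mRNA, cfg)
  changed_mi <- screen_changed(norm$miRNA, cfg)
  changed_m <- screen_changed(norm$mRNA, cfg)
  lnc_mi <- region_data$targets$lnc_mi
  mi_m <- region_data$targets$mi_m

  log <- list()
  note <- function(stage, direction, before, after) {
    log[[length(log) + 1]] <<- tibble(stage = stage, direction = direction,
                                      n_before = before, n_after = after)
  }

  directions <- list()
  for (d in c("up", "down")) {
    lncs <- de_lnc$feature_id[de_lnc$regulation == d]
    predicted_mi <- unique(lnc_mi$target_id[lnc_mi$source_id %in% lncs])
    mis <- anticorrelated_mirnas(predicted_mi, changed_mi$up, changed_mi$down, d)
    note("anticorrelated_mirnas", d, length(predicted_mi), length(mis))

    bip_edges <- lnc_mi[lnc_mi$source_id %in% lncs & lnc_mi$target_id %in% mis, ]
    bip <- centralities(build_bipartite(
      tibble(node_id = lncs, regulation = d), bip_edges,
      tibble(node_id = mis, regulation = opposite_dir(d))))
    hubs <- if (length(mis)) select_hub_mirnas(bip) else character()
    note("select_hub_mirnas", d, length(mis), length(hubs))

    predicted_m <- unique(mi_m$target_id[mi_m$source_id %in% hubs])
    concord <- concordant_mrnas(predicted_m, changed_m$up, changed_m$down,
                                opposite_dir(d))
    note("concordant_mrnas", d, length(predicted_m), length(concord))
    sig_m <- intersect(concord, de_m$feature_id[de_m$regulation == d])
    note("significant_mrnas", d, length(concord), length(sig_m))

    nodes <- bind_rows(
      tibble(node_id = lncs, node_class = "lncRNA", regulation = d),
      tibble(node_id = hubs, node_class = "miRNA",
             regulation = opposite_dir(d)),
      tibble(node_id = sig_m, node_class = "mRNA", regulation = d)
    )
    keep_lm <- lnc_mi[lnc_mi$source_id %in% lncs & lnc_mi$target_id %in% hubs, ]
    keep_mm <- mi_m[mi_m$source_id %in% hubs & mi_m$target_id %in% sig_m, ]
    graph <- centralities(cerna_graph(nodes, bind_rows(keep_lm, keep_mm)))
    triads <- assemble_triads(graph)
    note("assemble_triads", d,
         nrow(triads$retained) + nrow(triads$rejected), nrow(triads$retained))
    directions[[d]] <- list(lncrnas = lncs, mirnas = mis, hub_mirnas = hubs,
                            mrnas = sig_m, graph = graph, triads = triads)
  }

  structure(list(region = region,
                 de = list(lncRNA = de_lnc, mRNA = de_m),
                 changed = list(miRNA = changed_mi, mRNA = changed_m),
                 directions = directions, log = bind_rows(log)),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("<region_report> %s\n", x$region))
  n_tri <- sum(vapply(x$directions, function(d) nrow(d$triads$retained), 0L))
  cat(sprintf("  SDELs: %d up / %d down; retained triads: %d\n",
              sum(x$de$lncRNA$regulation == "up"),
              sum(x$de$lncRNA$regulation == "down"), n_tri))
  invisible(x)
}

#' All retained triads of a region report
#' @param report A `region_report`.
#' @return A tibble of retained triads across both directions.
#' @export
report_triads <- function(report) {
  bind_rows(lapply(report$directions, function(d) d$triads$retained))
}

#' Run the cross-region core workflow
#'
#' Intersects the two regions' SDEL sets into the core lncRNAs (requiring
#' consistent regulation), builds the shared lncRNA-miRNA network over
#' miRNAs changed consistently in both regions, selects hub miRNAs, keeps
#' mRNAs that are significantly and consistently differentially expressed
#' in both regions, assembles the L-M-T network and its sign-consistent
#' triads, and finally validates every network RNA with qPCR data where
#' available, dropping discordant and non-significant RNAs from the final
#' ceRNA network.
#'
#' @param data A dataset bundle as from [simulate_dataset()] (elements
#'   `matrices`, `lengths`, `targets`, and optionally `qpcr`).
#' @param cfg A [screening_config()].
#' @param qpcr_alpha Significance level for the qPCR concordance filter.
#' @return A list of class `core_report`: the per-region reports, the core
#'   lncRNA table, hub miRNAs, the L-M-T [cerna_graph], triads, the qPCR
#'   verdict table, and the final validated [cerna_graph].
#' @export
run_core <- function(data, cfg = screening_config(), qpcr_alpha = 0.05) {
  rep_cx <- run_region(region_input(data, "cortex"), cfg)
  rep_hc <- run_region(region_input(data, "hippocampus"), cfg)

  cons_lnc <- cross_region_consistency(rep_cx$de$lncRNA, rep_hc$de$lncRNA)
  core <- cons_lnc[cons_lnc$in_both & cons_lnc$status == "consistent", ]

  lnc_mi <- data$targets$lnc_mi
  mi_m <- data$targets$mi_m
  # miRNAs changed in the same direction in both regions, anti to their lncRNA
  ch_mi <- function(rep) rep$changed$miRNA
  mi_both <- list(up = intersect(ch_mi(rep_cx)$up, ch_mi(rep_hc)$up),
                  down = intersect(ch_mi(rep_cx)$down, ch_mi(rep_hc)$down))
  shared <- list()
  for (d in c("up", "down")) {
    lncs <- core$feature_id[core$regulation_region1 == d]
    predicted <- unique(lnc_mi$target_id[lnc_mi$source_id %in% lncs])
    mis <- anticorrelated_mirnas(predicted, mi_both$up, mi_both$down, d)
    shared[[d]] <- list(lncs = lncs, mis = mis)
  }
  all_lncs <- tibble(
    node_id = core$feature_id, regulation = core$regulation_region1)
  all_mis <- bind_rows(
    tibble(node_id = shared$up$mis, regulation = "down"),
    tibble(node_id = shared$down$mis, regulation = "up")) |>
    distinct(.data$node_id, .keep_all = TRUE)
  shared_edges <- lnc_mi[lnc_mi$source_id %in% all_lncs$node_id &
                           lnc_mi$target_id %in% all_mis$node_id, ]
  shared_graph <- centralities(build_bipartite(all_lncs, shared_edges, all_mis))
  hubs <- if (nrow(all_mis)) select_hub_mirnas(shared_graph) else character()

  # mRNAs: targets of hub miRNAs, significantly DE with a consistent
  # direction in both regions, anti-correlated with their miRNA
  cons_m <- cross_region_consistency(rep_cx$de$mRNA, rep_hc$de$mRNA)
  core_m <- cons_m[cons_m$in_both & cons_m$status == "consistent", ]
  predicted_m <- unique(mi_m$target_id[mi_m$source_id %in% hubs])
  mi_reg <- setNames(all_mis$regulation, all_mis$node_id)
  sig_m <- character()
  for (d in c("up", "down")) {
    hubs_d <- hubs[mi_reg[hubs] == d]
    pred_d <- unique(mi_m$target_id[mi_m$source_id %in% hubs_d])
    sig_m <- union(sig_m, intersect(
      pred_d, core_m$feature_id[core_m$regulation_region1 == opposite_dir(d)]))
  }

  m_reg <- setNames(core_m$regulation_region1, core_m$feature_id)
  lmt <- build_lmt_network(
    all_lncs, tibble(node_id = hubs, regulation = unname(mi_reg[hubs])),
    tibble(node_id = sig_m, regulation = unname(m_reg[sig_m])),
    bind_rows(lnc_mi, mi_m))
  triads <- assemble_triads(lmt)

  # qPCR validation of every RNA in the L-M-T network
  qpcr_verdicts <- tibble(gene_id = character(), rel_expr = numeric(),
                          p_value = numeric(), verdict = character())
  validated_graph <- lmt
  if (!is.null(data$qpcr) && nrow(data$qpcr)) {
    nodes <- network_nodes(lmt)
    reg_of <- setNames(nodes$regulation, nodes$node_id)
    testable <- intersect(nodes$node_id, unique(data$qpcr$gene_id))
    qpcr_verdicts <- bind_rows(lapply(testable, function(g) {
      dd <- compute_ddct(data$qpcr, g)
      tibble(gene_id = g, rel_expr = dd$rel_expr, p_value = dd$p_value,
             verdict = concordance_filter(dd, reg_of[[g]], qpcr_alpha))
    }))
    drop <- qpcr_verdicts$gene_id[qpcr_verdicts$verdict != "validated"]
    keep_nodes <- nodes[!nodes$node_id %in% drop, , drop = FALSE]
    keep_edges <- network_edges(lmt) |>
      filter(!.data$source_id %in% drop, !.data$target_id %in% drop)
    used <- unique(c(keep_edges$source_id, keep_edges$target_id))
    keep_nodes <- keep_nodes[keep_nodes$node_id %in% used, , drop = FALSE]
    validated_graph <- centralities(cerna_graph(
      keep_nodes[, c("node_id", "node_class", "regulation")], keep_edges))
  }

  structure(list(cortex = rep_cx, hippocampus = rep_hc,
                 core_lncrnas = core, hub_mirnas = hubs,
                 lmt_graph = lmt, triads = triads,
                 qpcr = qpcr_verdicts, final_graph = validated_graph),
            class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("<core_report> %d core lncRNAs, %d hub miRNAs, %d retained triads, %d validated nodes\n",
              nrow(x$core_lncrnas), length(x$hub_mirnas),
              nrow(x$triads$retained), nrow(network_nodes(x$final_graph))))
  invisible(x)
}
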