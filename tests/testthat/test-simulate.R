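test_that("generators are pure functions of the config and seed", {
  cfg <- simulation_config(seed = 23)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$matrices$cortex$lncRNA$values,
                   d2$matrices$cortex$lncRNA$values)
  expect_identical(d1$targets, d2$targets)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$qpcr, d2$qpcr)
  d3 <- simulate_dataset(simulation_config(seed = 24))
  expect_false(identical(d1$matrices$cortex$lncRNA$values,
                         d3$matrices$cortex$lncRNA$values))
})

test_that("config validation rejects malformed triad patterns", {
  expect_error(simulation_config(planted_triads = tibble::tibble(
    log2fc_lnc = 2, log2fc_mi = 2, log2fc_m = 2)), class = "cernet_usage_error")
  expect_error(simulation_config(planted_triads = tibble::tibble(
    log2fc_lnc = 0.5, log2fc_mi = -1, log2fc_m = 0.5)),
    class = "cernet_usage_error")
  expect_silent(simulation_config(planted_triads = tibble::tibble(
    log2fc_lnc = -3, log2fc_mi = 2, log2fc_m = -3)))
})

test_that("planted group means differ by the configured fold change", {
  cfg <- simulation_config(seed = 25, nb_dispersion = 1e-4)
  sim <- simulate_counts(cfg)
  pl <- sim$ground_truth$planted
  pl <- pl[pl$kind == "planted" & pl$region == "cortex" & pl$rna_class == "lncRNA", ]
  em <- sim$matrices$cortex$lncRNA
  case <- rowMeans(em$values[pl$feature_id, em$samples$group == "case", drop = FALSE])
  ctrl <- rowMeans(em$values[pl$feature_id, em$samples$group == "control", drop = FALSE])
  got <- log2_fold_change(case, ctrl, 1e-1)
  expect_equal(got, pl$true_log2fc, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("ground-truth triads are edge-consistent and sign-consistent", {
  gt <- simulate_counts(simulation_config(seed = 26))$ground_truth
  tri <- gt$triads
  ed <- gt$edges
  ekey <- paste(ed$source_id, ed$target_id)
  expect_true(all(paste(tri$lncrna_id, tri$mirna_id) %in% ekey))
  expect_true(all(paste(tri$mirna_id, tri$mrna_id) %in% ekey))
  expect_true(all(tri$lnc_regulation == tri$mrna_regulation))
  expect_true(all(tri$lnc_regulation != tri$mirna_regulation))
})

test_that("decoy edges scale linearly and never involve planted endpoints on both sides", {
  cfg0 <- simulation_config(seed = 27, decoy_edge_rate = 0)
  sim <- simulate_counts(cfg0)
  t0 <- simulate_target_tables(cfg0, sim$ground_truth)
  gt_edges <- sim$ground_truth$edges
  expect_equal(nrow(t0$lnc_mi) + nrow(t0$mi_m), nrow(gt_edges))

  n_at <- function(rate) {
    cfg <- simulation_config(seed = 27, decoy_edge_rate = rate)
    tt <- simulate_target_tables(cfg, sim$ground_truth)
    nrow(tt$lnc_mi) + nrow(tt$mi_m)
  }
  base <- n_at(0)
  d1 <- n_at(0.1) - base; d2 <- n_at(0.2) - base; d4 <- n_at(0.4) - base
  expect_equal(d2 / d1, 2, tolerance = 0.1)
  expect_equal(d4 / d1, 4, tolerance = 0.1)

  # decoy mi_m edges never start from a planted miRNA
  cfg <- simulation_config(seed = 27)
  tt <- simulate_target_tables(cfg, sim$ground_truth)
  decoy_mm <- tt$mi_m[grepl("decoy", tt$mi_m$provenance) &
                        !grepl("planted", tt$mi_m$provenance), ]
  planted_mi <- unique(sim$ground_truth$triads$mirna_id)
  expect_length(intersect(decoy_mm$source_id, planted_mi), 0)
})

test_that("planted seed sites are recovered exactly and background is clean", {
  cfg <- simulation_config(seed = 28)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(sim$ground_truth, cfg)
  sites <- seqs$sites
  expect_gt(nrow(sites), 0)
  for (i in seq_len(nrow(sites))) {
    got <- find_seed_sites(seqs$mirna_seqs[[sites$mirna_id[i]]],
                           seqs$transcript_seqs[[sites$transcript_id[i]]],
                           sites$transcript_id[i], sites$mirna_id[i])
    hit <- got[got$start == sites$start[i] & got$site_type == "8mer", ]
    expect_equal(nrow(hit), 1)
  }

  # non-edge pairs: site count consistent with the uniform-background rate
  set.seed(29)
  ed <- sim$ground_truth$edges
  mirs <- names(seqs$mirna_seqs); txs <- names(seqs$transcript_seqs)
  ekey <- c(paste(ed$source_id, ed$target_id), paste(ed$target_id, ed$source_id))
  n_pairs <- 0; n_sites <- 0
  for (mi in mirs) for (tx in txs) {
    if (paste(tx, mi) %in% ekey) next
    n_pairs <- n_pairs + 1
    n_sites <- n_sites + nrow(find_seed_sites(seqs$mirna_seqs[[mi]],
                                              seqs$transcript_seqs[[tx]]))
  }
  # expected 6mer-core hits per pair: (L - 5) / 4^6
  L <- nchar(seqs$transcript_seqs[[1]])
  expected <- n_pairs * (L - 5) / 4^6
  expect_lt(abs(n_sites - expected), 3 * sqrt(expected) + 3)

  # empty ground truth: background-only output
  cfg0 <- simulation_config(seed = 30, planted_triads = tibble::tibble(
    log2fc_lnc = numeric(), log2fc_mi = numeric(), log2fc_m = numeric()))
  sim0 <- simulate_counts(cfg0)
  seqs0 <- simulate_sequences(sim0$ground_truth, cfg0)
  expect_equal(nrow(seqs0$sites), 0)
  expect_length(seqs0$mirna_seqs, 0)
})

test_that("a planted 16-fold lncRNA is recovered as an SDEL almost surely", {
  hits <- vapply(1:40, function(s) {
    cfg <- simulation_config(
      seed = 400 + s,
      planted_triads = tibble::tibble(log2fc_lnc = 4, log2fc_mi = -2,
                                      log2fc_m = 4),
      n_lnc = 150, n_mi = 50, n_m = 100)
    sim <- simulate_counts(cfg)
    de <- call_sdels(compute_tpm(sim$matrices$cortex$lncRNA,
                                 sim$lengths$lncRNA))
    pl <- sim$ground_truth$planted
    id <- pl$feature_id[pl$rna_class == "lncRNA" & pl$kind == "planted" &
                          pl$region == "cortex"][1]
    de$regulation[de$feature_id == id] == "up"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("region-discordant lncRNAs flip direction only in the hippocampus", {
  cfg <- simulation_config(seed = 31, discordant_lnc = 2)
  sim <- simulate_counts(cfg)
  pl <- sim$ground_truth$planted
  pl <- pl[pl$rna_class == "lncRNA" & pl$kind == "planted", ]
  cx <- pl[pl$region == "cortex", ]; hc <- pl[pl$region == "hippocampus", ]
  dirs <- dplyr::inner_join(cx, hc, by = "feature_id")
  expect_equal(sum(dirs$direction.x != dirs$direction.y), 2)
})
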