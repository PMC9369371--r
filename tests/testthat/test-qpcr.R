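qpcr_rows <- function(gene, case_ct, ctrl_ct, case_ref = 18, ctrl_ref = 18,
                      ref_id = "GAPDH") {
  n <- length(case_ct)
  tibble::tibble(
    sample_id = c(paste0("case_", seq_len(n)), paste0("ctrl_", seq_along(ctrl_ct))),
    group = c(rep("case", n), rep("control", length(ctrl_ct))),
    gene_id = gene,
    ct = c(case_ct, ctrl_ct),
    reference_id = ref_id,
    reference_ct = c(rep(case_ref, n), rep(ctrl_ref, length(ctrl_ct))))
}

test_that("ddCt quantification matches hand calculations", {
  # case dCt = 2, control dCt = 6 -> ddCt = -4, 16-fold up
  tab <- qpcr_rows("g", rep(20, 4), rep(24, 4))
  res <- compute_ddct(tab, "g")
  expect_equal(res$ddct, -4)
  expect_equal(res$rel_expr, 16)
  expect_equal(res$fold_direction, "up")

  # label swap inverts the fold
  swapped <- tab
  swapped$group <- rev(swapped$group)
  res2 <- compute_ddct(swapped, "g")
  expect_equal(res2$rel_expr, 1 / 16)
  expect_equal(res2$fold_direction, "down")

  # no difference
  flat <- qpcr_rows("g", rep(22, 4), rep(22, 4))
  res3 <- compute_ddct(flat, "g")
  expect_equal(res3$rel_expr, 1)
  expect_equal(res3$fold_direction, "unchanged")
})

test_that("ddCt is invariant to per-sample constant shifts", {
  set.seed(17)
  tab <- qpcr_rows("g", 20 + rnorm(4, 0, 0.2), 23 + rnorm(4, 0, 0.2))
  base <- compute_ddct(tab, "g")
  shift <- runif(nrow(tab), -2, 2)  # e.g. loading differences
  tab2 <- tab
  tab2$ct <- tab2$ct + shift
  tab2$reference_ct <- tab2$reference_ct + shift
  expect_equal(compute_ddct(tab2, "g")$rel_expr, base$rel_expr)
})

test_that("qPCR table validation catches structural errors", {
  tab <- qpcr_rows("g", rep(20, 4), rep(24, 4))
  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(compute_ddct(dup, "g"), class = "cernet_validation_error")
  small <- tab[c(1, 2, 5, 6, 7, 8), ]
  expect_error(compute_ddct(small, "g"), class = "cernet_usage_error")
  miss <- tab
  miss$reference_ct[2] <- NA
  expect_error(compute_ddct(miss, "g"), class = "cernet_validation_error")
})

test_that("exact Mann-Whitney matches assignment enumeration", {
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mann_whitney_p(5:8, 1:4), 2 / 70)

  set.seed(18)
  for (i in 1:25) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- sample(1:6, n, replace = TRUE)  # coarse values force ties
    y <- sample(1:6, m, replace = TRUE)
    expect_equal(mann_whitney_p(x, y), oracle_mw(x, y), tolerance = 1e-12)
  }
  # tie-free case agrees with the reference exact implementation
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(4)
    expect_equal(mann_whitney_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney p is invariant to monotone transforms", {
  set.seed(19)
  x <- runif(5, 1, 10); y <- runif(6, 1, 10)
  p <- mann_whitney_p(x, y)
  expect_equal(mann_whitney_p(log(x), log(y)), p)
  expect_equal(mann_whitney_p(x^3, y^3), p)
})

test_that("concordance filter applies direction and significance rules", {
  up_sig <- compute_ddct(qpcr_rows("g", rep(20, 4), rep(24, 4)), "g")
  expect_equal(up_sig$p_value, 2 / 70)
  expect_equal(concordance_filter(up_sig, "up"), "validated")
  expect_equal(concordance_filter(up_sig, "down"), "discordant")

  set.seed(20)
  flat <- compute_ddct(qpcr_rows("g", 22 + rnorm(4, 0, .5), 22 + rnorm(4, 0, .5)), "g")
  expect_equal(concordance_filter(flat, "up"), "not_significant")
})

test_that("planted qPCR effects are recovered through the generator", {
  cfg <- simulation_config(seed = 21, qpcr_ct_sd = 0)
  sim <- simulate_counts(cfg)
  q <- simulate_qpcr(sim$ground_truth, cfg)
  # noise-free: relative expression equals the planted fold exactly
  pl <- sim$ground_truth$planted
  gene16 <- pl$feature_id[pl$rna_class == "mRNA" & pl$true_log2fc == 4][1]
  res <- compute_ddct(q$table, gene16)
  expect_equal(res$rel_expr, 16)

  # with default noise, verdicts recover the planted status
  cfg2 <- simulation_config(seed = 22)
  sim2 <- simulate_counts(cfg2)
  lncs <- unique(sim2$ground_truth$triads$lncrna_id)
  q2 <- simulate_qpcr(sim2$ground_truth, cfg2,
                      discordant = lncs[1], unchanged = lncs[2])
  verdicts <- vapply(q2$truth$gene_id, function(g) {
    concordance_filter(compute_ddct(q2$table, g),
                       q2$truth$seq_direction[q2$truth$gene_id == g])
  }, "")
  agree <- mean(verdicts == q2$truth$expected_verdict)
  expect_gte(agree, 0.95)
})
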