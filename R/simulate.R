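# Seeded generators for every input the pipeline consumes, with ground-truth
# bookkeeping. The defaults emulate the study design: 3-vs-3 bulk RNA-seq of
# two brain regions, negative-binomial counts with biological CV ~0.1,
# sponge modules whose lncRNA/mRNA fold changes match the magnitudes seen in
# the published SDEL tables, prediction tables with decoys, transcripts with
# embedded seed sites, and a 4-vs-4 qPCR panel. The dispersion default (CV
# ~7%) reflects the very low within-group variability the published q-values
# imply for a 3-vs-3 design.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

default_planted_triads <- function() {
  bind_rows(
    tibble(log2fc_lnc = 8, log2fc_mi = -2, log2fc_m = 4)[rep(1, 6), ],
    tibble(log2fc_lnc = -8, log2fc_mi = 2, log2fc_m = -4)[rep(1, 6), ]
  )
}

#' Simulation settings
#'
#' All knobs of the synthetic-data generators. Defaults are the study
#' conditions: three samples per group, negative-binomial counts with
#' dispersion 0.01 (biological CV about 10%, typical for isogenic mouse
#' bulk RNA-seq), twelve planted sponge triads in two sign-pattern modules
#' with lncRNA/mRNA effect magnitudes in the published tables' range, a 20%
#' decoy-edge rate, 2% expression dropout, and 0.25-cycle qPCR noise.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   config including this seed.
#' @param n_lnc,n_mi,n_m Feature counts per RNA class.
#' @param samples_per_group Samples per group per region.
#' @param nb_mean_log_range Natural-log range of baseline mean counts.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param planted_triads Tibble with `log2fc_lnc`, `log2fc_mi`, `log2fc_m`;
#'   each row's signs must follow the ceRNA pattern (+,-,+) or (-,+,-) with
#'   magnitudes >= 1.
#' @param decoy_edge_rate Decoy prediction edges per feature of the
#'   downstream layer.
#' @param dropout_rate Fraction of unplanted features silenced (counts set
#'   to zero) in one randomly chosen group - the regime printed as 0.0001
#'   in the published tables.
#' @param qpcr_samples_per_group Samples per group in the qPCR panel.
#' @param qpcr_ct_sd Gaussian SD of Ct noise, in cycles.
#' @param discordant_lnc Number of planted lncRNAs whose effect direction is
#'   flipped in the hippocampus (0 = regions fully consistent).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_lnc = 300, n_mi = 200, n_m = 500,
                              samples_per_group = 3,
                              nb_mean_log_range = log(c(10, 1000)),
                              nb_dispersion = 0.005,
                              planted_triads = default_planted_triads(),
                              decoy_edge_rate = 0.2, dropout_rate = 0.02,
                              qpcr_samples_per_group = 4, qpcr_ct_sd = 0.25,
                              discordant_lnc = 0) {
  planted_triads <- as_tibble(planted_triads)
  stopifnot(n_lnc > 0, n_mi > 0, n_m > 0, samples_per_group >= 2,
            nb_dispersion > 0, decoy_edge_rate >= 0, dropout_rate >= 0,
            qpcr_ct_sd >= 0)
  if (nrow(planted_triads)) {
    ok <- with(planted_triads,
               abs(log2fc_lnc) >= 1 & abs(log2fc_mi) >= 1 & abs(log2fc_m) >= 1 &
                 sign(log2fc_lnc) == sign(log2fc_m) &
                 sign(log2fc_mi) == -sign(log2fc_lnc))
    if (!all(ok)) {
      stop_usage("planted triads must follow the (+,-,+)/(-,+,-) sign pattern with |log2fc| >= 1")
    }
  }
  structure(list(seed = as.integer(seed), n_lnc = n_lnc, n_mi = n_mi, n_m = n_m,
                 samples_per_group = samples_per_group,
                 nb_mean_log_range = nb_mean_log_range,
                 nb_dispersion = nb_dispersion, planted_triads = planted_triads,
                 decoy_edge_rate = decoy_edge_rate, dropout_rate = dropout_rate,
                 qpcr_samples_per_group = qpcr_samples_per_group,
                 qpcr_ct_sd = qpcr_ct_sd, discordant_lnc = discordant_lnc),
            class = "simulation_config")
}

# Allocate planted triads to features. Triads sharing a sign pattern form a
# sponge module: each entry gets its own lncRNA and mRNA, miRNAs come from a
# shared pool (half the module size), and the lncRNA-miRNA layer is completed
# within the module - sponges bind many miRNAs, which is also what gives hub
# miRNAs their degree. Ground-truth triads are ALL sign-consistent triples
# induced by the planted edges.
plan_modules <- function(cfg) {
  pt <- cfg$planted_triads
  if (nrow(pt) == 0) {
    return(list(features = tibble(rna_class = character(), feature_id = character(),
                                  log2fc = numeric()),
                edges = tibble(source_id = character(), target_id = character(),
                               edge_type = character(), provenance = character()),
                triads = tibble()))
  }
  pt$pattern <- ifelse(pt$log2fc_lnc > 0, "up", "down")
  feats <- list(); edges <- list()
  counters <- c(lnc = 0L, mi = 0L, m = 0L)
  for (pat in unique(pt$pattern)) {
    rows <- pt[pt$pattern == pat, , drop = FALSE]
    k <- nrow(rows)
    pool <- max(1L, k %/% 2L)
    lnc_ids <- sprintf("lnc_%04d", counters["lnc"] + seq_len(k))
    m_ids <- sprintf("mrna_%04d", counters["m"] + seq_len(k))
    mi_ids <- sprintf("miR-sim-%03d", counters["mi"] + seq_len(pool))
    counters <- counters + c(lnc = k, mi = pool, m = k)
    mi_of <- mi_ids[(seq_len(k) - 1L) %% pool + 1L]
    feats[[pat]] <- bind_rows(
      tibble(rna_class = "lncRNA", feature_id = lnc_ids, log2fc = rows$log2fc_lnc),
      tibble(rna_class = "miRNA", feature_id = mi_ids,
             log2fc = rows$log2fc_mi[match(mi_ids, mi_of)]),
      tibble(rna_class = "mRNA", feature_id = m_ids, log2fc = rows$log2fc_m)
    )
    edges[[pat]] <- bind_rows(
      tidyr::expand_grid(source_id = lnc_ids, target_id = mi_ids) |>
        mutate(edge_type = "lnc_mi"),
      tibble(source_id = mi_of, target_id = m_ids, edge_type = "mi_m")
    )
  }
  features <- bind_rows(feats)
  edges <- distinct(bind_rows(edges)) |> mutate(provenance = "planted_db")
  reg <- setNames(ifelse(features$log2fc > 0, "up", "down"), features$feature_id)
  lm <- edges[edges$edge_type == "lnc_mi", ]
  mm <- edges[edges$edge_type == "mi_m", ]
  triads <- inner_join(
    lm |> select(lncrna_id = "source_id", mirna_id = "target_id"),
    mm |> select(mirna_id = "source_id", mrna_id = "target_id"),
    by = "mirna_id", relationship = "many-to-many") |>
    mutate(lnc_regulation = unname(reg[.data$lncrna_id]),
           mirna_regulation = unname(reg[.data$mirna_id]),
           mrna_regulation = unname(reg[.data$mrna_id])) |>
    filter(.data$lnc_regulation == .data$mrna_regulation,
           .data$lnc_regulation != .data$mirna_regulation) |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  list(features = features, edges = edges, triads = triads)
}

simulate_class_counts <- function(ids, planted, base_mean, cfg, flip = character()) {
  n <- length(ids)
  spg <- cfg$samples_per_group
  mu_case <- mu_ctrl <- base_mean
  if (nrow(planted)) {
    idx <- match(planted$feature_id, ids)
    lfc <- planted$log2fc
    lfc[planted$feature_id %in% flip] <- -lfc[planted$feature_id %in% flip]
    # the detectable (high) side keeps the drawn planted mean
    mu_case[idx] <- ifelse(lfc > 0, planted$high_mean,
                           planted$high_mean / 2^abs(lfc))
    mu_ctrl[idx] <- ifelse(lfc > 0, planted$high_mean / 2^abs(lfc),
                           planted$high_mean)
  }
  size <- 1 / cfg$nb_dispersion
  draw <- function(mu) {
    matrix(rnbinom(n * spg, mu = rep(mu, spg), size = size), nrow = n)
  }
  vals <- cbind(draw(mu_case), draw(mu_ctrl))
  # dropout: silence a random unplanted subset in one random group
  free <- setdiff(seq_len(n), match(planted$feature_id, ids))
  n_drop <- round(cfg$dropout_rate * length(free))
  dropped <- tibble(feature_id = character(), direction = character())
  if (n_drop > 0) {
    di <- sample(free, n_drop)
    zero_case <- sample(c(TRUE, FALSE), n_drop, replace = TRUE)
    vals[di[zero_case], seq_len(spg)] <- 0L
    vals[di[!zero_case], spg + seq_len(spg)] <- 0L
    dropped <- tibble(feature_id = ids[di],
                      direction = ifelse(zero_case, "down", "up"))
  }
  rownames(vals) <- ids
  colnames(vals) <- c(paste0("case_", seq_len(spg)), paste0("control_", seq_len(spg)))
  list(values = vals, dropped = dropped)
}

#' Simulate negative-binomial count matrices for both regions
#'
#' Draws baseline mean expression per feature (log-uniform), plants the
#' configured sponge-module fold changes on top, adds dropout features
#' (silenced in one group), and samples negative-binomial counts for a
#' 3-vs-3 design in each region. Planted effects are identical in both
#' regions unless `discordant_lnc` requests flipped lncRNAs in the
#' hippocampus.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `matrices` (per region, per RNA class [expr_matrix]
#'   objects), `lengths` (named length vectors for lncRNA and mRNA), and
#'   `ground_truth` (planted features per region, induced triads, planted
#'   edges).
#' @export
simulate_counts <- function(cfg) {
  plan <- plan_modules(cfg)
  with_seed(cfg$seed, {
    ids <- list(
      lncRNA = sprintf("lnc_%04d", seq_len(cfg$n_lnc)),
      miRNA = sprintf("miR-sim-%03d", seq_len(cfg$n_mi)),
      mRNA = sprintf("mrna_%04d", seq_len(cfg$n_m))
    )
    lengths <- list(
      lncRNA = setNames(round(runif(cfg$n_lnc, 300, 3000)), ids$lncRNA),
      mRNA = setNames(round(runif(cfg$n_m, 500, 5000)), ids$mRNA)
    )
    base <- lapply(ids, function(v) {
      exp(runif(length(v), cfg$nb_mean_log_range[1], cfg$nb_mean_log_range[2]))
    })
    planted <- plan$features |>
      mutate(high_mean = runif(dplyr::n(), 200, 1000))
    flip <- character()
    if (cfg$discordant_lnc > 0) {
      lncs <- planted$feature_id[planted$rna_class == "lncRNA"]
      flip <- head(lncs, cfg$discordant_lnc)
    }
    matrices <- list(); truth <- list()
    for (region in c("cortex", "hippocampus")) {
      reg_flip <- if (region == "hippocampus") flip else character()
      for (cls in c("lncRNA", "miRNA", "mRNA")) {
        pl <- planted[planted$rna_class == cls, , drop = FALSE]
        sim <- simulate_class_counts(ids[[cls]], pl, base[[cls]], cfg, reg_flip)
        grp <- c(rep("case", cfg$samples_per_group),
                 rep("control", cfg$samples_per_group))
        matrices[[region]][[cls]] <- expr_matrix(
          sim$values, setNames(grp, colnames(sim$values)), cls, region)
        lfc <- pl$log2fc
        lfc[pl$feature_id %in% reg_flip] <- -lfc[pl$feature_id %in% reg_flip]
        truth[[paste(region, cls)]] <- bind_rows(
          tibble(region = region, rna_class = cls, feature_id = pl$feature_id,
                 true_log2fc = lfc,
                 direction = as.character(ifelse(lfc > 0, "up", "down")),
                 kind = "planted"),
          if (nrow(sim$dropped)) {
            tibble(region = region, rna_class = cls,
                   feature_id = sim$dropped$feature_id, true_log2fc = NA_real_,
                   direction = sim$dropped$direction, kind = "dropout")
          }
        )
      }
    }
    list(matrices = matrices, lengths = lengths,
         ground_truth = list(planted = bind_rows(truth), triads = plan$triads,
                             edges = plan$edges))
  })
}

#' Simulate target-prediction tables with decoys
#'
#' Emits the planted module edges plus decoy predictions. Decoy
#' lncRNA-miRNA edges either attach unplanted miRNAs to planted lncRNAs
#' (sponges predict many partners - this is what gives the hub-degree
#' distribution its long tail of degree-1 miRNAs) or connect unplanted
#' lncRNAs; decoy miRNA-mRNA edges point from unplanted miRNAs to unplanted
#' mRNAs. By construction no decoy can complete a sign-consistent triad of
#' planted features.
#'
#' @param cfg A [simulation_config()].
#' @param ground_truth The `ground_truth` element of [simulate_counts()].
#' @return A list with edge tibbles `lnc_mi` and `mi_m`.
#' @export
simulate_target_tables <- function(cfg, ground_truth) {
  planted_edges <- ground_truth$edges
  pl <- ground_truth$planted[ground_truth$planted$kind == "planted", ]
  planted_ids <- lapply(split(pl$feature_id, pl$rna_class), unique)
  with_seed(cfg$seed + 1L, {
    all_lnc <- sprintf("lnc_%04d", seq_len(cfg$n_lnc))
    all_mi <- sprintf("miR-sim-%03d", seq_len(cfg$n_mi))
    all_m <- sprintf("mrna_%04d", seq_len(cfg$n_m))
    free_lnc <- setdiff(all_lnc, planted_ids$lncRNA)
    free_mi <- setdiff(all_mi, planted_ids$miRNA)
    free_m <- setdiff(all_m, planted_ids$mRNA)
    # sponge decoys: planted lncRNAs predict many miRNA partners (scaled with
    # the miRNA pool, spread evenly so every sponge gets its share); plus
    # background decoys among unplanted lncRNAs
    n_sponge <- round(cfg$decoy_edge_rate * cfg$n_mi)
    n_bg <- round(cfg$decoy_edge_rate * cfg$n_lnc)
    n_mm <- round(cfg$decoy_edge_rate * cfg$n_m)
    decoy_lm <- bind_rows(
      if (n_sponge > 0 && length(planted_ids$lncRNA)) {
        tibble(source_id = rep_len(planted_ids$lncRNA, n_sponge),
               target_id = sample(free_mi, n_sponge))
      },
      if (n_bg > 0) {
        tibble(source_id = sample(free_lnc, n_bg, replace = TRUE),
               target_id = sample(free_mi, n_bg, replace = TRUE))
      }
    )
    decoy_mm <- if (n_mm > 0) {
      tibble(source_id = sample(free_mi, n_mm, replace = TRUE),
             target_id = sample(free_m, n_mm, replace = TRUE))
    }
    lm <- bind_rows(
      planted_edges[planted_edges$edge_type == "lnc_mi", ],
      if (!is.null(decoy_lm) && nrow(decoy_lm)) {
        mutate(decoy_lm, edge_type = "lnc_mi", provenance = "decoy_db")
      }
    )
    mm <- bind_rows(
      planted_edges[planted_edges$edge_type == "mi_m", ],
      if (!is.null(decoy_mm) && nrow(decoy_mm)) {
        mutate(decoy_mm, edge_type = "mi_m", provenance = "decoy_db")
      }
    )
    list(lnc_mi = merge_predictions(list(lm)), mi_m = merge_predictions(list(mm)))
  })
}

#' Simulate miRNA and transcript sequences with embedded seed sites
#'
#' Background transcript sequence is i.i.d. uniform; each planted edge gets
#' one embedded 8mer seed site at a recorded position (on the lncRNA for
#' lnc_mi edges, on the mRNA for mi_m edges).
#'
#' @param ground_truth The `ground_truth` element of [simulate_counts()].
#' @param cfg A [simulation_config()].
#' @param transcript_length Length of each simulated transcript.
#' @return A list: `mirna_seqs`, `transcript_seqs` (named character
#'   vectors), `sites` (tibble of planted site coordinates, 0-based
#'   half-open).
#' @export
simulate_sequences <- function(ground_truth, cfg, transcript_length = 500) {
  edges <- ground_truth$edges
  with_seed(cfg$seed + 2L, {
    rand_seq <- function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }
    mirs <- sort(unique(c(edges$target_id[edges$edge_type == "lnc_mi"],
                          edges$source_id[edges$edge_type == "mi_m"])))
    mirna_seqs <- setNames(vapply(mirs, function(i) rand_seq(22), ""), mirs)
    txs <- sort(unique(c(edges$source_id[edges$edge_type == "lnc_mi"],
                         edges$target_id[edges$edge_type == "mi_m"])))
    transcript_seqs <- setNames(
      vapply(txs, function(i) rand_seq(transcript_length), ""), txs)
    sites <- list()
    used <- setNames(vector("list", length(txs)), txs)  # occupied intervals
    if (nrow(edges)) {
      for (i in seq_len(nrow(edges))) {
        tx_id <- if (edges$edge_type[i] == "lnc_mi") edges$source_id[i] else edges$target_id[i]
        mi_id <- if (edges$edge_type[i] == "lnc_mi") edges$target_id[i] else edges$source_id[i]
        mir <- mirna_seqs[[mi_id]]
        site <- paste0(revcomp(substr(mir, 2, 8)), "A")  # 8mer, 8 nt
        # non-overlapping insert position (1 nt clearance so sites stay intact)
        repeat {
          pos <- sample.int(transcript_length - 9L, 1) + 1L  # 1-based start
          clear <- all(vapply(used[[tx_id]], function(iv) {
            pos + 8L < iv[1] || pos > iv[2] + 1L
          }, TRUE))
          if (clear) break
        }
        used[[tx_id]] <- c(used[[tx_id]], list(c(pos, pos + 7L)))
        seqv <- transcript_seqs[[tx_id]]
        substr(seqv, pos, pos + 7L) <- site
        transcript_seqs[[tx_id]] <- seqv
        sites[[i]] <- tibble(transcript_id = tx_id, mirna_id = mi_id,
                             start = pos - 1L, end = pos + 7L,
                             site_type = "8mer")
      }
    }
    list(mirna_seqs = mirna_seqs, transcript_seqs = transcript_seqs,
         sites = bind_rows(sites))
  })
}

#' Simulate a qPCR validation panel
#'
#' Generates Ct values for the distinct RNAs of the planted triads under the
#' inverse of the 2^-ddCt model: Ct = baseline - log2(expression) + Gaussian
#' noise. Reference genes (GAPDH for lncRNA/mRNA, U6 for miRNA) are constant
#' across groups up to noise. Selected genes can be flipped (discordant with
#' RNA-seq) or flattened (no group effect) to exercise the concordance
#' filter.
#'
#' @param ground_truth The `ground_truth` element of [simulate_counts()].
#' @param cfg A [simulation_config()].
#' @param discordant Gene IDs simulated with the opposite direction.
#' @param unchanged Gene IDs simulated with no group difference.
#' @return A list: `table` (qPCR tibble for [compute_ddct()]) and `truth`
#'   (per-gene planted qPCR direction and expected verdict).
#' @export
simulate_qpcr <- function(ground_truth, cfg, discordant = character(),
                          unchanged = character()) {
  pl <- ground_truth$planted
  pl <- pl[pl$kind == "planted" & pl$region == "cortex", , drop = FALSE]
  if (nrow(pl) == 0) stop_usage("no planted features to validate")
  with_seed(cfg$seed + 3L, {
    spg <- cfg$qpcr_samples_per_group
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(pl))) {
      gene <- pl$feature_id[i]
      lfc <- pl$true_log2fc[i]
      if (gene %in% discordant) lfc <- -lfc
      if (gene %in% unchanged) lfc <- 0
      ref <- if (pl$rna_class[i] == "miRNA") "U6" else "GAPDH"
      base_expr <- 2^6
      expr <- c(rep(base_expr * 2^lfc, spg), rep(base_expr, spg))
      noise <- rnorm(2 * spg, 0, cfg$qpcr_ct_sd)
      ref_noise <- rnorm(2 * spg, 0, cfg$qpcr_ct_sd)
      rows[[gene]] <- tibble(
        sample_id = c(paste0("case_", seq_len(spg)), paste0("control_", seq_len(spg))),
        group = c(rep("case", spg), rep("control", spg)),
        gene_id = gene,
        ct = 30 - log2(expr) + noise,
        reference_id = ref,
        reference_ct = 18 + ref_noise
      )
      verdict <- if (gene %in% unchanged) "not_significant"
                 else if (gene %in% discordant) "discordant" else "validated"
      truth[[gene]] <- tibble(
        gene_id = gene, seq_direction = pl$direction[i],
        qpcr_log2fc = lfc, expected_verdict = verdict)
    }
    list(table = bind_rows(rows), truth = bind_rows(truth))
  })
}

#' Simulate a complete input bundle
#'
#' Convenience wrapper running all generators with one config: counts and
#' lengths for both regions, target tables with decoys, sequences with
#' planted seed sites, the qPCR panel, and the combined ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `matrices`, `lengths`, `targets`, `sequences`,
#'   `qpcr`, and `ground_truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  counts <- simulate_counts(cfg)
  targets <- simulate_target_tables(cfg, counts$ground_truth)
  seqs <- simulate_sequences(counts$ground_truth, cfg)
  qpcr <- if (nrow(cfg$planted_triads)) simulate_qpcr(counts$ground_truth, cfg)
  gt <- counts$ground_truth
  gt$seed_sites <- seqs$sites
  gt$qpcr <- qpcr$truth %||% tibble()
  list(matrices = counts$matrices, lengths = counts$lengths, targets = targets,
       sequences = seqs, qpcr = qpcr$table %||% tibble(), ground_truth = gt)
}
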