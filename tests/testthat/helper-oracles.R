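# Independent oracles used to cross-check the package implementations.
# Deliberately written with different algorithms than the implementation
# (matrix DP instead of Brandes, explicit enumeration instead of closed
# forms) so agreement is informative.

# all-pairs shortest-path distances and path counts by DP over path length
oracle_apsp <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  reach <- diag(1, n)  # paths of current length
  for (len in seq_len(n - 1)) {
    reach <- reach %*% adj
    newly <- is.infinite(dist) & reach > 0
    dist[newly] <- len
    sigma[newly] <- reach[newly]
  }
  list(dist = dist, sigma = sigma)
}

# Cytoscape-convention centralities from the DP tables
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  ap <- oracle_apsp(adj)
  d <- ap$dist; sig <- ap$sigma
  degree <- rowSums(adj)
  closeness <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (!length(reach)) return(0)
    length(reach) / sum(d[v, reach])
  }, 0)
  betweenness <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t]) || sig[s, t] == 0) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
    if (n > 2) tot / ((n - 1) * (n - 2) / 2) else 0
  }, 0)
  list(degree = degree, closeness = closeness, betweenness = betweenness)
}

# random typed tripartite graph as a cerna_graph plus its adjacency matrix
random_cerna_graph <- function(n_lnc, n_mi, n_m, p = 0.4) {
  nodes <- tibble::tibble(
    node_id = c(sprintf("L%02d", seq_len(n_lnc)), sprintf("I%02d", seq_len(n_mi)),
                sprintf("M%02d", seq_len(n_m))),
    node_class = rep(c("lncRNA", "miRNA", "mRNA"), c(n_lnc, n_mi, n_m)),
    regulation = sample(c("up", "down"), n_lnc + n_mi + n_m, replace = TRUE)
  )
  pairs <- rbind(
    expand.grid(s = seq_len(n_lnc), t = n_lnc + seq_len(n_mi), type = "lnc_mi",
                stringsAsFactors = FALSE),
    expand.grid(s = n_lnc + seq_len(n_mi), t = n_lnc + n_mi + seq_len(n_m),
                type = "mi_m", stringsAsFactors = FALSE)
  )
  pairs <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  edges <- tibble::tibble(source_id = nodes$node_id[pairs$s],
                          target_id = nodes$node_id[pairs$t],
                          edge_type = pairs$type, provenance = "sim")
  g <- cerna_graph(nodes, edges)
  n <- nrow(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes$node_id, nodes$node_id))
  if (nrow(edges)) {
    adj[cbind(edges$source_id, edges$target_id)] <- 1
    adj[cbind(edges$target_id, edges$source_id)] <- 1
  }
  list(graph = g, adj = adj)
}

# position-by-position seed-site scan, strongest type per core occurrence
oracle_seed_sites <- function(mirna_seq, transcript_seq) {
  norm <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  mir <- norm(mirna_seq); tx <- norm(transcript_seq)
  core <- rc(substr(mir, 2, 7))
  m8c <- rc(substr(mir, 8, 8))
  hits <- list()
  for (s in seq_len(max(nchar(tx) - 5, 0))) {
    if (substr(tx, s, s + 5) != core) next
    has_m8 <- s > 1 && substr(tx, s - 1, s - 1) == m8c
    has_a1 <- s + 6 <= nchar(tx) && substr(tx, s + 6, s + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    st <- s - 1 - has_m8
    en <- s + 5 + has_a1
    hits[[length(hits) + 1]] <- data.frame(start = st, end = en,
                                           site_type = type)
  }
  do.call(rbind, hits)
}

# exact hypergeometric upper tail by direct enumeration
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# exact two-sided Mann-Whitney p by enumerating assignments, with U computed
# from pairwise comparisons (not ranks)
oracle_mw <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); m <- length(y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
}

# brute-force triad enumeration over all node triples
oracle_triads <- function(graph) {
  nodes <- network_nodes(graph)
  edges <- network_edges(graph)
  has_edge <- function(a, b) {
    any((edges$source_id == a & edges$target_id == b) |
          (edges$source_id == b & edges$target_id == a))
  }
  lncs <- nodes[nodes$node_class == "lncRNA", ]
  mis <- nodes[nodes$node_class == "miRNA", ]
  ms <- nodes[nodes$node_class == "mRNA", ]
  out <- list()
  for (i in seq_len(nrow(lncs))) for (j in seq_len(nrow(mis)))
    for (k in seq_len(nrow(ms))) {
      if (!has_edge(lncs$node_id[i], mis$node_id[j])) next
      if (!has_edge(mis$node_id[j], ms$node_id[k])) next
      if (is.na(lncs$regulation[i]) || is.na(mis$regulation[j]) ||
          is.na(ms$regulation[k])) next
      if (lncs$regulation[i] != ms$regulation[k]) next
      if (lncs$regulation[i] == mis$regulation[j]) next
      out[[length(out) + 1]] <- paste(lncs$node_id[i], mis$node_id[j],
                                      ms$node_id[k])
    }
  sort(as.character(unlist(out)))
}

# Benjamini-Hochberg step-up, written from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small count matrix builder for normalization tests
toy_matrix <- function(values, rna_class = "mRNA", region = "cortex") {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  # first half case, second half control
  grp <- setNames(rep(c("case", "control"), each = ceiling(ncol(m) / 2))[
    seq_len(ncol(m))], colnames(m))
  expr_matrix(m, grp, rna_class, region)
}
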