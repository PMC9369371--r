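# Hypergeometric overrepresentation analysis over a user-supplied annotation.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X is the number of annotated genes drawn when `n` genes
#' are sampled without replacement from a background of `N` genes of which
#' `K` carry the annotation.
#'
#' @param k Observed overlap (query genes carrying the term).
#' @param K Background genes carrying the term.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10) # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0)) {
    stop_usage("impossible hypergeometric configuration")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation analysis of a gene set
#'
#' Tests each annotation term with at least one query gene for enrichment of
#' the query against the background, BH-adjusts over the tested terms, and
#' sorts by p-value then term ID. Significance is declared at `p_threshold`
#' on the raw p-value.
#'
#' @param query Character vector of query gene IDs (subset of background).
#' @param annotation Tibble with columns `term_id`, `term_name`, `category`
#'   (`"BP"`, `"CC"`, `"MF"`, or `"pathway"`), `gene_id` (long format, one
#'   row per term-gene pair); see [read_gmt()].
#' @param background Character vector of background gene IDs; defaults to
#'   every gene in the annotation.
#' @param p_threshold Raw p-value cutoff for the `significant` flag.
#' @return A tibble of class `ora_result` with columns `term_id`,
#'   `term_name`, `category`, `k`, `K`, `n`, `N`, `p_value`, `q_value`,
#'   `significant`.
#' @export
run_ora <- function(query, annotation, background = NULL, p_threshold = 0.01) {
  if (length(query) == 0) stop_usage("empty query gene set")
  annotation <- as_tibble(annotation)
  if (is.null(background)) background <- unique(annotation$gene_id)
  query <- unique(query)
  if (!all(query %in% background)) {
    stop_usage("query genes must all be contained in the background")
  }
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(query)
  res <- annotation |>
    group_by(.data$term_id, .data$term_name, .data$category) |>
    summarise(k = sum(unique(.data$gene_id) %in% query),
              K = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    filter(.data$k > 0) |>
    mutate(n = n, N = N,
           p_value = hypergeom_upper_tail(.data$k, .data$K, n, N))
  res <- res |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           significant = .data$p_value < p_threshold) |>
    arrange(.data$p_value, .data$term_id)
  class(res) <- c("ora_result", class(res))
  res
}

#' Top terms per annotation category
#'
#' First `k` terms per category after ordering by p-value with term-ID
#' tie-break - the selection rule used for enrichment bubble charts.
#'
#' @param results An `ora_result` (or compatible tibble).
#' @param k Terms to keep per category.
#' @return The filtered tibble.
#' @export
top_k_per_category <- function(results, k = 10) {
  as_tibble(results) |>
    arrange(.data$p_value, .data$term_id) |>
    group_by(.data$category) |>
    slice_head(n = k) |>
    ungroup()
}

#' Read a GMT-style annotation file
#'
#' Each tab-separated line is `term_id`, `term_name`, then gene IDs. A
#' category can be encoded as a `category:` prefix on the term name (e.g.
#' `BP:axon guidance`); lines without one default to `"pathway"`.
#'
#' @param path Path to the GMT file.
#' @return A long-format annotation tibble for [run_ora()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_format("GMT line needs term, name and >=1 gene")
    nm <- f[2]
    cat_match <- regmatches(nm, regexec("^(BP|CC|MF|pathway):(.*)$", nm))[[1]]
    if (length(cat_match)) {
      category <- cat_match[2]; nm <- cat_match[3]
    } else category <- "pathway"
    tibble(term_id = f[1], term_name = nm, category = category,
           gene_id = unique(f[-(1:2)]))
  })
  bind_rows(rows)
}
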