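# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ceRNA graph into its node table
#'
#' @param x A [cerna_graph].
#' @param ... Unused.
#' @return The node tibble (with centralities when computed).
#' @method tidy cerna_graph
#' @export
tidy.cerna_graph <- function(x, ...) as_tibble(network_nodes(x))

#' One-row summary of a ceRNA graph
#'
#' @inheritParams tidy.cerna_graph
#' @return A tibble with node counts per class and the edge count.
#' @method glance cerna_graph
#' @export
glance.cerna_graph <- function(x, ...) {
  n <- network_nodes(x)
  tibble(n_nodes = nrow(n),
         n_lncrna = sum(n$node_class == "lncRNA", na.rm = TRUE),
         n_mirna = sum(n$node_class == "miRNA", na.rm = TRUE),
         n_mrna = sum(n$node_class == "mRNA", na.rm = TRUE),
         n_edges = nrow(network_edges(x)))
}

#' Tidy a differential-expression table
#'
#' @param x A `de_table` from [call_sdels()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy de_table
#' @export
tidy.de_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_table")
  out
}

#' One-row summary of a differential-expression screen
#'
#' @inheritParams tidy.de_table
#' @return A tibble with feature and call counts.
#' @method glance de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble(rna_class = attr(x, "rna_class") %||% NA_character_,
         region = attr(x, "region") %||% NA_character_,
         n_features = nrow(x),
         n_up = sum(x$regulation == "up"),
         n_down = sum(x$regulation == "down"))
}

#' Tidy a qPCR quantification result
#'
#' @param x A `ddct_result` from [compute_ddct()].
#' @param ... Unused.
#' @return The per-sample delta-Ct tibble.
#' @method tidy ddct_result
#' @export
tidy.ddct_result <- function(x, ...) as_tibble(attr(x, "per_sample"))

#' One-row summary of a qPCR quantification
#'
#' @inheritParams tidy.ddct_result
#' @return The result row as a plain tibble.
#' @method glance ddct_result
#' @export
glance.ddct_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ddct_result")
  out
}

#' Tidy a per-region pipeline report
#'
#' @param x A `region_report` from [run_region()].
#' @param ... Unused.
#' @return The stage-count log tibble.
#' @method tidy region_report
#' @export
tidy.region_report <- function(x, ...) x$log

#' One-row summary of a per-region pipeline run
#'
#' @inheritParams tidy.region_report
#' @return Counts of SDELs, hub miRNAs, network mRNAs and retained triads.
#' @method glance region_report
#' @export
glance.region_report <- function(x, ...) {
  tibble(region = x$region,
         n_sdel_up = sum(x$de$lncRNA$regulation == "up"),
         n_sdel_down = sum(x$de$lncRNA$regulation == "down"),
         n_hub_mirnas = length(unique(unlist(
           lapply(x$directions, `[[`, "hub_mirnas")))),
         n_network_mrnas = length(unique(unlist(
           lapply(x$directions, `[[`, "mrnas")))),
         n_triads = nrow(report_triads(x)))
}
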