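# Multi-database target-prediction merging and anti-correlation filters.

#' Merge target-prediction tables
#'
#' Unions edge tables from several databases into one table keyed on
#' (source, target), concatenating the provenance tags of duplicated
#' predictions (sorted, deduplicated, `;`-joined). Idempotent and
#' order-independent.
#'
#' @param tables A list of edge tibbles (as returned by
#'   [read_target_table()]), all of the same `edge_type`.
#' @return A single merged edge tibble.
#' @export
merge_predictions <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  all_edges <- bind_rows(tables)
  if (nrow(all_edges) == 0) {
    return(tibble(source_id = character(), target_id = character(),
                  edge_type = character(), provenance = character()))
  }
  if (length(unique(all_edges$edge_type)) > 1) {
    stop_usage("cannot merge tables of different edge types")
  }
  all_edges |>
    tidyr::separate_rows("provenance", sep = ";") |>
    group_by(.data$source_id, .data$target_id, .data$edge_type) |>
    summarise(provenance = paste(sort(unique(.data$provenance)), collapse = ";"),
              .groups = "drop") |>
    arrange(.data$source_id, .data$target_id)
}

#' Anti-correlated miRNA intersection
#'
#' Under the ceRNA hypothesis a sponging lncRNA and its miRNAs move in
#' opposite directions: the predicted targets of upregulated lncRNAs are
#' intersected with the downregulated miRNA set, and vice versa.
#'
#' @param predicted Character vector of predicted miRNA IDs.
#' @param changed_up,changed_down Character vectors of miRNAs up/down in the
#'   expression screen.
#' @param lnc_regulation `"up"` or `"down"` - the direction of the lncRNAs
#'   behind the prediction.
#' @return Character vector (sorted) of retained miRNAs.
#' @export
anticorrelated_mirnas <- function(predicted, changed_up, changed_down,
                                  lnc_regulation) {
  assert_scalar_choice(lnc_regulation, c("up", "down"), "lnc_regulation")
  opposite <- if (lnc_regulation == "up") changed_down else changed_up
  sort(intersect(predicted, opposite))
}

#' Concordant mRNA intersection
#'
#' The mirror filter one layer down: targets of downregulated miRNAs are
#' intersected with upregulated mRNAs (the de-repressed direction), and vice
#' versa, so that mRNAs move with the lncRNA and against the miRNA.
#'
#' @param predicted Character vector of predicted mRNA IDs.
#' @param changed_up,changed_down Character vectors of mRNAs up/down in the
#'   expression screen.
#' @param mirna_regulation `"up"` or `"down"`.
#' @return Character vector (sorted) of retained mRNAs.
#' @export
concordant_mrnas <- function(predicted, changed_up, changed_down,
                             mirna_regulation) {
  assert_scalar_choice(mirna_regulation, c("up", "down"), "mirna_regulation")
  opposite <- if (mirna_regulation == "down") changed_up else changed_down
  sort(intersect(predicted, opposite))
}

#' Cross-region regulation consistency
#'
#' Splits features by whether their regulation call agrees between two brain
#' regions. Features significant in only one region are kept as consistent
#' but flagged, so downstream stages can restrict to features present in
#' both regions when required.
#'
#' @param de_region1,de_region2 `de_table`s (or tibbles with `feature_id`
#'   and `regulation`); `ns` rows are ignored.
#' @return A tibble with `feature_id`, `regulation_region1`,
#'   `regulation_region2`, `status` (`"consistent"`/`"inconsistent"`), and
#'   `in_both` (logical flag).
#' @export
cross_region_consistency <- function(de_region1, de_region2) {
  pick <- function(d) {
    d <- as_tibble(d)[, c("feature_id", "regulation")]
    d[d$regulation != "ns", , drop = FALSE]
  }
  r1 <- pick(de_region1); r2 <- pick(de_region2)
  dplyr::full_join(r1, r2, by = "feature_id",
                   suffix = c("_region1", "_region2")) |>
    mutate(
      in_both = !is.na(.data$regulation_region1) &
        !is.na(.data$regulation_region2),
      status = dplyr::if_else(
        .data$in_both &
          .data$regulation_region1 != .data$regulation_region2,
        "inconsistent", "consistent")
    ) |>
    arrange(.data$feature_id)
}
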