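#' Expression matrix for one RNA class in one brain region
#'
#' A light container holding a feature-by-sample matrix of expression values
#' together with the per-sample case/control labels, the RNA class
#' (lncRNA/miRNA/mRNA), the brain region, and the unit of the values.
#' Invariants are enforced at construction: IDs are unique, values are
#' non-negative (except z-scores), every sample carries a group label, and
#' each group has at least one sample.
#'
#' @param values Numeric matrix, features in rows and samples in columns, with
#'   row and column names set to feature and sample IDs.
#' @param group Character vector of per-sample labels, `"case"` or
#'   `"control"`, either named by sample ID or in column order.
#' @param rna_class One of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @param region One of `"cortex"`, `"hippocampus"`.
#' @param unit One of `"counts"`, `"TPM"`, `"CPM"`, `"zscore"`.
#'
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(rpois(8, 50), 2, 4,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' em <- expr_matrix(m, c(s1 = "case", s2 = "case", s3 = "control",
#'                        s4 = "control"), "mRNA", "cortex")
#' em
#' @export
expr_matrix <- function(values, group, rna_class, region, unit = "counts") {
  assert_scalar_choice(rna_class, c("lncRNA", "miRNA", "mRNA"), "rna_class")
  assert_scalar_choice(region, c("cortex", "hippocampus"), "region")
  assert_scalar_choice(unit, c("counts", "TPM", "CPM", "zscore"), "unit")
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop_format(sprintf("duplicate feature ID: %s", dup))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop_format(sprintf("duplicate sample ID: %s", dup))
  }
  if (anyNA(values)) stop_validation("missing values are not allowed")
  if (unit != "zscore" && any(values < 0)) {
    bad <- rownames(values)[which(values < 0, arr.ind = TRUE)[1, 1]]
    stop_validation(sprintf("negative value in feature %s", bad))
  }
  if (!is.null(names(group))) {
    missing <- setdiff(colnames(values), names(group))
    if (length(missing)) {
      stop_validation(sprintf("sample without group label: %s", missing[1]))
    }
    group <- unname(group[colnames(values)])
  }
  if (length(group) != ncol(values)) {
    stop_validation("`group` must label every sample")
  }
  if (!all(group %in% c("case", "control"))) {
    stop_validation("group labels must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% group)) {
    stop_validation("each of 'case' and 'control' needs at least one sample")
  }
  structure(
    list(values = values,
         samples = tibble(sample_id = colnames(values), group = group),
         rna_class = rna_class, region = region, unit = unit),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s / %s [%s]: %d features x %d samples (%d case, %d control)\n",
              x$rna_class, x$region, x$unit, nrow(x$values), ncol(x$values),
              sum(x$samples$group == "case"), sum(x$samples$group == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Long-format view of an expression matrix
#'
#' @param x An [expr_matrix].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `group`, `value`,
#'   plus the class/region/unit as constant columns.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  long <- tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  long |>
    left_join(x$samples, by = "sample_id") |>
    mutate(rna_class = x$rna_class, region = x$region, unit = x$unit) |>
    select("feature_id", "sample_id", "group", "value",
           "rna_class", "region", "unit")
}

group_values <- function(x, group) {
  x$values[, x$samples$sample_id[x$samples$group == group], drop = FALSE]
}

#' Read an expression matrix from a TSV file
#'
#' Expects a header row of sample IDs and a first column of feature IDs, as
#' exported by quantification tools. Values are validated as non-negative
#' counts; duplicated IDs, missing values, and unlabeled samples are errors.
#'
#' @param path Path to the TSV file.
#' @inheritParams expr_matrix
#' @param group_map Named character vector (or two-column data frame
#'   `sample_id`, `group`) assigning `"case"`/`"control"` to every sample.
#' @return An [expr_matrix] with `unit = "counts"`.
#' @export
read_expression_matrix <- function(path, rna_class, region, group_map) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(df) < 2) stop_format("expression TSV needs feature IDs plus >=1 sample")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate feature ID in %s: %s", path,
                        ids[duplicated(ids)][1]))
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- ids
  if (is.data.frame(group_map)) {
    group_map <- setNames(group_map$group, group_map$sample_id)
  }
  expr_matrix(m, group_map, rna_class, region, unit = "counts")
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips are value-identical.
#'
#' @param x An [expr_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- tibble(feature_id = rownames(x$values))
  df <- dplyr::bind_cols(df, as_tibble(as.data.frame(x$values)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
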