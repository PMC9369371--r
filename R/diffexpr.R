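# Fold-change computation and differential-expression screening.

#' Screening thresholds for differential-expression calls
#'
#' Bundles the thresholds used throughout the screening stage. The defaults
#' reproduce the study conditions: a pseudo-floor of 1e-4 on group means
#' (matching the "0.0001" convention used for undetected transcripts in
#' printed tables), a linear fold-change cutoff of 2 with q < 0.01 for
#' significance calls, and a strict signed fold-change cutoff of 1 for the
#' permissive "changed" screen.
#'
#' @param fc_floor Pseudo-floor applied to group means before ratios.
#' @param sdel_fc_threshold Linear fold-change cutoff for significance calls.
#' @param sdel_q_threshold BH q-value cutoff for significance calls.
#' @param changed_fc_threshold Signed fold-change cutoff (strict) for the
#'   changed-set screen.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(fc_floor = 1e-4, sdel_fc_threshold = 2,
                             sdel_q_threshold = 0.01,
                             changed_fc_threshold = 1) {
  stopifnot(fc_floor > 0, sdel_fc_threshold > 0, sdel_q_threshold > 0,
            changed_fc_threshold > 0)
  structure(list(fc_floor = fc_floor, sdel_fc_threshold = sdel_fc_threshold,
                 sdel_q_threshold = sdel_q_threshold,
                 changed_fc_threshold = changed_fc_threshold,
                 test = "student_t", mtc = "benjamini_hochberg"),
            class = "screening_config")
}

#' Floored log2 fold change
#'
#' log2 ratio of case to control group means, with both means floored at
#' `fc_floor` so undetected features yield large finite fold changes rather
#' than infinities.
#'
#' @param mean_case,mean_control Non-negative group means (same unit).
#' @param fc_floor Pseudo-floor (default 1e-4).
#' @return Numeric vector of log2 fold changes.
#' @examples
#' log2_fold_change(131.1167, 0.0467) # 11.46
#' @export
log2_fold_change <- function(mean_case, mean_control, fc_floor = 1e-4) {
  if (any(mean_case < 0) || any(mean_control < 0)) {
    stop_validation("group means must be non-negative")
  }
  log2(pmax(mean_case, fc_floor) / pmax(mean_control, fc_floor))
}

#' Signed (linear) fold change
#'
#' Reports the floored linear ratio r for upregulation (r >= 1) and -1/r for
#' downregulation, so the magnitude is always at least 1 and the sign carries
#' the direction.
#'
#' @inheritParams log2_fold_change
#' @return Numeric vector with `|value| >= 1`.
#' @examples
#' signed_fold_change(10, 5)  #  2
#' signed_fold_change(5, 10)  # -2
#' @export
signed_fold_change <- function(mean_case, mean_control, fc_floor = 1e-4) {
  r <- 2^log2_fold_change(mean_case, mean_control, fc_floor)
  ifelse(r >= 1, r, -1 / r)
}

# per-feature two-sided equal-variance Student's t; zero-variance-in-both
# features get p = 1 (no evidence of change at all)
row_student_t <- function(case, ctrl) {
  n1 <- ncol(case); n2 <- ncol(ctrl)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var); v2 <- apply(ctrl, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * pt(-abs(tt), df = n1 + n2 - 2)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  p
}

#' Call significantly differentially expressed features
#'
#' Per feature: group means on the normalized scale, floored log2 fold
#' change, a two-sided equal-variance Student's t-test, Benjamini-Hochberg
#' q-values over the full feature list, and a regulation call. A feature is
#' called `up` when its linear fold change exceeds `sdel_fc_threshold` and
#' its q-value falls below `sdel_q_threshold`; `down` for the reciprocal
#' fold-change condition; otherwise `ns`.
#'
#' @param norm An [expr_matrix] with `unit` `"TPM"` or `"CPM"` and at least
#'   two samples per group.
#' @param cfg A [screening_config()].
#' @return A tibble of class `de_table` with columns `feature_id`,
#'   `mean_case`, `mean_control`, `log2fc`, `signed_fc`, `p_value`,
#'   `q_value`, `regulation`, and attributes recording class/region.
#' @export
call_sdels <- function(norm, cfg = screening_config()) {
  if (!norm$unit %in% c("TPM", "CPM")) {
    stop_usage("call_sdels expects TPM or CPM values")
  }
  case <- group_values(norm, "case")
  ctrl <- group_values(norm, "control")
  if (ncol(case) < 2 || ncol(ctrl) < 2) {
    stop_usage("need at least two samples per group for the t-test")
  }
  lfc <- log2_fold_change(rowMeans(case), rowMeans(ctrl), cfg$fc_floor)
  p <- row_student_t(case, ctrl)
  q <- p.adjust(p, method = "BH")
  lin <- 2^lfc
  reg <- dplyr::case_when(
    lin > cfg$sdel_fc_threshold & q < cfg$sdel_q_threshold ~ "up",
    lin < 1 / cfg$sdel_fc_threshold & q < cfg$sdel_q_threshold ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(
    feature_id = rownames(norm$values),
    mean_case = rowMeans(case), mean_control = rowMeans(ctrl),
    log2fc = lfc,
    signed_fc = signed_fold_change(rowMeans(case), rowMeans(ctrl), cfg$fc_floor),
    p_value = p, q_value = q, regulation = reg
  )
  attr(out, "rna_class") <- norm$rna_class
  attr(out, "region") <- norm$region
  class(out) <- c("de_table", class(out))
  out
}

#' Screen for any-change features
#'
#' The permissive screen used for miRNAs and mRNAs: a feature is `up` when
#' its signed fold change strictly exceeds +1 and `down` when it falls
#' strictly below -1; features with equal floored group means belong to
#' neither set.
#'
#' @inheritParams call_sdels
#' @return A list with character vectors `up` and `down`.
#' @export
screen_changed <- function(norm, cfg = screening_config()) {
  case <- rowMeans(group_values(norm, "case"))
  ctrl <- rowMeans(group_values(norm, "control"))
  sfc <- signed_fold_change(case, ctrl, cfg$fc_floor)
  ids <- rownames(norm$values)
  list(up = ids[sfc > cfg$changed_fc_threshold],
       down = ids[sfc < -cfg$changed_fc_threshold])
}
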