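# Paired before/after comparison of per-subject numeric columns (the 33
# movement features, or any externally supplied scores) with two-tailed
# paired t-tests, mean +/- SD summaries and significance stars. No
# multiple-testing correction is applied to the primary p-values; a
# Holm-adjusted column is emitted alongside, clearly labelled as an
# extension.

#' Two-tailed paired t-test from first principles
#'
#' Classical paired t on the within-subject differences
#' `d = before - after`: `t = mean(d) / (sd(d) / sqrt(n))`, two-tailed p
#' from Student's t with `n - 1` degrees of freedom. Pairs with a missing
#' value on either side are dropped and the effective `n` is reported.
#' A positive `t` means the column decreased after treatment.
#'
#' Degenerate edges: all differences exactly zero gives `t = 0, p = 1`;
#' identical nonzero differences (zero SD, nonzero mean) are a
#' degenerate-variance error.
#'
#' @param before,after Numeric vectors of equal length, paired by position.
#' @return List with `statistic`, `p.value`, `n` (effective pairs), `df`,
#'   `mean_diff` and `sd_diff`.
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after))
    sq_stop("before and after must have equal length", "skelquant_input_error")
  ok <- !(is.na(before) | is.na(after))
  d <- before[ok] - after[ok]
  n <- length(d)
  if (n < 2L)
    sq_stop(sprintf("fewer than 2 complete pairs (n = %d)", n),
            "skelquant_insufficient_pairs_error")
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(statistic = 0, p.value = 1, n = n, df = n - 1L,
                  mean_diff = 0, sd_diff = 0))
    sq_stop("all differences identical and nonzero: t statistic undefined",
            "skelquant_degenerate_variance_error")
  }
  t_stat <- md / (sdd / sqrt(n))
  list(statistic = t_stat,
       p.value = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       n = n, df = n - 1L, mean_diff = md, sd_diff = sdd)
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Pair two per-subject feature tables into a cohort
#'
#' Validates that the two sessions cover identical subject and column sets;
#' rows are matched by `subject_id`, never by position.
#'
#' @param before,after Data frames with a `subject_id` column and identical
#'   numeric columns (e.g. from [feature_table()]).
#' @return A list of class `paired_cohort` with aligned `before` and
#'   `after` data frames.
#' @export
paired_cohort <- function(before, after) {
  if (!"subject_id" %in% names(before) || !"subject_id" %in% names(after))
    sq_stop("both tables need a subject_id column", "skelquant_input_error")
  unmatched <- c(setdiff(before$subject_id, after$subject_id),
                 setdiff(after$subject_id, before$subject_id))
  if (length(unmatched) > 0L)
    sq_stop(sprintf("unmatched subjects between sessions: %s",
                    paste(unique(unmatched), collapse = ", ")),
            "skelquant_input_error")
  if (anyDuplicated(before$subject_id) || anyDuplicated(after$subject_id))
    sq_stop("duplicate subject_id within a session", "skelquant_input_error")
  if (nrow(before) < 2L)
    sq_stop("a paired cohort needs at least 2 subjects", "skelquant_input_error")
  cols_b <- setdiff(names(before), c("subject_id", "session"))
  cols_a <- setdiff(names(after), c("subject_id", "session"))
  if (!setequal(cols_b, cols_a))
    sq_stop("before/after column sets differ", "skelquant_input_error")
  after <- after[match(before$subject_id, after$subject_id), , drop = FALSE]
  structure(list(before = before, after = after, columns = cols_b),
            class = "paired_cohort")
}

#' Compare a paired cohort column by column
#'
#' One two-tailed paired t-test per column, with mean +/- SD per session
#' computed on the paired (complete-case) subset. Missing values are handled
#' by pairwise deletion per column and the effective `n` is reported.
#' Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, uncorrected
#' (matching the convention of reporting each feature at the nominal level);
#' `p_holm` is a Holm step-down adjustment added as a labelled extension.
#' Columns whose test is degenerate are returned as flagged rows (`NA`
#' statistics plus a `note`), not errors.
#'
#' @param cohort A [paired_cohort()].
#' @param columns Columns to compare; defaults to every shared numeric
#'   column, in [feature_names()] order when they are the 33 features.
#' @return Data frame of class `cohort_comparison`: one row per column with
#'   `feature`, `n`, `mean_before`, `sd_before`, `mean_after`, `sd_after`,
#'   `t_statistic`, `p_value`, `stars`, `p_holm`, `note`.
#' @export
compare_cohort <- function(cohort, columns = NULL) {
  if (!inherits(cohort, "paired_cohort"))
    sq_stop("cohort must be a paired_cohort", "skelquant_input_error")
  if (is.null(columns)) {
    columns <- cohort$columns
    if (setequal(columns, feature_names())) columns <- feature_names()
  }
  missing_cols <- setdiff(columns, cohort$columns)
  if (length(missing_cols) > 0L)
    sq_stop(sprintf("columns not present in both sessions: %s",
                    paste(missing_cols, collapse = ", ")),
            "skelquant_input_error")

  rows <- lapply(columns, function(cl) {
    b <- cohort$before[[cl]]; a <- cohort$after[[cl]]
    ok <- !(is.na(b) | is.na(a))
    res <- tryCatch(paired_t_test(b, a), skelquant_error = function(e)
      list(statistic = NA_real_, p.value = NA_real_, n = sum(ok),
           note = conditionMessage(e)))
    data.frame(feature = cl, n = res$n,
               mean_before = if (any(ok)) mean(b[ok]) else NA_real_,
               sd_before = if (sum(ok) > 1L) stats::sd(b[ok]) else NA_real_,
               mean_after = if (any(ok)) mean(a[ok]) else NA_real_,
               sd_after = if (sum(ok) > 1L) stats::sd(a[ok]) else NA_real_,
               t_statistic = res$statistic, p_value = res$p.value,
               note = res$note %||% "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- p_stars(out$p_value)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out <- out[c("feature", "n", "mean_before", "sd_before", "mean_after",
               "sd_after", "t_statistic", "p_value", "stars", "p_holm",
               "note")]
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' @export
print.cohort_comparison <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$mean_before <- sprintf("%.*g", digits, df$mean_before)
  df$mean_after <- sprintf("%.*g", digits, df$mean_after)
  print.data.frame(df[c("feature", "n", "mean_before", "mean_after",
                        "p_value", "stars")], row.names = FALSE)
  invisible(x)
}

#' Render a comparison in the publication table layout
#'
#' Columns: feature, `Before Treatment` and `After Treatment` as
#' `mean ± SD`, `p Value`, stars.
#'
#' @param comparison A `cohort_comparison`.
#' @param digits Significant digits for means and SDs.
#' @return Data frame of formatted character columns.
#' @export
format_comparison_table <- function(comparison, digits = 2) {
  fmt <- function(m, s) ifelse(is.na(m), "",
    sprintf("%.*f ± %.*f", digits, m, digits, s))
  data.frame(Parameters = comparison$feature,
             `Before Treatment` = fmt(comparison$mean_before,
                                      comparison$sd_before),
             `After Treatment` = fmt(comparison$mean_after,
                                     comparison$sd_after),
             `p Value` = ifelse(is.na(comparison$p_value), "",
                                sprintf("%.4f", comparison$p_value)),
             Significance = comparison$stars,
             check.names = FALSE, stringsAsFactors = FALSE)
}
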