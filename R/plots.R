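# Before/after boxplot panels per feature family, with significance stars
# from the paired comparison. Base graphics, rendered straight to PNG:
# no interactive display is assumed.

family_label <- function(family) {
  switch(family,
         acf_orig = "First autocorrelation, original series",
         acf_diff = "First autocorrelation, differenced series",
         avgvar = "Averaged variance, original series",
         family)
}

#' Boxplot panel of one feature family, before vs after
#'
#' Draws 11 paired boxplots (one per skeleton parameter) for the chosen
#' feature family, annotated with the significance stars of the paired
#' comparison (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#'
#' @param cohort A [paired_cohort()] of feature tables.
#' @param family One of `"acf_orig"`, `"acf_diff"`, `"avgvar"`.
#' @param comparison Optional precomputed [compare_cohort()] result; run on
#'   the fly when omitted.
#' @param file Optional PNG path; when given, the panel is written there
#'   (1200 x 600 px) instead of the active device.
#' @return The comparison rows of the family, invisibly.
#' @export
plot_feature_boxplots <- function(cohort, family = c("acf_orig", "acf_diff",
                                                     "avgvar"),
                                  comparison = NULL, file = NULL) {
  family <- match.arg(family)
  cols <- paste0(family, "_", parameter_names())
  if (is.null(comparison)) comparison <- compare_cohort(cohort, cols)
  comparison <- comparison[match(cols, comparison$feature), ]

  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 600, res = 110)
    on.exit(grDevices::dev.off())
  }
  vals <- list(); at <- numeric(0); centers <- numeric(0)
  for (k in seq_along(cols)) {
    vals[[2 * k - 1]] <- cohort$before[[cols[k]]]
    vals[[2 * k]] <- cohort$after[[cols[k]]]
    at <- c(at, 3 * k - 1.6, 3 * k - 0.8)
    centers <- c(centers, 3 * k - 1.2)
  }
  op <- graphics::par(mar = c(9, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::boxplot(vals, at = at, xaxt = "n",
                    col = rep(c("grey80", "grey45"), length(cols)),
                    border = "grey20", outline = TRUE, pch = 16, cex = 0.5,
                    ylab = family_label(family))
  graphics::axis(1, at = centers, labels = FALSE)
  graphics::text(centers, graphics::par("usr")[3] -
                   0.04 * diff(graphics::par("usr")[3:4]),
                 labels = gsub("_", " ", parameter_names()),
                 srt = 45, adj = 1, xpd = TRUE, cex = 0.8)
  ymax <- graphics::par("usr")[4]
  graphics::text(centers, ymax - 0.03 * diff(graphics::par("usr")[3:4]),
                 labels = comparison$stars, cex = 1.1)
  graphics::title(main = sprintf("%s (before: light, after: dark)",
                                 family_label(family)))
  invisible(comparison)
}
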