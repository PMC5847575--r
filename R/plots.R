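#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_boxplot geom_segment
#'   geom_line geom_abline labs theme_minimal scale_y_continuous
NULL

#' Plot retention-time stability per standard peptide
#'
#' @param object An [rt_stability()] result.
#' @param ... Unused.
#' @return A ggplot: apex RT standard deviation per standard.
#' @export
autoplot.rt_stability <- function(object, ...) {
  ggplot(object$per_standard,
         aes(x = stats::reorder(.data$peptide_id, .data$mean_rt),
             y = .data$sd_seconds)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "apex RT SD (s)",
         title = sprintf("Mean RT SD %.1f s across %d standards",
                         object$mean_sd_seconds, nrow(object$per_standard))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot batch clustering in principal-component space
#'
#' @param object A [batch_diagnostics()] result.
#' @param ... Unused.
#' @return A ggplot: runs in PC1/PC2, colored by batch, QC runs as triangles.
#' @export
autoplot.batch_diagnostics <- function(object, ...) {
  ggplot(object$scores,
         aes(x = .data$PC1, y = .data$PC2, colour = .data$batch,
             shape = .data$sample_type)) +
    geom_point(size = 2, alpha = 0.8) +
    labs(title = sprintf("Batch silhouette %.2f", object$silhouette),
         x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2])) +
    theme_minimal()
}

#' Plot an isolation-window scheme
#'
#' @param object A [design_windows()] scheme.
#' @param ... Unused.
#' @return A ggplot of the window tiling along m/z.
#' @export
autoplot.acquisition_scheme <- function(object, ...) {
  ggplot(object$windows,
         aes(x = .data$mz_start, xend = .data$mz_end,
             y = .data$window, yend = .data$window)) +
    geom_segment(linewidth = 2, colour = "steelblue") +
    labs(x = "m/z (Th)", y = "window",
         title = sprintf("%d x %g m/z windows, cycle %.2f s",
                         object$n_windows, object$width, object$t_cycle)) +
    theme_minimal()
}

#' Plot empirical-Bayes shrinkage of batch effects
#'
#' @param object A [fit_combat()] model.
#' @param ... Unused.
#' @return A ggplot of raw vs shrunk additive batch estimates per batch.
#' @export
autoplot.combat_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$gamma_hat, y = .data$gamma_star,
                           colour = .data$batch)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.4, size = 0.8) +
    labs(x = "raw batch estimate", y = "shrunk batch estimate") +
    theme_minimal()
}

#' Compare the kept-precursor counts of the four filter policies
#'
#' @param verdicts A [filter_verdicts()] tibble.
#' @return A ggplot bar chart of precursors kept per policy.
#' @export
plot_filter_comparison <- function(verdicts) {
  assert_columns(verdicts, c("sparse", "complete", "percentile", "median"),
                 "Filter verdicts")
  counts <- tibble(
    mode = factor(c("complete", "median", "percentile", "sparse"),
                  levels = c("complete", "percentile", "median", "sparse")),
    kept = c(sum(verdicts$complete), sum(verdicts$median),
             sum(verdicts$percentile), sum(verdicts$sparse))
  )
  ggplot(counts, aes(x = .data$mode, y = .data$kept)) +
    geom_col(fill = "grey40") +
    labs(x = "Qvalue filter policy", y = "precursors kept") +
    theme_minimal()
}

#' Plot CV distributions by group type
#'
#' @param cv A [cv_table()] result.
#' @return A ggplot boxplot of per-feature CVs per group.
#' @export
plot_cv <- function(cv) {
  assert_columns(cv, c("group", "group_type", "cv"), "CV table")
  ggplot(cv[!is.na(cv$cv), ],
         aes(x = .data$group, y = .data$cv, fill = .data$group_type)) +
    geom_boxplot(outlier.size = 0.4) +
    scale_y_continuous(limits = c(0, NA)) +
    labs(x = NULL, y = "CV (%)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
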