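#' Per-feature coefficients of variation by replicate group
#'
#' CVs are computed on linear-scale intensities (sample SD / mean, in
#' percent), per feature within named run groups; groups with fewer than 2
#' measured values yield a missing CV, never 0. Three group families cover the
#' standard diagnostics of a QC-anchored design:
#'
#' * `qc_intra`: QC runs within one batch (one group per batch),
#' * `qc_inter`: all QC runs pooled across batches,
#' * `replicate_total`: study replicates of one covariate level (e.g. one
#'   strain) pooled across batches — the "total variability" groups.
#'
#' @param qm A linear-scale [quant_matrix()].
#' @param design Sample-design tibble covering the matrix's runs.
#' @param grouping Which group families to compute (any subset of the three).
#' @param covariate Design column defining the replicate groups, default
#'   `"strain"`.
#' @return A tibble with one row per (feature, group): `group`, `group_type`,
#'   `n_runs`, `n_present`, `cv` (%). Summarise with [cv_summary()].
#' @export
cv_table <- function(qm, design,
                     grouping = c("qc_intra", "qc_inter", "replicate_total"),
                     covariate = "strain") {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "linear") abort("CVs are computed on linear-scale intensities.")
  grouping <- match.arg(grouping, several.ok = TRUE)
  design <- validate_sample_design(design)
  runs <- colnames(qm$values)
  design <- design[design$run_id %in% runs, ]
  groups <- list()
  if ("qc_intra" %in% grouping) {
    qc <- design[design$sample_type == "QC", ]
    for (b in sort(unique(qc$batch))) {
      groups[[paste0("QC_", b)]] <-
        list(runs = qc$run_id[qc$batch == b], type = "qc_intra")
    }
  }
  if ("qc_inter" %in% grouping) {
    groups[["QC_all"]] <- list(runs = design$run_id[design$sample_type == "QC"],
                               type = "qc_inter")
  }
  if ("replicate_total" %in% grouping) {
    assert_columns(design, covariate, "Sample design")
    st <- design[design$sample_type == "study", ]
    for (lev in sort(unique(st[[covariate]]))) {
      groups[[paste0(covariate, "_", lev)]] <-
        list(runs = st$run_id[st[[covariate]] == lev], type = "replicate_total")
    }
  }
  groups <- groups[vapply(groups, function(g) length(g$runs) >= 2L, logical(1))]
  if (length(groups) == 0L) {
    abort("No group with >= 2 runs under the requested grouping.")
  }
  out <- purrr::imap(groups, function(g, name) {
    sub <- qm$values[, g$runs, drop = FALSE]
    tibble(
      precursor_id = rownames(sub),
      group = name,
      group_type = g$type,
      n_runs = length(g$runs),
      n_present = unname(rowSums(!is.na(sub))),
      cv = unname(apply(sub, 1L, cv_percent))
    )
  })
  dplyr::bind_rows(out)
}

#' Cohort-level CV summary
#'
#' Median CV across features (and groups) per group type, with the spread
#' across groups.
#'
#' @param cv A [cv_table()] result.
#' @return A tibble per `group_type`: `median_cv`, `median_cv_by_group_mean`,
#'   `median_cv_by_group_sd`, `n_features`, `n_groups`.
#' @export
cv_summary <- function(cv) {
  assert_columns(cv, c("group", "group_type", "cv"), "CV table")
  per_group <- cv |>
    dplyr::group_by(.data$group_type, .data$group) |>
    dplyr::summarise(median_cv = median(.data$cv, na.rm = TRUE),
                     .groups = "drop")
  cv |>
    dplyr::group_by(group_type = .data$group_type) |>
    dplyr::summarise(
      median_cv = median(.data$cv, na.rm = TRUE),
      n_features = dplyr::n_distinct(.data$precursor_id),
      n_groups = dplyr::n_distinct(.data$group),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      per_group |>
        dplyr::group_by(group_type = .data$group_type) |>
        dplyr::summarise(median_cv_by_group_mean = mean(.data$median_cv),
                         median_cv_by_group_sd = sd(.data$median_cv),
                         .groups = "drop"),
      by = "group_type"
    )
}

#' Variability reduction achieved by a correction
#'
#' `100 * (median_before - median_after) / median_before`, computed on the
#' total (cross-batch) CV. Accepts either two [cv_table()] results (the median
#' is taken over all feature-group CVs of `group_type`) or two plain numbers
#' (the medians themselves). A negative value means the correction increased
#' variability; it is returned, not an error.
#'
#' @param before,after [cv_table()] results on the same features and grouping,
#'   or single numeric median CVs.
#' @param group_type Group family defining "total" variability, default
#'   `"replicate_total"`.
#' @return The reduction in percent.
#' @export
variability_reduction <- function(before, after, group_type = "replicate_total") {
  med <- function(x) {
    if (is.numeric(x) && length(x) == 1L) return(x)
    assert_columns(x, c("group_type", "cv"), "CV table")
    median(x$cv[x$group_type == group_type], na.rm = TRUE)
  }
  if (is.data.frame(before) && is.data.frame(after)) {
    key_b <- unique(before[c("precursor_id", "group")])
    key_a <- unique(after[c("precursor_id", "group")])
    if (!identical(dim(key_b), dim(key_a))) {
      abort("`before` and `after` must cover the same features and groups.")
    }
  }
  mb <- med(before)
  ma <- med(after)
  if (!is.finite(mb) || mb == 0) abort("Median CV before correction is zero or undefined.")
  100 * (mb - ma) / mb
}

#' Batch-effect diagnostics
#'
#' Three views of how strongly batches structure a matrix: (1) per-feature
#' one-way R-squared of the batch factor; (2) a principal-component projection
#' of the runs (complete-case features, feature-centered, first 2 components);
#' (3) the mean silhouette width of the batch labels in that projection
#' (near 0: no batch clustering; towards 1: runs cluster by batch).
#'
#' @param qm A log2-scale [quant_matrix()] with at least 3 runs.
#' @param design Sample-design tibble with at least 2 batches among the
#'   matrix's runs.
#' @return A `batch_diagnostics` object: `r2` (per-feature tibble), `scores`
#'   (per-run tibble with `PC1`, `PC2`, `batch`, `sample_type`),
#'   `silhouette` (mean width), `var_explained` (by PC1/PC2).
#' @export
batch_diagnostics <- function(qm, design) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") abort("Batch diagnostics expect a log2-scale matrix.")
  design <- validate_sample_design(design)
  runs <- colnames(qm$values)
  if (length(runs) < 3L) abort("Need >= 3 runs.")
  design <- design[match(runs, design$run_id), ]
  if (anyNA(design$run_id)) abort("Design does not cover all matrix runs.")
  batch <- factor(design$batch)
  if (nlevels(batch) < 2L) abort("Need >= 2 batches.")
  complete <- qm$values[rowSums(is.na(qm$values)) == 0L, , drop = FALSE]
  if (nrow(complete) < 2L) abort("Need >= 2 complete features.")
  # one-way batch R2 per feature
  gm <- rowMeans(complete)
  sst <- rowSums((complete - gm)^2)
  ssb <- rep(0, nrow(complete))
  for (b in levels(batch)) {
    cols <- batch == b
    ssb <- ssb + sum(cols) * (rowMeans(complete[, cols, drop = FALSE]) - gm)^2
  }
  r2 <- tibble(precursor_id = rownames(complete),
               batch_r2 = ifelse(sst > 0, ssb / sst, NA_real_))
  centered <- complete - gm
  pc <- stats::prcomp(t(centered), center = FALSE, rank. = 2L)
  scores <- tibble(run_id = runs, PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                   batch = as.character(batch),
                   sample_type = design$sample_type)
  sil <- cluster::silhouette(as.integer(batch),
                             stats::dist(pc$x[, 1:2, drop = FALSE]))
  structure(
    list(r2 = r2, scores = scores,
         silhouette = mean(sil[, "sil_width"]),
         var_explained = (pc$sdev[1:2]^2) / sum(pc$sdev^2)),
    class = "batch_diagnostics"
  )
}

#' @export
print.batch_diagnostics <- function(x, ...) {
  cat(sprintf("<batch_diagnostics> mean batch silhouette %.3f; median batch R2 %.3f\n",
              x$silhouette, median(x$r2$batch_r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
glance.batch_diagnostics <- function(x, ...) {
  tibble(silhouette = x$silhouette,
         median_batch_r2 = median(x$r2$batch_r2, na.rm = TRUE),
         pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}
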