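#' Run the full post-processing pipeline
#'
#' Executes the stages in fixed order: Qvalue filter -> pivot/log ->
#' robust-sum normalization -> retention-time stability (side channel) ->
#' batch correction -> peptide selection -> geometric rollup -> QC metrics.
#' Standard (iRT) rows feed the retention-time stage and are excluded from the
#' quantification path. The run is deterministic given (inputs, config): the
#' only stochastic component (the surrogate-count permutation null) is seeded
#' from the config.
#'
#' @param report A long-report tibble (see [read_long_report()]).
#' @param design A sample-design tibble covering every run of the report.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, each stage output, the QC
#'   report (JSON + markdown dossier) and a provenance record are written
#'   there.
#' @return A `dia_pipeline` list: `protein_matrix`, `qc` (assembled QC
#'   sections), `stages` (per-stage objects), `stage_counts` (features/runs
#'   after each stage), `provenance`.
#' @export
run_pipeline <- function(report, design, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- validate_long_report(report)
  design <- validate_sample_design(design)
  orphan_runs <- setdiff(unique(report$run_id), design$run_id)
  if (length(orphan_runs)) {
    abort(sprintf("Design is missing run id(s) present in the report: %s.",
                  paste(head(orphan_runs, 5), collapse = ", ")))
  }
  stages <- list()
  counts <- list()
  note_count <- function(stage, n_features, n_runs) {
    counts[[length(counts) + 1L]] <<- tibble(stage = stage,
                                             n_features = n_features,
                                             n_runs = n_runs)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  analyte <- report[!report$is_standard, , drop = FALSE]
  note_count("input", dplyr::n_distinct(analyte$precursor_id),
             dplyr::n_distinct(analyte$run_id))

  # retention-time side channel (uses the standards, full report)
  stages$rt <- if (any(report$is_standard) && dplyr::n_distinct(report$run_id) >= 2) {
    run_stage("rt_stability", rt_stability(report))
  }

  if (config$filter_mode != "none") {
    policy <- filter_policy(config$filter_mode, config$qvalue_cutoff,
                            config$percentile_fraction)
    analyte <- run_stage("qvalue_filter", qvalue_filter(analyte, policy))
    stages$filter <- list(policy = policy,
                          kept = attr(analyte, "kept"),
                          verdicts = run_stage("qvalue_filter",
                                               filter_verdicts(report[!report$is_standard, ],
                                                               config$qvalue_cutoff,
                                                               config$percentile_fraction)))
    note_count("qvalue_filter", dplyr::n_distinct(analyte$precursor_id),
               dplyr::n_distinct(analyte$run_id))
  }

  qm_linear <- run_stage("pivot", pivot_to_matrix(analyte, "linear",
                                                  run_order = design$run_id[design$run_id %in% analyte$run_id]))

  if (config$normalize) {
    norm <- run_stage("robust_sum_normalize",
                      robust_sum_normalize(qm_linear, config$pool_fraction))
    stages$normalize <- norm
    qm_linear <- norm$matrix
    note_count("normalize", nrow(qm_linear$values), ncol(qm_linear$values))
  }
  qm_log <- to_scale(qm_linear, "log2")

  cv_before <- run_stage("qc_metrics", cv_table(qm_linear, design,
                                                covariate = config$covariate))
  diag_before <- run_stage("qc_metrics", try_or_null(
    batch_diagnostics(qm_log, design)))

  corrected <- qm_log
  if (config$correction == "combat") {
    d2 <- design
    d2$condition <- ifelse(d2$sample_type == "QC", "QC", d2[[config$covariate]])
    model <- run_stage("batch_correction",
                       fit_combat(qm_log, d2, covariates = "condition",
                                  shrink = config$shrink))
    corrected <- run_stage("batch_correction", apply_combat(qm_log, model))
    stages$correction <- model
  } else if (config$correction == "sva") {
    model <- run_stage("batch_correction",
                       estimate_surrogates(qm_log,
                                           control_fraction = config$control_fraction,
                                           k = config$sva_k,
                                           perm_seed = config$seed))
    corrected <- run_stage("batch_correction",
                           regress_out_surrogates(qm_log, model))
    stages$correction <- model
  }
  note_count("batch_correction", nrow(corrected$values), ncol(corrected$values))
  corrected_linear <- to_scale(corrected, "linear")
  cv_after <- run_stage("qc_metrics", cv_table(corrected_linear, design,
                                               covariate = config$covariate))
  diag_after <- run_stage("qc_metrics", try_or_null(
    batch_diagnostics(corrected, design)))

  groups <- if (config$select_peptides) {
    run_stage("select_peptides",
              select_peptides(corrected, rho_min = config$rho_min,
                              min_overlap = config$min_overlap))
  }
  stages$selection <- groups
  prot <- run_stage("rollup",
                    rollup_geometric(corrected, groups,
                                     min_present_fraction = config$min_present_fraction))
  keep_prot <- prot$proteins$n_peptides >= config$min_peptides
  prot$values <- prot$values[keep_prot, , drop = FALSE]
  prot$proteins <- prot$proteins[keep_prot, , drop = FALSE]
  note_count("rollup", nrow(prot$values), ncol(prot$values))

  qc <- assemble_qc(stages, cv_before, cv_after, diag_before, diag_after,
                    config)
  provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stage_counts = dplyr::bind_rows(counts),
    n_input_rows = nrow(report),
    package_version = as.character(utils::packageVersion("diaq"))
  )
  result <- structure(
    list(protein_matrix = prot, qc = qc, stages = stages,
         cv_before = cv_before, cv_after = cv_after,
         stage_counts = dplyr::bind_rows(counts), provenance = provenance),
    class = "dia_pipeline"
  )
  if (!is.null(out_dir)) persist_pipeline(result, out_dir)
  result
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

assemble_qc <- function(stages, cv_before, cv_after, diag_before, diag_after,
                        config) {
  cvs_b <- cv_summary(cv_before)
  cvs_a <- cv_summary(cv_after)
  pick <- function(s, type, col = "median_cv") {
    v <- s[[col]][s$group_type == type]
    if (length(v)) v else NA_real_
  }
  reduction <- try_or_null(variability_reduction(cv_before, cv_after))
  list(
    rt = if (!is.null(stages$rt)) list(
      mean_sd_seconds = stages$rt$mean_sd_seconds,
      max_cv_percent = stages$rt$max_cv_percent,
      median_run_r2 = stages$rt$median_r2
    ),
    filter = if (!is.null(stages$filter)) list(
      mode = stages$filter$policy$mode,
      qvalue_cutoff = stages$filter$policy$qvalue_cutoff,
      n_kept = length(stages$filter$kept),
      n_total = nrow(stages$filter$verdicts)
    ),
    normalize = if (!is.null(stages$normalize)) as.list(glance(stages$normalize)),
    correct = if (!is.null(stages$correction)) {
      c(list(mode = config$correction), as.list(glance(stages$correction)))
    },
    cv = list(
      intra_batch_median = pick(cvs_b, "qc_intra"),
      inter_batch_median = pick(cvs_b, "qc_inter"),
      intra_batch_median_corrected = pick(cvs_a, "qc_intra"),
      inter_batch_median_corrected = pick(cvs_a, "qc_inter"),
      total_median = pick(cvs_b, "replicate_total"),
      total_median_corrected = pick(cvs_a, "replicate_total"),
      reduction_percent = reduction
    ),
    batch = list(
      silhouette_before = if (!is.null(diag_before)) diag_before$silhouette,
      silhouette_after = if (!is.null(diag_after)) diag_after$silhouette
    )
  )
}

persist_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_quant_matrix(result$protein_matrix$values,
                     file.path(out_dir, "protein_matrix.tsv"),
                     id_column = "protein_id")
  if (!is.null(result$stages$selection)) {
    write_dia_tsv(tidy(result$stages$selection),
                  file.path(out_dir, "selection_audit.tsv"))
  }
  if (!is.null(result$stages$filter)) {
    write_dia_tsv(result$stages$filter$verdicts,
                  file.path(out_dir, "filter_audit.tsv"))
  }
  if (!is.null(result$stages$normalize)) {
    write_dia_tsv(result$stages$normalize$factors,
                  file.path(out_dir, "normalization_factors.tsv"))
  }
  write_dia_tsv(result$stage_counts, file.path(out_dir, "stage_counts.tsv"))
  render_report(result$qc, out_dir)
  jsonlite::write_json(result$provenance[c("config", "config_hash",
                                           "n_input_rows", "package_version")],
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dia_pipeline <- function(x, ...) {
  cat(sprintf("<dia_pipeline> %d proteins x %d runs; stages: %s\n",
              nrow(x$protein_matrix$values), ncol(x$protein_matrix$values),
              paste(x$stage_counts$stage, collapse = " -> ")))
  invisible(x)
}

#' @export
glance.dia_pipeline <- function(x, ...) {
  tibble(n_proteins = nrow(x$protein_matrix$values),
         n_runs = ncol(x$protein_matrix$values),
         cv_total_median = x$qc$cv$total_median,
         cv_total_median_corrected = x$qc$cv$total_median_corrected,
         cv_reduction_percent = x$qc$cv$reduction_percent %||% NA_real_)
}
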