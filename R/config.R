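#' Pipeline configuration
#'
#' Stage toggles and parameters of [run_pipeline()]. Defaults follow the
#' package's reference workflow: median Qvalue filtering at 1% FDR, robust-sum
#' normalization with 10% tails, QC-anchored empirical-Bayes batch correction
#' with parametric shrinkage, correlation-based peptide selection at
#' `rho_min = 0.5`, geometric rollup.
#'
#' @param filter_mode Qvalue policy (`"median"`, `"sparse"`, `"complete"`,
#'   `"percentile"`) or `"none"` to skip filtering.
#' @param qvalue_cutoff Qvalue threshold in (0, 1].
#' @param percentile_fraction Passing fraction for the percentile policy.
#' @param normalize Run robust-sum normalization?
#' @param pool_fraction Tail fraction removed from the normalization pool.
#' @param correction `"combat"`, `"sva"` or `"none"` (the two correction modes
#'   are mutually exclusive per pipeline run).
#' @param shrink Empirical-Bayes shrinkage for the combat mode.
#' @param covariate Design column holding the biological covariate (e.g.
#'   genotype); combined with the QC flag into the condition covariate that
#'   anchors the correction.
#' @param sva_k Number of surrogates (or `"auto"`) for the sva mode.
#' @param control_fraction Control-feature fraction for the sva mode.
#' @param select_peptides Run correlation-based peptide selection?
#' @param rho_min Minimum mean pairwise correlation for quantifier peptides.
#' @param min_overlap Minimum shared runs per correlation pair.
#' @param min_present_fraction Rollup presence threshold per (protein, run).
#' @param min_peptides Minimum selected peptides for a protein to be reported.
#' @param seed Seed for the pipeline's stochastic components (surrogate-count
#'   permutations).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter_mode = "median",
                            qvalue_cutoff = 0.01,
                            percentile_fraction = 0.1,
                            normalize = TRUE,
                            pool_fraction = 0.10,
                            correction = c("combat", "sva", "none"),
                            shrink = TRUE,
                            covariate = "strain",
                            sva_k = 1L,
                            control_fraction = 0.5,
                            select_peptides = TRUE,
                            rho_min = 0.5,
                            min_overlap = 6L,
                            min_present_fraction = 0.5,
                            min_peptides = 1L,
                            seed = 1L) {
  correction <- match.arg(correction)
  if (!filter_mode %in% c("none", "sparse", "complete", "percentile", "median")) {
    abort(sprintf("Unknown filter mode '%s'.", filter_mode))
  }
  assert_scalar_number(qvalue_cutoff, "qvalue_cutoff", lower = 1e-12, upper = 1)
  assert_scalar_number(pool_fraction, "pool_fraction", lower = 0, upper = 0.49)
  assert_scalar_number(control_fraction, "control_fraction",
                       lower = 1e-6, upper = 1 - 1e-9)
  assert_scalar_number(min_present_fraction, "min_present_fraction",
                       lower = 0, upper = 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> filter=%s(%.3g) normalize=%s correction=%s select=%s seed=%d\n",
              x$filter_mode, x$qvalue_cutoff, x$normalize, x$correction,
              x$select_peptides, x$seed))
  invisible(x)
}
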