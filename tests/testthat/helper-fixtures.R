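# fixtures are built in code; nothing is read from disk except the shipped
# iRT reference table

# quick quant_matrix from a bare matrix; features map to themselves unless a
# protein vector is given
make_qm <- function(values, scale = "log2", proteins = NULL) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("r%02d", seq_len(ncol(values)))
  mapping <- tibble::tibble(precursor_id = rownames(values),
                            protein_id = proteins %||% rownames(values))
  quant_matrix(values, scale, mapping)
}

`%||%` <- rlang::`%||%`

# minimal long report: intensities and qvalues given as precursor x run matrices
report_from_matrices <- function(intensity, qvalue = NULL, rt = NULL,
                                 proteins = NULL, is_standard = FALSE) {
  if (is.null(qvalue)) qvalue <- matrix(0.001, nrow(intensity), ncol(intensity))
  idx <- which(!is.na(intensity), arr.ind = TRUE)
  tibble::tibble(
    run_id = colnames(intensity)[idx[, "col"]],
    precursor_id = rownames(intensity)[idx[, "row"]],
    protein_id = (proteins %||% rownames(intensity))[idx[, "row"]],
    intensity = intensity[idx],
    qvalue = qvalue[idx],
    rt_observed = if (is.null(rt)) NA_real_ else rt[idx],
    is_standard = is_standard
  )
}

# two-batch design for n runs, with a genotype covariate and optional QC runs
toy_design <- function(n, n_batches = 2, qc_every = 0, covariate_levels = 2) {
  qc <- if (qc_every > 0) seq_len(n) %% qc_every == 0 else rep(FALSE, n)
  tibble::tibble(
    run_id = sprintf("r%02d", seq_len(n)),
    batch = sprintf("b%d", ceiling(seq_len(n) / (n / n_batches))),
    acq_order = seq_len(n),
    sample_type = ifelse(qc, "QC", "study"),
    strain = ifelse(qc, "QC", sprintf("g%d", rep_len(seq_len(covariate_levels), n))),
    replicate_id = seq_len(n)
  )
}

# a small simulated cohort shared by several files (built once per session)
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_dia(truth_params(
      n_proteins = 40, n_strains = 6, replicates_per_strain = 4,
      qc_every = c(4, 5), seed = 2024))
  }
  .fixture_cache$small
}

# the full-scale default cohort (38 strains x 8 replicates + QCs, 3 batches)
cohort_sim <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- simulate_dia(truth_params())
  }
  .fixture_cache$cohort
}

# matched cohort without batch effects, for the corrected-vs-clean comparison
cohort_sim_clean <- function() {
  if (is.null(.fixture_cache$clean)) {
    .fixture_cache$clean <- simulate_dia(truth_params(
      batch_add_sd = 0, batch_mult_shape = 1e6))
  }
  .fixture_cache$clean
}
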