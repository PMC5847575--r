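#' Ground-truth parameters for the synthetic DIA cohort
#'
#' Defines the generative model of a multi-batch, QC-interspersed SWATH study:
#' per-feature log2 signal
#' `y = base_g + effect_{p(g),s} + a_{i,g} + d_{i,g} * eps + inj_j`,
#' where `a` and `d` are additive and multiplicative per-(batch, feature) batch
#' effects, `inj_j` a per-run injection scale, and `eps` technical noise whose
#' SD is implied by `tech_cv`. QC runs carry the pooled mean of all strain
#' profiles. Abundance-dependent dropout follows a logistic curve in log2
#' intensity; a small fraction of rows are false identifications carrying large
#' qvalues. Retention times arise from per-feature reference iRT values through
#' a per-run linear map plus apex jitter; the spiked iRT standard peptides are
#' present in every run.
#'
#' Defaults emulate a 38-strain cohort acquired in 3 batches with a QC
#' injection every 10--12 samples (~337 runs in total), within-batch technical
#' CV of 12%, additive batch offsets of 0.18 log2 units (cross-batch QC CV
#' ~17%), and RT jitter of 17.7 s on a 60-min gradient.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Length-3 vector `(min, mode, max)` of the
#'   discrete triangular distribution of peptides per protein.
#' @param n_strains Number of biological strains (genotypes).
#' @param replicates_per_strain Replicates per strain, spread over batches.
#' @param n_batches Number of acquisition batches.
#' @param qc_every Length-2 integer range: a QC sample is inserted after every
#'   `k` study runs, `k` drawn uniformly from this range; each batch also opens
#'   and closes with a QC.
#' @param tech_cv Within-batch technical CV (linear scale fraction).
#' @param batch_add_sd SD (log2 units) of additive batch offsets `a_{i,g}`.
#' @param batch_mult_shape Shape of the inverse-gamma distribution of
#'   multiplicative batch factors `d^2_{i,g}` (mean fixed at 1); larger values
#'   give less dispersion.
#' @param effect_sd SD (log2 units) of protein-level strain effects.
#' @param inj_sd SD (log2 units) of the per-run injection scale (what
#'   robust-sum normalization removes).
#' @param missing_logit_slope,missing_logit_mid Logistic dropout parameters:
#'   probability of detection is `plogis(slope * (y - mid))` in log2 units.
#' @param false_id_rate Fraction of report rows that are false identifications
#'   (qvalue above 0.01).
#' @param rt_gradient_min Gradient length, minutes.
#' @param rt_jitter_sd Apex retention-time jitter SD, seconds.
#' @param rt_slope_sd,rt_intercept_sd SD of the per-run linear RT map's slope
#'   (dimensionless, around 1) and intercept (seconds).
#' @param base_mean,base_sd Mean and SD of protein base abundance (log2 a.u.).
#' @param seed Integer seed; the dataset is a pure function of the parameters.
#' @return A `truth_params` list.
#' @export
truth_params <- function(n_proteins = 250,
                         peptides_per_protein = c(2, 4, 10),
                         n_strains = 38,
                         replicates_per_strain = 8,
                         n_batches = 3,
                         qc_every = c(10, 12),
                         tech_cv = 0.12,
                         batch_add_sd = 0.18,
                         batch_mult_shape = 50,
                         effect_sd = 0.5,
                         inj_sd = 0.15,
                         missing_logit_slope = 0.8,
                         missing_logit_mid = 10.5,
                         false_id_rate = 0.01,
                         rt_gradient_min = 60,
                         rt_jitter_sd = 17.7,
                         rt_slope_sd = 0.002,
                         rt_intercept_sd = 5,
                         base_mean = 14,
                         base_sd = 2,
                         seed = 42) {
  p <- as.list(environment())
  for (nm in c("n_proteins", "n_strains", "replicates_per_strain", "n_batches")) {
    assert_scalar_number(p[[nm]], nm, lower = 1)
  }
  assert_scalar_number(tech_cv, "tech_cv", lower = 0, upper = 0.999)
  assert_scalar_number(false_id_rate, "false_id_rate", lower = 0, upper = 0.999)
  if (length(qc_every) == 1L) qc_every <- rep(qc_every, 2L)
  if (min(qc_every) < 2) abort("`qc_every` must be >= 2.")
  p$qc_every <- qc_every
  if (length(peptides_per_protein) != 3L ||
      is.unsorted(peptides_per_protein) || peptides_per_protein[1] < 1) {
    abort("`peptides_per_protein` must be (min, mode, max) with min >= 1.")
  }
  structure(p, class = "truth_params")
}

# discrete triangular draw on min..max peaking at mode
draw_triangular <- function(n, mmm) {
  support <- seq(mmm[1], mmm[3])
  w <- pmin(support - mmm[1] + 1, mmm[3] - support + 1)
  w <- w * ifelse(support <= mmm[2],
                  (support - mmm[1] + 1) / (mmm[2] - mmm[1] + 1),
                  (mmm[3] - support + 1) / (mmm[3] - mmm[2] + 1))
  sample(support, n, replace = TRUE, prob = w)
}

# acquisition layout: per batch, QC at the start, after every k study runs
# (k ~ U{qc_every}), and at the end
build_design <- function(params) {
  strains <- sprintf("strain_%02d", seq_len(params$n_strains))
  study <- tidyr::expand_grid(strain = strains,
                              replicate_id = seq_len(params$replicates_per_strain))
  study$batch <- sprintf("batch_%d",
                         (study$replicate_id - 1L) %% params$n_batches + 1L)
  rows <- list()
  qc_counter <- 0L
  for (b in sort(unique(study$batch))) {
    sb <- study[study$batch == b, ]
    sb <- sb[sample.int(nrow(sb)), ]
    add_qc <- function() {
      qc_counter <<- qc_counter + 1L
      tibble(strain = "QC", replicate_id = qc_counter, batch = b,
             sample_type = "QC")
    }
    rows[[length(rows) + 1L]] <- add_qc()
    i <- 0L
    gap <- sample(seq(params$qc_every[1], params$qc_every[2]), 1L)
    since_qc <- 0L
    while (i < nrow(sb)) {
      i <- i + 1L
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(sb[i, ], sample_type = "study")
      since_qc <- since_qc + 1L
      if (since_qc >= gap && i < nrow(sb)) {
        rows[[length(rows) + 1L]] <- add_qc()
        since_qc <- 0L
        gap <- sample(seq(params$qc_every[1], params$qc_every[2]), 1L)
      }
    }
    rows[[length(rows) + 1L]] <- add_qc()
  }
  design <- dplyr::bind_rows(rows)
  design$acq_order <- seq_len(nrow(design))
  design$run_id <- sprintf("run_%03d", design$acq_order)
  design[c("run_id", "batch", "acq_order", "sample_type", "strain", "replicate_id")]
}

#' Simulate a synthetic DIA cohort with known ground truth
#'
#' Generates a long precursor report, a sample design, and the full generative
#' truth (base abundances, strain effects, per-(batch, feature) batch effects,
#' per-run injection scales and RT maps, true/false identification labels).
#' The result is a pure function of `params` (including its seed).
#'
#' @param params A [truth_params()] object.
#' @return A `dia_simulation` list with elements `report` (long-report tibble),
#'   `design` (design tibble) and `truth`.
#' @examples
#' sim <- simulate_dia(truth_params(n_proteins = 10, n_strains = 4,
#'                                  replicates_per_strain = 3, seed = 1))
#' dplyr::count(sim$design, sample_type)
#' @export
simulate_dia <- function(params) {
  stopifnot(inherits(params, "truth_params"))
  withr::with_seed(params$seed, simulate_dia_impl(params))
}

simulate_dia_impl <- function(params) {
  design <- build_design(params)
  n_runs <- nrow(design)
  strains <- sort(unique(design$strain[design$sample_type == "study"]))

  # feature table: proteins, peptides per protein, precursor m/z and iRT
  n_pep <- draw_triangular(params$n_proteins, params$peptides_per_protein)
  proteins <- sprintf("P%04d", seq_len(params$n_proteins))
  peptide <- tibble(
    protein_id = rep(proteins, n_pep),
    precursor_id = unlist(lapply(seq_len(params$n_proteins), function(i) {
      sprintf("%s_pep%02d/2", proteins[i], seq_len(n_pep[i]))
    }))
  )
  protein_base <- stats::rnorm(params$n_proteins, params$base_mean, params$base_sd)
  names(protein_base) <- proteins
  peptide$base <- protein_base[peptide$protein_id] + stats::rnorm(nrow(peptide), 0, 1)
  peptide$mz <- pmin(400 + stats::rgamma(nrow(peptide), shape = 2.5, scale = 110),
                     1250)
  peptide$irt <- stats::runif(nrow(peptide), -20, 110)
  peptide$is_standard <- FALSE

  standards <- irt_reference()
  standards_tbl <- tibble(
    protein_id = "iRT_standard",
    precursor_id = paste0(standards$peptide_id, "/2"),
    base = stats::rnorm(nrow(standards), 16, 0.5),
    mz = stats::runif(nrow(standards), 450, 800),
    irt = standards$irt,
    is_standard = TRUE
  )
  features <- dplyr::bind_rows(peptide, standards_tbl)
  G <- nrow(features)

  # strain effects at the protein level so peptides of one protein co-vary
  strain_eff <- matrix(stats::rnorm(params$n_proteins * length(strains),
                                    0, params$effect_sd),
                       nrow = params$n_proteins,
                       dimnames = list(proteins, strains))
  qc_eff <- rowMeans(strain_eff)

  batches <- sort(unique(design$batch))
  batch_add <- matrix(stats::rnorm(G * length(batches), 0, params$batch_add_sd),
                      nrow = G, dimnames = list(features$precursor_id, batches))
  # d^2 ~ inverse-gamma with mean 1 (the prior family the corrector assumes)
  batch_mult2 <- matrix((params$batch_mult_shape - 1) /
                          stats::rgamma(G * length(batches),
                                        shape = params$batch_mult_shape, rate = 1),
                        nrow = G, dimnames = list(features$precursor_id, batches))
  batch_add[features$is_standard, ] <- 0   # spiked standards see no batch effect
  batch_mult2[features$is_standard, ] <- 1

  inj <- stats::rnorm(n_runs, 0, params$inj_sd)
  sigma_t <- cv_to_sigma_log2(params$tech_cv)

  # per-run RT map over iRT units: rt = slope_irt * irt + intercept_irt + jitter
  grad_sec <- params$rt_gradient_min * 60
  c2 <- 0.94 * grad_sec / 140        # seconds per iRT unit (iRT -25..115)
  c1 <- 0.03 * grad_sec + 25 * c2
  run_slope <- stats::rnorm(n_runs, 1, params$rt_slope_sd)
  run_int <- stats::rnorm(n_runs, 0, params$rt_intercept_sd)
  slope_irt <- run_slope * c2
  intercept_irt <- run_slope * c1 + run_int

  # feature effect per run (strain or pooled-QC profile), expanded to peptides
  prot_idx <- match(features$protein_id, proteins)   # NA for standards
  eff_run <- matrix(0, nrow = G, ncol = n_runs)
  for (j in seq_len(n_runs)) {
    e <- if (design$sample_type[j] == "QC") qc_eff else strain_eff[, design$strain[j]]
    eff_run[, j] <- ifelse(is.na(prot_idx), 0, e[prot_idx])
  }

  bi <- match(design$batch, batches)
  eps <- matrix(stats::rnorm(G * n_runs, 0, sigma_t), nrow = G)
  y <- features$base + eff_run +
    batch_add[, bi, drop = FALSE] +
    sqrt(batch_mult2[, bi, drop = FALSE]) * eps +
    matrix(inj, nrow = G, ncol = n_runs, byrow = TRUE)
  dimnames(y) <- list(features$precursor_id, design$run_id)

  # abundance-dependent dropout (standards always detected)
  p_detect <- stats::plogis(params$missing_logit_slope * (y - params$missing_logit_mid))
  detected <- matrix(stats::runif(G * n_runs) < p_detect, nrow = G)
  detected[features$is_standard, ] <- TRUE

  # qvalues: true IDs below 0.01, false IDs above
  is_false <- matrix(stats::runif(G * n_runs) < params$false_id_rate, nrow = G)
  is_false[features$is_standard, ] <- FALSE
  qv <- matrix(10^stats::runif(G * n_runs, -5, log10(0.01)), nrow = G)
  qv_false <- matrix(stats::runif(G * n_runs, 0.02, 1), nrow = G)
  qv[is_false] <- qv_false[is_false]

  rt <- outer(features$irt, slope_irt) +
    matrix(intercept_irt, nrow = G, ncol = n_runs, byrow = TRUE) +
    matrix(stats::rnorm(G * n_runs, 0, params$rt_jitter_sd), nrow = G)

  idx <- which(detected, arr.ind = TRUE)
  report <- tibble(
    run_id = design$run_id[idx[, "col"]],
    precursor_id = features$precursor_id[idx[, "row"]],
    protein_id = features$protein_id[idx[, "row"]],
    intensity = 2^y[idx],
    qvalue = qv[idx],
    rt_observed = rt[idx],
    is_standard = features$is_standard[idx[, "row"]]
  )
  report <- dplyr::arrange(report, match(.data$run_id, design$run_id),
                           .data$precursor_id)

  truth <- list(
    params = params,
    features = features,
    protein_base = tibble(protein_id = proteins, base = unname(protein_base)),
    strain_effects = strain_eff,
    batch_additive = batch_add,
    batch_mult2 = batch_mult2,
    run_effects = tibble(
      run_id = design$run_id, injection = inj,
      rt_slope_irt = slope_irt, rt_intercept_irt = intercept_irt
    ),
    false_ids = tibble(
      run_id = design$run_id[which(is_false & detected, arr.ind = TRUE)[, "col"]],
      precursor_id = features$precursor_id[
        which(is_false & detected, arr.ind = TRUE)[, "row"]]
    ),
    sigma_tech_log2 = sigma_t
  )
  structure(list(report = report, design = design, truth = truth),
            class = "dia_simulation")
}

#' @export
print.dia_simulation <- function(x, ...) {
  cat(sprintf("<dia_simulation> %d runs (%d QC) in %d batches, %d precursors, %d proteins\n",
              nrow(x$design), sum(x$design$sample_type == "QC"),
              dplyr::n_distinct(x$design$batch),
              nrow(x$truth$features),
              dplyr::n_distinct(x$truth$features$protein_id)))
  invisible(x)
}

#' Expected QC coefficients of variation implied by the generative truth
#'
#' Closed-form linear-scale CVs from the generating SDs, per feature: the
#' intra-batch QC CV reflects technical noise (scaled by the batch's
#' multiplicative factor) plus injection variability; the cross-batch QC CV
#' additionally carries the spread of the realized additive batch offsets.
#' For a log2-normal signal with log2 SD `s`, CV = sqrt(exp((s ln 2)^2) - 1).
#'
#' @param sim A [simulate_dia()] result with at least 2 QC runs.
#' @return A tibble with one row per (feature, batch): `expected_intra_cv`,
#'   plus the feature-level `expected_cross_cv` (repeated within feature),
#'   in percent.
#' @export
truth_cv <- function(sim) {
  stopifnot(inherits(sim, "dia_simulation"))
  design <- sim$design
  qc <- design[design$sample_type == "QC", ]
  if (nrow(qc) < 2) abort("Need at least 2 QC runs.")
  p <- sim$truth$params
  sigma_t <- sim$truth$sigma_tech_log2
  batches <- colnames(sim$truth$batch_additive)
  w <- as.numeric(table(factor(qc$batch, levels = batches)))
  w <- w / sum(w)
  add <- sim$truth$batch_additive
  mult2 <- sim$truth$batch_mult2
  intra_sd <- sqrt(mult2 * sigma_t^2 + p$inj_sd^2)
  abar <- drop(add %*% w)
  cross_var <- drop((add - abar)^2 %*% w) + drop(mult2 %*% w) * sigma_t^2 +
    p$inj_sd^2
  out <- tidyr::expand_grid(precursor_id = rownames(add), batch = batches)
  out$expected_intra_cv <- unname(100 * lognormal_cv(intra_sd[cbind(
    match(out$precursor_id, rownames(add)), match(out$batch, batches))]))
  out$expected_cross_cv <- unname(100 * lognormal_cv(
    sqrt(cross_var)[match(out$precursor_id, rownames(add))]))
  out
}

#' Reference iRT values of the spiked standard peptides
#'
#' The 11-peptide retention-time standard kit with its fixed dimensionless iRT
#' values, used to calibrate chromatographic time linearly between runs.
#'
#' @return A tibble with `peptide_id` and `irt`.
#' @export
irt_reference <- function() {
  path <- system.file("extdata", "irt_reference.tsv", package = "diaq",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cd", progress = FALSE)
}
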