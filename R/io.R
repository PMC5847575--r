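#' Column-name dialects for long precursor reports
#'
#' Extracted DIA reports use tool- and version-dependent column headers. A
#' dialect maps the package's canonical column names to the names found in a
#' file. Two presets ship with the package; any named character vector with the
#' same canonical names works as a user-supplied dialect.
#'
#' Canonical columns: `run_id`, `precursor_id`, `protein_id`, `intensity`,
#' `qvalue`, `rt_observed` (seconds), `is_standard`.
#'
#' @return A named list of dialects, each a named character vector
#'   `canonical -> file column`.
#' @examples
#' names(dia_dialects())
#' dia_dialects()$spectronaut
#' @export
dia_dialects <- function() {
  list(
    canonical = c(
      run_id = "run_id", precursor_id = "precursor_id",
      protein_id = "protein_id", intensity = "intensity",
      qvalue = "qvalue", rt_observed = "rt_observed",
      is_standard = "is_standard"
    ),
    spectronaut = c(
      run_id = "R.FileName", precursor_id = "EG.PrecursorId",
      protein_id = "PG.ProteinAccessions", intensity = "FG.Quantity",
      qvalue = "EG.Qvalue", rt_observed = "EG.ApexRT",
      is_standard = "EG.IsReference"
    )
  )
}

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L) {
    presets <- dia_dialects()
    if (!dialect %in% names(presets)) {
      abort(sprintf("Unknown dialect preset '%s'. Available: %s.",
                    dialect, paste(names(presets), collapse = ", ")))
    }
    return(presets[[dialect]])
  }
  needed <- names(dia_dialects()$canonical)
  if (!is.character(dialect) || !all(needed %in% names(dialect))) {
    abort(sprintf("A dialect must name all canonical columns: %s.",
                  paste(needed, collapse = ", ")))
  }
  dialect[needed]
}

#' Read a long-format precursor report
#'
#' Reads a tab-separated report with one row per (run, precursor), renames
#' columns to the canonical schema via a dialect, coerces types, and validates
#' the result. Rows whose intensity, qvalue or retention time fail to parse as
#' numbers are dropped and counted; empty strings and `"NA"` are both read as
#' missing.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect A preset name (see [dia_dialects()]) or a named character
#'   vector mapping canonical column names to file column names.
#' @return A validated long-report tibble with canonical columns. The read
#'   summary (rows kept/dropped, number of runs and precursors) is attached as
#'   attribute `"read_summary"`.
#' @export
read_long_report <- function(path, dialect = "canonical") {
  map <- resolve_dialect(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("Empty report file: %s", path))
  miss <- map[!map %in% names(raw)]
  if (length(miss)) {
    abort(sprintf("Report is missing mandatory column(s): %s.",
                  paste(sprintf("%s (canonical '%s')", miss, names(miss)),
                        collapse = ", ")))
  }
  df <- tibble(
    run_id       = raw[[map[["run_id"]]]],
    precursor_id = raw[[map[["precursor_id"]]]],
    protein_id   = raw[[map[["protein_id"]]]],
    intensity    = suppressWarnings(as.numeric(raw[[map[["intensity"]]]])),
    qvalue       = suppressWarnings(as.numeric(raw[[map[["qvalue"]]]])),
    rt_observed  = suppressWarnings(as.numeric(raw[[map[["rt_observed"]]]])),
    is_standard  = parse_logical_col(raw[[map[["is_standard"]]]])
  )
  # unparseable numerics: original cell non-missing but coercion gave NA
  bad <- (!is.na(raw[[map[["intensity"]]]]) & is.na(df$intensity)) |
    (!is.na(raw[[map[["qvalue"]]]]) & is.na(df$qvalue)) |
    (!is.na(raw[[map[["rt_observed"]]]]) & is.na(df$rt_observed))
  dropped <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  df <- validate_long_report(df)
  summary <- list(rows_kept = nrow(df), rows_dropped = dropped,
                  n_runs = dplyr::n_distinct(df$run_id),
                  n_precursors = dplyr::n_distinct(df$precursor_id))
  inform(sprintf("Read %d rows (%d dropped as unparseable): %d runs, %d precursors.",
                 summary$rows_kept, summary$rows_dropped,
                 summary$n_runs, summary$n_precursors))
  attr(df, "read_summary") <- summary
  df
}

parse_logical_col <- function(x) {
  if (is.null(x)) return(rep(FALSE, 0L))
  out <- tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
  out[is.na(x)] <- FALSE
  out
}

#' Validate a long precursor report
#'
#' Checks the canonical schema and its invariants: unique (run, precursor)
#' pairs, non-negative intensities, qvalues in \[0, 1\] and present wherever an
#' intensity is present, and at least one run.
#'
#' @param report A data frame with canonical long-report columns.
#' @return The report as a tibble, invisibly validated.
#' @export
validate_long_report <- function(report) {
  assert_columns(report, c("run_id", "precursor_id", "protein_id",
                           "intensity", "qvalue"), "Long report")
  report <- as_tibble(report)
  if (!"rt_observed" %in% names(report)) report$rt_observed <- NA_real_
  if (!"is_standard" %in% names(report)) report$is_standard <- FALSE
  if (nrow(report) == 0L) abort("Long report has no rows.")
  dup <- duplicated(report[c("run_id", "precursor_id")])
  if (any(dup)) {
    abort(sprintf("Duplicate (run_id, precursor_id) pairs, e.g. (%s, %s).",
                  report$run_id[dup][1], report$precursor_id[dup][1]))
  }
  if (any(report$intensity < 0, na.rm = TRUE)) {
    abort("Intensities must be non-negative.")
  }
  if (any(report$qvalue < 0 | report$qvalue > 1, na.rm = TRUE)) {
    abort("Qvalues must lie in [0, 1].")
  }
  orphan <- !is.na(report$intensity) & is.na(report$qvalue)
  if (any(orphan)) {
    abort(sprintf("%d row(s) have an intensity but no qvalue.", sum(orphan)))
  }
  report
}

#' Read a sample-design table
#'
#' Reads the per-run design: acquisition batch and order, sample type
#' (`"QC"` or `"study"`), biological covariates (any additional columns,
#' e.g. `strain`), and replicate index.
#'
#' @param path Path to a tab-separated file with columns `run_id`, `batch`,
#'   `acq_order`, `sample_type`, `replicate_id` plus covariate columns.
#' @return A validated design tibble ordered by `acq_order`.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, na = c("", "NA"), progress = FALSE,
                        show_col_types = FALSE)
  validate_sample_design(df)
}

#' Validate a sample-design table
#'
#' @param design A data frame with columns `run_id`, `batch`, `acq_order`,
#'   `sample_type` and optionally `replicate_id` plus covariates.
#' @param require_qc If `TRUE`, additionally require at least 2 QC runs per
#'   batch (needed by QC-anchored batch correction).
#' @return The design as a tibble, sorted by acquisition order.
#' @export
validate_sample_design <- function(design, require_qc = FALSE) {
  assert_columns(design, c("run_id", "batch", "acq_order", "sample_type"),
                 "Sample design")
  design <- as_tibble(design)
  if (anyDuplicated(design$run_id)) abort("Design run ids must be unique.")
  if (!all(design$sample_type %in% c("QC", "study"))) {
    abort("`sample_type` must be 'QC' or 'study'.")
  }
  if (any(design$acq_order < 1 | design$acq_order != round(design$acq_order))) {
    abort("`acq_order` must be positive integers.")
  }
  design$batch <- as.character(design$batch)
  if (require_qc) {
    qc <- table(design$batch[design$sample_type == "QC"])
    bad <- setdiff(unique(design$batch),
                   names(qc)[qc >= 2])
    if (length(bad)) {
      abort(sprintf("QC-anchored correction needs >= 2 QC runs per batch; batch(es) %s do not comply.",
                    paste(bad, collapse = ", ")))
    }
  }
  dplyr::arrange(design, .data$acq_order)
}

#' Write a design or report tibble as TSV
#'
#' Missing values are written as `"NA"`.
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dia_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}
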