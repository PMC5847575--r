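#' Construct a quantification matrix
#'
#' A `quant_matrix` holds a precursors-by-runs intensity matrix together with
#' its scale (`"linear"` or `"log2"`), the precursor-to-protein map, and the
#' run order. It is the working container of the matrix-shaped pipeline stages
#' (normalization, batch correction, rollup); [pivot_to_matrix()] and
#' [matrix_to_long()] convert to and from the tidy long report.
#'
#' @param values Numeric matrix, one row per precursor (rownames), one column
#'   per run (colnames). Missing cells are `NA`.
#' @param scale `"linear"` (values >= 0) or `"log2"` (finite where present).
#' @param mapping Tibble with columns `precursor_id`, `protein_id` covering all
#'   rows.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, scale = c("linear", "log2"), mapping) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must be a matrix with row and column names.")
  }
  if (anyDuplicated(rownames(values))) abort("Row (precursor) ids must be unique.")
  if (anyDuplicated(colnames(values))) abort("Column (run) ids must be unique.")
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    abort("Linear-scale values must be non-negative.")
  }
  if (scale == "log2" && any(!is.finite(values) & !is.na(values))) {
    abort("log2-scale values must be finite where present.")
  }
  assert_columns(mapping, c("precursor_id", "protein_id"), "Precursor mapping")
  mapping <- dplyr::distinct(as_tibble(mapping[c("precursor_id", "protein_id")]))
  missing_map <- setdiff(rownames(values), mapping$precursor_id)
  if (length(missing_map)) {
    abort(sprintf("Mapping lacks %d precursor(s), e.g. %s.",
                  length(missing_map), missing_map[1]))
  }
  structure(
    list(values = values, scale = scale,
         mapping = mapping[match(rownames(values), mapping$precursor_id), ],
         run_order = colnames(values)),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d precursors x %d runs (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Pivot a long report to a quantification matrix
#'
#' One row per precursor, one column per run (runs in first-appearance order
#' unless `run_order` is given). With `scale = "log2"`, strictly positive
#' intensities are log2-transformed; zeros denote non-detection in DIA reports
#' and become missing, with a message stating the count.
#'
#' @param report A long-report tibble (see [read_long_report()]).
#' @param scale Output scale, `"linear"` or `"log2"`.
#' @param run_order Optional character vector fixing the column order.
#' @return A [quant_matrix()].
#' @export
pivot_to_matrix <- function(report, scale = c("linear", "log2"), run_order = NULL) {
  scale <- match.arg(scale)
  report <- validate_long_report(report)
  runs <- run_order %||% unique(report$run_id)
  if (!all(report$run_id %in% runs)) abort("`run_order` must cover all runs.")
  precs <- unique(report$precursor_id)
  m <- matrix(NA_real_, nrow = length(precs), ncol = length(runs),
              dimnames = list(precs, runs))
  m[cbind(match(report$precursor_id, precs), match(report$run_id, runs))] <-
    report$intensity
  if (scale == "log2") {
    zeros <- sum(m == 0, na.rm = TRUE)
    if (zeros > 0) {
      inform(sprintf("%d zero intensit%s treated as missing on log2 transform.",
                     zeros, if (zeros == 1) "y" else "ies"))
      m[m == 0] <- NA_real_
    }
    m <- log2(m)
  }
  mapping <- dplyr::distinct(report[c("precursor_id", "protein_id")])
  quant_matrix(m, scale, mapping)
}

#' Un-pivot a quantification matrix to tidy rows
#'
#' Inverse of [pivot_to_matrix()] up to row ordering: missing cells produce no
#' row. log2 matrices are returned on the log2 scale in the `intensity` column
#' (column `scale` records it).
#'
#' @param qm A [quant_matrix()].
#' @return A tibble with `run_id`, `precursor_id`, `protein_id`, `intensity`,
#'   `scale`.
#' @export
matrix_to_long <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  idx <- which(!is.na(qm$values), arr.ind = TRUE)
  tibble(
    run_id = colnames(qm$values)[idx[, "col"]],
    precursor_id = rownames(qm$values)[idx[, "row"]],
    protein_id = qm$mapping$protein_id[idx[, "row"]],
    intensity = qm$values[idx],
    scale = qm$scale
  )
}

#' @export
as_tibble.quant_matrix <- function(x, ...) matrix_to_long(x)

#' Write a quantification matrix as TSV
#'
#' Rows are features; the first column holds the feature id. Missing cells are
#' written as `"NA"`. Values round-trip bit-identically through
#' [read_quant_matrix()] (full double precision).
#'
#' @param qm A [quant_matrix()] (or a plain feature matrix such as a protein
#'   matrix).
#' @param path Output path.
#' @param id_column Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(qm, path, id_column = "precursor_id") {
  values <- if (inherits(qm, "quant_matrix")) qm$values else qm
  df <- as_tibble(values, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(!!id_column := rownames(values)), df)
  # format with full precision so the round trip is exact
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a quantification matrix from TSV
#'
#' @param path File written by [write_quant_matrix()].
#' @param scale Scale of the stored values.
#' @param mapping Optional precursor-to-protein tibble; defaults to mapping
#'   every feature to itself (useful for protein matrices).
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path, scale = c("linear", "log2"), mapping = NULL) {
  scale <- match.arg(scale)
  # base strtod parsing guarantees the %.17g round trip is bit-exact
  df <- utils::read.delim(path, na.strings = c("", "NA"), check.names = FALSE,
                          colClasses = "character")
  ids <- as.character(df[[1]])
  raw <- as.matrix(df[-1])
  m <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw),
              dimnames = list(ids, colnames(raw)))
  if (is.null(mapping)) mapping <- tibble(precursor_id = ids, protein_id = ids)
  quant_matrix(m, scale, mapping)
}

# subset a quant_matrix by row ids, keeping metadata in step
subset_features <- function(qm, keep) {
  quant_matrix(qm$values[keep, , drop = FALSE], qm$scale, qm$mapping)
}

# switch scale of a quant_matrix
to_scale <- function(qm, scale) {
  if (qm$scale == scale) return(qm)
  v <- qm$values
  if (scale == "log2") {
    v[v == 0] <- NA_real_
    v <- log2(v)
  } else {
    v <- 2^v
  }
  quant_matrix(v, scale, qm$mapping)
}
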