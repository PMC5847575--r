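#' Robust-sum injection normalization
#'
#' Corrects run-to-run injection differences by equalizing a robust total
#' signal. Precursors are ranked by their cross-run median relative intensity
#' (intensities divided by the run median first, so that the reference pool
#' does not depend on per-run scale); the most
#' and least intense `pool_fraction` of precursors are excluded, and the
#' remaining reference pool is further restricted to precursors quantified in
#' every run so that each run's robust sum `S_r` adds the same members. Each
#' run is rescaled by `f_r = median(S) / S_r` (the lower median, i.e. the
#' robust sum of the median run), after which all robust sums are equal (to
#' 1e-9 relative). The operation is idempotent, and rescaling a run's raw
#' intensities leaves the normalized output unchanged whenever the identity
#' of the median run is preserved.
#'
#' @param qm A linear-scale [quant_matrix()] with at least 10 precursors
#'   quantified in at least half of the runs.
#' @param pool_fraction Fraction removed from each tail of the ranked
#'   precursors, default 0.10. Ties at the pool boundary break by precursor id.
#' @return A `robust_sum` list: `matrix` (normalized [quant_matrix()]),
#'   `factors` (tibble `run_id`, `robust_sum`, `factor`), `pool` (precursor
#'   ids of the reference pool).
#' @export
robust_sum_normalize <- function(qm, pool_fraction = 0.10) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "linear") abort("Robust-sum normalization expects a linear-scale matrix.")
  assert_scalar_number(pool_fraction, "pool_fraction", lower = 0, upper = 0.49)
  v <- qm$values
  present_frac <- rowMeans(!is.na(v))
  if (sum(present_frac >= 0.5) < 10L) {
    abort("Need >= 10 precursors quantified in >= 50% of runs.")
  }
  # rank on run-median-normalized intensities so the pool is invariant under
  # per-run rescaling (which makes the operation idempotent)
  run_med <- apply(v, 2L, median, na.rm = TRUE)
  med <- apply(sweep(v, 2L, run_med, `/`), 1L, median, na.rm = TRUE)
  ord <- order(med, rownames(v))   # deterministic tie-break by precursor id
  n <- length(ord)
  n_tail <- floor(n * pool_fraction)
  pool_ids <- rownames(v)[ord][seq.int(n_tail + 1L, n - n_tail)]
  complete <- rownames(v)[rowSums(is.na(v)) == 0L]
  pool_ids <- intersect(pool_ids, complete)
  if (length(pool_ids) == 0L) {
    abort(paste("Reference pool is empty after restricting to precursors",
                "present in all runs; decrease `pool_fraction` or filter for",
                "completeness first."))
  }
  s <- colSums(v[pool_ids, , drop = FALSE])
  # lower median: the target is an actual run's robust sum, so rescaling a
  # non-median run leaves every normalized value unchanged
  target <- sort(s)[ceiling(length(s) / 2)]
  f <- target / s
  out <- sweep(v, 2L, f, `*`)
  structure(
    list(matrix = quant_matrix(out, "linear", qm$mapping),
         factors = tibble(run_id = colnames(v), robust_sum = unname(s),
                          factor = unname(f)),
         pool = pool_ids,
         pool_fraction = pool_fraction),
    class = "robust_sum"
  )
}

#' @export
print.robust_sum <- function(x, ...) {
  cat(sprintf("<robust_sum> pool of %d precursors; factors in [%.3f, %.3f]\n",
              length(x$pool), min(x$factors$factor), max(x$factors$factor)))
  invisible(x)
}

#' @export
tidy.robust_sum <- function(x, ...) x$factors

#' @export
glance.robust_sum <- function(x, ...) {
  tibble(pool_size = length(x$pool), pool_fraction = x$pool_fraction,
         factor_min = min(x$factors$factor),
         factor_max = max(x$factors$factor),
         factor_cv_percent = cv_percent(x$factors$factor))
}
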