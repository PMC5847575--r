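#' Qvalue filter policy
#'
#' The four precursor-level completeness policies compared on large DIA
#' cohorts. With `n` the number of runs in the cohort and "passing" meaning a
#' measured qvalue at or below `qvalue_cutoff` (a missing qvalue fails):
#'
#' * `sparse`: keep a precursor if it passes in at least one run,
#' * `complete`: keep only precursors measured in every run and passing in all,
#' * `percentile`: keep if the fraction of runs passing is at least
#'   `percentile_fraction`,
#' * `median`: keep if at least half of the runs pass — the lower-median
#'   reading of "median qvalue <= cutoff", identical to `percentile` with
#'   fraction 0.5.
#'
#' For a fixed cutoff the kept sets nest:
#' complete ⊆ median ⊆ percentile(p ≤ 0.5) ⊆ sparse.
#'
#' @param mode One of `"sparse"`, `"complete"`, `"percentile"`, `"median"`.
#' @param qvalue_cutoff Qvalue threshold in (0, 1], default 0.01 (1% FDR).
#' @param percentile_fraction Required passing fraction in (0, 1); only used by
#'   `mode = "percentile"`.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(mode = c("median", "sparse", "complete", "percentile"),
                          qvalue_cutoff = 0.01, percentile_fraction = 0.1) {
  if (!is.character(mode) || !mode[1] %in% c("sparse", "complete", "percentile", "median")) {
    abort(sprintf("Unknown filter mode '%s'.", mode[1]))
  }
  mode <- match.arg(mode)
  assert_scalar_number(qvalue_cutoff, "qvalue_cutoff", lower = 1e-12, upper = 1)
  if (mode == "percentile") {
    assert_scalar_number(percentile_fraction, "percentile_fraction",
                         lower = 1e-12, upper = 1 - 1e-12)
  }
  structure(list(mode = mode, qvalue_cutoff = qvalue_cutoff,
                 percentile_fraction = if (mode == "percentile") percentile_fraction),
            class = "filter_policy")
}

# per-precursor pass statistics over the cohort's runs
precursor_pass_stats <- function(report, cutoff, runs = NULL) {
  runs <- runs %||% unique(report$run_id)
  if (!all(report$run_id %in% runs)) {
    abort("`runs` must cover every run present in the report.")
  }
  n_runs <- length(runs)
  report |>
    dplyr::group_by(precursor_id = .data$precursor_id) |>
    dplyr::summarise(
      n_measured = sum(!is.na(.data$intensity)),
      n_pass = sum(!is.na(.data$qvalue) & .data$qvalue <= cutoff),
      median_qvalue = median(.data$qvalue, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_runs = n_runs, pass_fraction = .data$n_pass / n_runs)
}

#' Filter precursors by a Qvalue policy
#'
#' Applies a [filter_policy()] at the precursor level: a precursor is kept or
#' dropped as a whole, and kept precursors retain their intensities in every
#' run regardless of the per-cell qvalue.
#'
#' @param report A long-report tibble.
#' @param policy A [filter_policy()], or a mode name passed through
#'   [filter_policy()] with default parameters.
#' @param qvalue_cutoff,percentile_fraction Convenience overrides when `policy`
#'   is given as a mode name.
#' @param runs Optional character vector of all cohort run ids (the
#'   denominator of the pass fraction); defaults to the runs present in the
#'   report. Supply it when some run contributed no rows at all.
#' @return The filtered report tibble. The kept precursor ids are attached as
#'   attribute `"kept"`, the applied policy as `"policy"`.
#' @examples
#' sim <- simulate_dia(truth_params(n_proteins = 20, n_strains = 4,
#'                                  replicates_per_strain = 3, seed = 7))
#' nrow(qvalue_filter(sim$report, "median"))
#' @export
qvalue_filter <- function(report, policy = filter_policy("median"),
                          qvalue_cutoff = 0.01, percentile_fraction = 0.1,
                          runs = NULL) {
  if (is.character(policy)) {
    policy <- filter_policy(policy, qvalue_cutoff, percentile_fraction)
  }
  stopifnot(inherits(policy, "filter_policy"))
  report <- validate_long_report(report)
  stats <- precursor_pass_stats(report, policy$qvalue_cutoff, runs)
  kept <- switch(
    policy$mode,
    sparse = stats$n_pass >= 1L,
    complete = stats$n_pass == stats$n_runs & stats$n_measured == stats$n_runs,
    percentile = stats$pass_fraction >= policy$percentile_fraction,
    median = stats$pass_fraction >= 0.5
  )
  kept_ids <- stats$precursor_id[kept]
  out <- report[report$precursor_id %in% kept_ids, , drop = FALSE]
  attr(out, "kept") <- kept_ids
  attr(out, "policy") <- policy
  out
}

#' Per-precursor verdicts under all four filter policies
#'
#' The audit table behind a policy-comparison curve: for every precursor, the
#' pass statistics and the keep/drop verdict of each mode at a common cutoff.
#'
#' @param report A long-report tibble.
#' @param qvalue_cutoff Qvalue threshold, default 0.01.
#' @param percentile_fraction Fraction for the percentile policy, default 0.1.
#' @param runs Optional character vector of all cohort run ids; defaults to
#'   the runs present in the report.
#' @return A tibble with one row per precursor: `n_measured`, `n_pass`,
#'   `median_qvalue`, `pass_fraction` and logical columns `sparse`, `complete`,
#'   `percentile`, `median`.
#' @export
filter_verdicts <- function(report, qvalue_cutoff = 0.01,
                            percentile_fraction = 0.1, runs = NULL) {
  report <- validate_long_report(report)
  stats <- precursor_pass_stats(report, qvalue_cutoff, runs)
  dplyr::mutate(
    stats,
    sparse = .data$n_pass >= 1L,
    complete = .data$n_pass == .data$n_runs & .data$n_measured == .data$n_runs,
    percentile = .data$pass_fraction >= percentile_fraction,
    median = .data$pass_fraction >= 0.5
  )
}
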