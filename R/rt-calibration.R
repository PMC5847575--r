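#' Fit per-run linear retention-time calibrations against iRT standards
#'
#' For every run, regresses the observed apex retention times (seconds) of the
#' detected standard peptides on their reference iRT values by least squares
#' (optionally by the robust median-of-pairwise-slopes estimator). Runs with
#' fewer than 2 detected standards are flagged unfit, never silently dropped.
#'
#' @param report A long-report tibble; standard peptides are the rows with
#'   `is_standard = TRUE`.
#' @param reference Tibble `peptide_id`, `irt` (defaults to the shipped
#'   11-standard kit, [irt_reference()]). Precursor ids are matched to
#'   `peptide_id` after stripping a trailing `/charge` suffix.
#' @param method `"ols"` (default) or `"robust"` (Theil-Sen median slope).
#' @return An `rt_calibration` object; [tidy()] returns the per-run tibble
#'   (`slope` s/iRT, `intercept` s, `residual_sd` s, `n_standards`,
#'   `r_squared`, `fitted`).
#' @export
fit_rt_calibration <- function(report, reference = irt_reference(),
                               method = c("ols", "robust")) {
  method <- match.arg(method)
  report <- validate_long_report(report)
  assert_columns(reference, c("peptide_id", "irt"), "iRT reference")
  std <- report[report$is_standard & !is.na(report$rt_observed), ]
  std$peptide_id <- strip_charge(std$precursor_id)
  std <- dplyr::inner_join(std, reference, by = "peptide_id")
  runs <- unique(report$run_id)
  fits <- lapply(runs, function(r) {
    d <- std[std$run_id == r, ]
    if (nrow(d) < 2L || dplyr::n_distinct(d$irt) < 2L) {
      return(tibble(run_id = r, slope = NA_real_, intercept = NA_real_,
                    slope_se = NA_real_, intercept_se = NA_real_,
                    residual_sd = NA_real_, n_standards = nrow(d),
                    r_squared = NA_real_, fitted = FALSE))
    }
    cf <- if (method == "ols") {
      stats::coef(stats::lm.fit(cbind(1, d$irt), d$rt_observed))
    } else {
      theil_sen(d$irt, d$rt_observed)
    }
    resid <- d$rt_observed - (cf[1] + cf[2] * d$irt)
    rsd <- if (nrow(d) > 2L) sqrt(sum(resid^2) / (nrow(d) - 2L)) else 0
    r2 <- if (stats::var(d$rt_observed) > 0) {
      stats::cor(d$rt_observed, cf[1] + cf[2] * d$irt)^2
    } else NA_real_
    sxx <- sum((d$irt - mean(d$irt))^2)
    tibble(run_id = r, slope = unname(cf[2]), intercept = unname(cf[1]),
           slope_se = rsd / sqrt(sxx),
           intercept_se = rsd * sqrt(1 / nrow(d) + mean(d$irt)^2 / sxx),
           residual_sd = rsd, n_standards = nrow(d), r_squared = r2,
           fitted = TRUE)
  })
  runs_tbl <- dplyr::bind_rows(fits)
  if (!any(runs_tbl$fitted)) {
    abort("No run could be calibrated: every run has < 2 detected standards.")
  }
  structure(list(runs = runs_tbl, reference = as_tibble(reference),
                 method = method),
            class = "rt_calibration")
}

strip_charge <- function(x) sub("/[0-9]+$", "", x)

theil_sen <- function(x, y) {
  pairs <- utils::combn(length(x), 2)
  slopes <- (y[pairs[2, ]] - y[pairs[1, ]]) / (x[pairs[2, ]] - x[pairs[1, ]])
  b <- median(slopes, na.rm = TRUE)
  c(median(y - b * x), b)
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf("<rt_calibration> %d runs (%d fitted, %s), median slope %.2f s/iRT\n",
              nrow(x$runs), sum(x$runs$fitted), x$method,
              median(x$runs$slope, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.rt_calibration <- function(x, ...) x$runs

#' @export
glance.rt_calibration <- function(x, ...) {
  tibble(n_runs = nrow(x$runs), n_fitted = sum(x$runs$fitted),
         median_slope = median(x$runs$slope, na.rm = TRUE),
         median_residual_sd = median(x$runs$residual_sd, na.rm = TRUE),
         method = x$method)
}

#' Map observed retention times to iRT units
#'
#' Inverts a run's fitted linear map: `irt = (rt_observed - intercept) / slope`.
#'
#' @param calibration An [fit_rt_calibration()] result.
#' @param run_id A single run id.
#' @param rt_observed Numeric vector of observed retention times, seconds.
#' @return Numeric vector in iRT units.
#' @export
to_irt <- function(calibration, run_id, rt_observed) {
  stopifnot(inherits(calibration, "rt_calibration"))
  row <- calibration$runs[calibration$runs$run_id == run_id, ]
  if (nrow(row) == 0L) abort(sprintf("Run '%s' not in calibration.", run_id))
  if (!row$fitted) abort(sprintf("Run '%s' is unfit (%d standards).",
                                 run_id, row$n_standards))
  (rt_observed - row$intercept) / row$slope
}

#' Retention-time stability of a cohort
#'
#' Per standard peptide: the sample SD (seconds) and CV (%) of raw apex
#' retention times across runs. Per run: the R-squared of observed versus
#' calibration-predicted retention time over all peptides with a known
#' reference iRT (standards by default; supply `peptide_reference` to include
#' library peptides).
#'
#' @param report A long-report tibble with at least 2 runs.
#' @param calibration Optional [fit_rt_calibration()]; fitted from `report`
#'   when `NULL`.
#' @param reference iRT reference table for the standards.
#' @param peptide_reference Optional tibble `precursor_id`, `irt` giving
#'   reference iRT values for non-standard peptides, used for the per-run
#'   R-squared.
#' @return An `rt_stability` object with `per_standard`, `per_run`, and
#'   cohort summaries; [glance()] returns `mean_sd_seconds`, `max_cv_percent`,
#'   `median_r2`.
#' @export
rt_stability <- function(report, calibration = NULL,
                         reference = irt_reference(),
                         peptide_reference = NULL) {
  report <- validate_long_report(report)
  if (dplyr::n_distinct(report$run_id) < 2L) abort("Need >= 2 runs.")
  if (is.null(calibration)) {
    calibration <- fit_rt_calibration(report, reference)
  }
  std <- report[report$is_standard & !is.na(report$rt_observed), ]
  std$peptide_id <- strip_charge(std$precursor_id)
  std <- std[std$peptide_id %in% reference$peptide_id, ]
  per_standard <- std |>
    dplyr::group_by(peptide_id = .data$peptide_id) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_rt = mean(.data$rt_observed),
      sd_seconds = if (dplyr::n() > 1) sd(.data$rt_observed) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(cv_percent = 100 * .data$sd_seconds / .data$mean_rt)

  # observed vs predicted RT per run over everything with a reference iRT
  ref_all <- dplyr::bind_rows(
    tibble(peptide_id = reference$peptide_id, irt = reference$irt),
    if (!is.null(peptide_reference)) {
      tibble(peptide_id = strip_charge(peptide_reference$precursor_id),
             irt = peptide_reference$irt)
    }
  )
  obs <- report[!is.na(report$rt_observed), ]
  obs$peptide_id <- strip_charge(obs$precursor_id)
  obs <- dplyr::inner_join(obs, ref_all, by = "peptide_id")
  obs <- dplyr::inner_join(obs, calibration$runs[c("run_id", "slope", "intercept", "fitted")],
                           by = "run_id")
  obs <- obs[obs$fitted, ]
  per_run <- obs |>
    dplyr::group_by(run_id = .data$run_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      r_squared = if (dplyr::n() > 2 && stats::var(.data$rt_observed) > 0) {
        stats::cor(.data$rt_observed,
                   .data$intercept[1] + .data$slope[1] * .data$irt)^2
      } else NA_real_,
      .groups = "drop"
    )
  structure(list(per_standard = per_standard, per_run = per_run,
                 mean_sd_seconds = mean(per_standard$sd_seconds, na.rm = TRUE),
                 max_cv_percent = max(per_standard$cv_percent, na.rm = TRUE),
                 median_r2 = median(per_run$r_squared, na.rm = TRUE)),
            class = "rt_stability")
}

#' @export
print.rt_stability <- function(x, ...) {
  cat(sprintf("<rt_stability> %d standards: mean RT SD %.1f s, max RT CV %.2f%%; median run R2 %.4f\n",
              nrow(x$per_standard), x$mean_sd_seconds, x$max_cv_percent,
              x$median_r2))
  invisible(x)
}

#' @export
glance.rt_stability <- function(x, ...) {
  tibble(n_standards = nrow(x$per_standard),
         mean_sd_seconds = x$mean_sd_seconds,
         max_cv_percent = x$max_cv_percent,
         median_r2 = x$median_r2)
}
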