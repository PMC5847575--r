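#' Render the QC dossier
#'
#' Assembles the per-stage QC sections into a machine-readable JSON summary
#' and a plain-text (markdown) dossier. Sections that were not run are
#' rendered as `"not run"`. Rendering is deterministic: two renders of the
#' same inputs are byte-identical.
#'
#' @param qc A named list with (any of) sections `rt`, `filter`, `normalize`,
#'   `correct`, `cv`, `batch`, as assembled by [run_pipeline()]; a section
#'   that was not run is `NULL`.
#' @param out_dir Optional directory; when given, `qc_report.json` and
#'   `qc_report.md` are written there.
#' @return Invisibly, a list with `json` (the summary list), `markdown`
#'   (character vector of lines).
#' @export
render_report <- function(qc, out_dir = NULL) {
  section_names <- c("rt", "filter", "normalize", "correct", "cv", "batch")
  if (!any(section_names %in% names(qc)) || all(vapply(qc, is.null, logical(1)))) {
    abort("At least one stage output is required.")
  }
  summary <- list(schema_version = "1.0")
  for (s in section_names) {
    sec <- qc[[s]]
    summary[[s]] <- if (is.null(sec)) "not run" else sanitize_numbers(sec)
  }
  md <- c("# DIA post-processing QC dossier", "")
  titles <- c(rt = "Retention-time stability", filter = "Qvalue filtering",
              normalize = "Robust-sum normalization",
              correct = "Batch correction", cv = "Coefficients of variation",
              batch = "Batch clustering")
  for (s in section_names) {
    md <- c(md, paste0("## ", titles[[s]]), "")
    sec <- summary[[s]]
    if (identical(sec, "not run")) {
      md <- c(md, "not run", "")
    } else {
      for (k in names(sec)) {
        v <- sec[[k]]
        md <- c(md, sprintf("- %s: %s", k,
                            if (is.null(v) || length(v) == 0) "NA"
                            else paste(format(v, digits = 6), collapse = ", ")))
      }
      md <- c(md, "")
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(md, file.path(out_dir, "qc_report.md"))
  }
  invisible(list(json = summary, markdown = md))
}

# every numeric field finite or null; drop non-scalar members for the summary
sanitize_numbers <- function(x) {
  out <- lapply(x, function(v) {
    if (is.null(v)) return(NULL)
    if (is.numeric(v)) {
      v <- unname(v)
      v[!is.finite(v)] <- NA
      return(if (length(v) == 1L && is.na(v)) NULL else v)
    }
    if (is.character(v) || is.logical(v)) return(unname(v))
    NULL
  })
  out[!vapply(out, is.null, logical(1))]
}
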