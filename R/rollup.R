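#' Select quantifier peptides per protein by pairwise correlation
#'
#' Peptides derived from one protein should co-vary across samples; peptides
#' that behave inconsistently (e.g. carrying variable post-translational
#' modifications, or interference) are excluded from quantification not by
#' abundance but by correlation. Per protein, each member's score is its mean
#' pairwise correlation with the other members, computed on runs where both
#' members are measured (pairs sharing fewer than `min_overlap` runs score
#' missing). Greedy backward elimination removes the lowest-scoring member and
#' recomputes while that score is below `rho_min` and more than 2 members
#' remain. Proteins with 2 or fewer members keep all members and are flagged
#' `unselected`. Ties break deterministically on (score, precursor id); a
#' member with no scorable pair is removed first.
#'
#' @param qm A log2-scale [quant_matrix()]; its mapping provides the
#'   precursor-to-protein groups.
#' @param rho_min Minimum acceptable mean pairwise correlation, default 0.5.
#' @param min_overlap Minimum shared measured runs per pair, default 6.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A `peptide_groups` object. [tidy()] returns the selection audit:
#'   one row per (protein, peptide) with final `score`, `kept`, and
#'   `removal_round` (NA when kept).
#' @export
select_peptides <- function(qm, rho_min = 0.5, min_overlap = 6L,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") abort("Peptide selection expects a log2-scale matrix.")
  if (nrow(qm$mapping) == 0L) abort("Empty precursor-to-protein mapping.")
  assert_scalar_number(rho_min, "rho_min", lower = -1, upper = 1)
  groups <- split(qm$mapping$precursor_id, qm$mapping$protein_id)
  audit <- vector("list", length(groups))
  selected <- vector("list", length(groups))
  names(selected) <- names(groups)
  for (gi in seq_along(groups)) {
    protein <- names(groups)[gi]
    members <- sort(groups[[gi]])
    if (length(members) <= 2L) {
      score <- if (length(members) == 2L) {
        r <- pair_cor(qm$values[members[1], ], qm$values[members[2], ],
                      min_overlap, method)
        c(r, r)
      } else {
        NA_real_
      }
      audit[[gi]] <- tibble(protein_id = protein, precursor_id = members,
                            score = score, kept = TRUE,
                            removal_round = NA_integer_, unselected = TRUE)
      selected[[protein]] <- members
      next
    }
    current <- members
    removed <- character(0)
    removal_round <- integer(0)
    removed_score <- numeric(0)
    round <- 0L
    repeat {
      scores <- mean_pairwise_cor(qm$values[current, , drop = FALSE],
                                  min_overlap, method)
      ord <- order(ifelse(is.na(scores), -Inf, scores), current)
      worst <- ord[1L]
      worst_score <- scores[worst]
      if (length(current) <= 2L ||
          (!is.na(worst_score) && worst_score >= rho_min)) break
      round <- round + 1L
      removed <- c(removed, current[worst])
      removal_round <- c(removal_round, round)
      removed_score <- c(removed_score, worst_score)
      current <- current[-worst]
    }
    final_scores <- mean_pairwise_cor(qm$values[current, , drop = FALSE],
                                      min_overlap, method)
    audit[[gi]] <- dplyr::bind_rows(
      tibble(protein_id = protein, precursor_id = current,
             score = final_scores, kept = TRUE, removal_round = NA_integer_,
             unselected = FALSE),
      tibble(protein_id = protein, precursor_id = removed,
             score = removed_score, kept = FALSE,
             removal_round = removal_round, unselected = FALSE)
    )
    selected[[protein]] <- current
  }
  structure(list(audit = dplyr::bind_rows(audit), selected = selected,
                 rho_min = rho_min, min_overlap = min_overlap,
                 method = method),
            class = "peptide_groups")
}

pair_cor <- function(x, y, min_overlap, method) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = method)
}

# mean pairwise correlation of each row with the other rows
mean_pairwise_cor <- function(m, min_overlap, method) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, n))
  cm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cm[i, j] <- cm[j, i] <- pair_cor(m[i, ], m[j, ], min_overlap, method)
    }
  }
  rowMeans(cm, na.rm = TRUE) |> (\(x) ifelse(is.nan(x), NA_real_, x))()
}

#' @export
print.peptide_groups <- function(x, ...) {
  cat(sprintf("<peptide_groups> %d proteins; %d of %d peptides kept (rho_min = %.2f)\n",
              length(x$selected), sum(x$audit$kept), nrow(x$audit), x$rho_min))
  invisible(x)
}

#' @export
tidy.peptide_groups <- function(x, ...) x$audit

#' @export
glance.peptide_groups <- function(x, ...) {
  tibble(n_proteins = length(x$selected),
         n_peptides = nrow(x$audit),
         n_kept = sum(x$audit$kept),
         n_unselected_proteins = dplyr::n_distinct(
           x$audit$protein_id[x$audit$unselected]),
         rho_min = x$rho_min, min_overlap = x$min_overlap)
}

#' Geometric rollup of peptide groups to protein quantities
#'
#' Per (protein, run): when the fraction of selected peptides measured in the
#' run is at least `min_present_fraction`, the protein value is the geometric
#' mean of the measured members (the arithmetic mean on the log2 scale);
#' otherwise missing. The output is on the same scale as the input.
#'
#' @param qm A [quant_matrix()] (linear or log2).
#' @param groups A [select_peptides()] result, or `NULL` to use all mapped
#'   peptides per protein.
#' @param min_present_fraction Minimum fraction of selected peptides that must
#'   be measured, default 0.5.
#' @return A `protein_matrix`: `values` (proteins x runs), `scale`, and a
#'   per-protein tibble `proteins` (`n_peptides`, mean selection `score`).
#' @export
rollup_geometric <- function(qm, groups = NULL, min_present_fraction = 0.5) {
  stopifnot(inherits(qm, "quant_matrix"))
  assert_scalar_number(min_present_fraction, "min_present_fraction",
                       lower = 0, upper = 1)
  if (is.null(groups)) {
    selected <- split(qm$mapping$precursor_id, qm$mapping$protein_id)
    audit <- NULL
  } else {
    stopifnot(inherits(groups, "peptide_groups"))
    selected <- groups$selected
    audit <- groups$audit
    absent <- setdiff(unlist(selected), rownames(qm$values))
    if (length(absent)) {
      abort(sprintf("Peptide group references precursor(s) absent from the matrix: %s.",
                    paste(head(absent, 3), collapse = ", ")))
    }
  }
  log_m <- if (qm$scale == "log2") qm$values else {
    v <- qm$values
    v[v == 0] <- NA_real_
    log2(v)
  }
  prot <- matrix(NA_real_, length(selected), ncol(log_m),
                 dimnames = list(names(selected), colnames(log_m)))
  for (p in seq_along(selected)) {
    mem <- log_m[selected[[p]], , drop = FALSE]
    n_present <- colSums(!is.na(mem))
    value <- colMeans(mem, na.rm = TRUE)
    value[n_present < min_present_fraction * nrow(mem) | n_present == 0] <- NA_real_
    prot[p, ] <- value
  }
  if (qm$scale == "linear") prot <- 2^prot
  prot[is.nan(prot)] <- NA_real_
  proteins <- tibble(
    protein_id = names(selected),
    n_peptides = lengths(selected),
    score = if (is.null(audit)) NA_real_ else {
      vapply(names(selected), function(p) {
        mean(audit$score[audit$protein_id == p & audit$kept], na.rm = TRUE)
      }, numeric(1))
    }
  )
  structure(list(values = prot, scale = qm$scale, proteins = proteins,
                 min_present_fraction = min_present_fraction),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("<protein_matrix> %d proteins x %d runs (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
tidy.protein_matrix <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble(protein_id = rownames(x$values)[idx[, "row"]],
         run_id = colnames(x$values)[idx[, "col"]],
         intensity = x$values[idx], scale = x$scale)
}

#' @export
as_tibble.protein_matrix <- function(x, ...) tidy(x)
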