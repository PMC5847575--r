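#' Estimate surrogate variables from low-variance control features
#'
#' A supervised surrogate-variable analysis that makes no use of experimental
#' factors: features are ranked by their variance across runs, the least
#' variable `control_fraction` form the control set (biology is assumed flat
#' there, so remaining structure is technical), the control submatrix is
#' row-centered, and its top right singular vectors are returned as surrogate
#' vectors (one value per run, orthonormal).
#'
#' With `k = "auto"` the number of surrogates is chosen by permutation: each
#' control feature's values are independently permuted across runs
#' (`n_perm` times, seeded), and a component is retained while its singular
#' value exceeds the 95th percentile of the corresponding permuted singular
#' values.
#'
#' @param qm A log2-scale [quant_matrix()] with at least 3 runs. Only features
#'   measured in every run can serve as controls.
#' @param control_fraction Fraction of least-variable features used as
#'   controls, default 0.5.
#' @param k Number of surrogates, or `"auto"`. Must be smaller than the number
#'   of runs.
#' @param n_perm Permutations for `k = "auto"`, default 19.
#' @param perm_seed Seed for the permutation null, so the choice of `k` is
#'   reproducible.
#' @return A `surrogate_model`: `controls` (feature ids), `vectors`
#'   (runs x k orthonormal matrix), `singular_values`, `k`.
#' @export
estimate_surrogates <- function(qm, control_fraction = 0.5, k = 1L,
                                n_perm = 19L, perm_seed = 1L) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") abort("Surrogate estimation expects a log2-scale matrix.")
  n_runs <- ncol(qm$values)
  if (n_runs < 3L) abort("Need >= 3 runs.")
  assert_scalar_number(control_fraction, "control_fraction",
                       lower = 1e-6, upper = 1)
  auto <- identical(k, "auto")
  if (!auto) {
    assert_scalar_number(k, "k", lower = 0)
    if (k >= n_runs) abort("`k` must be smaller than the number of runs.")
  }
  complete <- qm$values[rowSums(is.na(qm$values)) == 0L, , drop = FALSE]
  if (nrow(complete) < 2L) abort("Need >= 2 complete features.")
  v <- apply(complete, 1L, stats::var)
  n_ctrl <- max(2L, floor(nrow(complete) * control_fraction))
  controls <- rownames(complete)[order(v, rownames(complete))][seq_len(n_ctrl)]
  ctrl <- complete[controls, , drop = FALSE]
  ctrl <- ctrl - rowMeans(ctrl)
  if (all(abs(ctrl) < 1e-12)) {
    # constant matrix: no structure to estimate
    return(new_surrogate_model(controls, matrix(numeric(0), n_runs, 0L,
                                                dimnames = list(colnames(ctrl), NULL)),
                               numeric(0), control_fraction))
  }
  sv <- svd(ctrl)
  d <- sv$d
  if (auto) {
    k_max <- min(n_runs - 1L, nrow(ctrl) - 1L, length(d))
    perm_d <- withr::with_seed(perm_seed, {
      vapply(seq_len(n_perm), function(p) {
        perm <- t(apply(ctrl, 1L, sample))
        svd(perm - rowMeans(perm), nu = 0L, nv = 0L)$d[seq_len(k_max)]
      }, numeric(k_max))
    })
    thresh <- apply(perm_d, 1L, stats::quantile, probs = 0.95)
    k <- 0L
    for (j in seq_len(k_max)) {
      if (d[j] > thresh[j]) k <- j else break
    }
  }
  k <- as.integer(k)
  vectors <- sv$v[, seq_len(k), drop = FALSE]
  rownames(vectors) <- colnames(ctrl)
  new_surrogate_model(controls, vectors, d[seq_len(k)], control_fraction)
}

new_surrogate_model <- function(controls, vectors, d, control_fraction) {
  structure(list(controls = controls, vectors = vectors,
                 singular_values = d, k = ncol(vectors),
                 control_fraction = control_fraction),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> k = %d surrogate(s) from %d control features\n",
              x$k, length(x$controls)))
  invisible(x)
}

#' @export
tidy.surrogate_model <- function(x, ...) {
  if (x$k == 0L) {
    return(tibble(run_id = character(), surrogate = integer(), value = double()))
  }
  out <- as_tibble(x$vectors, .name_repair = ~ paste0("SV", seq_along(.x)))
  out$run_id <- rownames(x$vectors)
  tidyr::pivot_longer(out, -"run_id", names_to = "surrogate",
                      names_prefix = "SV", names_transform = as.integer,
                      values_to = "value")
}

#' @export
glance.surrogate_model <- function(x, ...) {
  tibble(k = x$k, n_controls = length(x$controls),
         control_fraction = x$control_fraction,
         top_singular_value = if (x$k) x$singular_values[1] else NA_real_)
}

#' Regress surrogate variables out of a quantification matrix
#'
#' Each feature is regressed on an intercept plus the surrogate vectors (over
#' its measured runs); the fitted surrogate component is subtracted while the
#' intercept is retained. A `k = 0` model returns the input unchanged; missing
#' cells stay missing.
#'
#' @param qm A log2-scale [quant_matrix()] whose runs match the model.
#' @param model An [estimate_surrogates()] result.
#' @return The corrected [quant_matrix()].
#' @export
regress_out_surrogates <- function(qm, model) {
  stopifnot(inherits(qm, "quant_matrix"), inherits(model, "surrogate_model"))
  if (model$k == 0L) return(qm)
  if (nrow(model$vectors) != ncol(qm$values) ||
      !all(rownames(model$vectors) == colnames(qm$values))) {
    abort("Surrogate vectors do not match the matrix's runs.")
  }
  X <- cbind(intercept = 1, model$vectors)
  Y <- qm$values
  out <- Y
  for (g in seq_len(nrow(Y))) {
    ok <- !is.na(Y[g, ])
    if (sum(ok) <= model$k) next
    cf <- stats::lm.fit(X[ok, , drop = FALSE], Y[g, ok])$coefficients
    cf[is.na(cf)] <- 0
    out[g, ok] <- Y[g, ok] - drop(model$vectors[ok, , drop = FALSE] %*% cf[-1L])
  }
  quant_matrix(out, "log2", qm$mapping)
}
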