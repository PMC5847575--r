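#' Fit a QC-anchored empirical-Bayes batch-correction model
#'
#' Models each feature's log2 signal as
#' `y = alpha_g + X beta_g + gamma_ig + delta_ig * eps`, with additive
#' (`gamma`) and multiplicative (`delta`) per-(batch, feature) batch effects,
#' and stabilizes the per-feature batch estimates by parametric empirical-Bayes
#' shrinkage toward moment-matched priors shared across features (a normal
#' prior for `gamma`, an inverse-gamma prior for `delta^2`).
#'
#' The fit proceeds feature-wise: (1) least squares of `y` on batch indicators
#' plus covariates under the constraint `sum_i n_i gamma_ig = 0` yields
#' `alpha_g`, `beta_g`; the pooled scale `sigma_g^2` is the mean squared
#' residual; (2) the signal is standardized,
#' `z = (y - alpha_g - X beta_g) / sigma_g`; (3) per-batch feature estimates
#' are the batch mean (`gamma_hat`) and batch variance (`delta2_hat`) of `z`;
#' (4) hyperpriors per batch come from moments across features
#' (`lambda = (m^2 + 2 s^2) / s^2`, `theta = (m^3 + m s^2) / s^2` for the
#' inverse-gamma); (5) the posterior estimates solve the fixed-point
#' `gamma* = (n tau2 gamma_hat + delta2* gamma_bar) / (n tau2 + delta2*)`,
#' `delta2* = (theta + 0.5 sum_j (z - gamma*)^2) / (n/2 + lambda - 1)`,
#' iterated to convergence. With `shrink = FALSE` the raw per-batch estimates
#' are used directly.
#'
#' QC anchoring is achieved by including the sample type as one level of a
#' condition covariate alongside the genotypes, so QC runs inform the batch
#' estimates in every batch without being treated as a biological group.
#' Features for which some batch has fewer than 2 measured runs (the batch
#' variance would be undefined) are excluded from the model and passed through
#' uncorrected by [apply_combat()], with the exclusion recorded.
#'
#' @param qm A log2-scale [quant_matrix()].
#' @param design A sample-design tibble covering all runs of `qm`; every batch
#'   needs at least 2 runs.
#' @param covariates Character vector of design columns to adjust for (factor
#'   or numeric); biological contrasts along these columns are preserved by the
#'   correction. Default none.
#' @param shrink Apply empirical-Bayes shrinkage (`TRUE`, parametric
#'   adjustment) or use the raw per-batch location/scale estimates (`FALSE`).
#' @param tol Convergence tolerance on `max |change in gamma*|`.
#' @param max_iter Maximum fixed-point iterations.
#' @return A `combat_model`; see [tidy.combat_model()] and [apply_combat()].
#' @export
fit_combat <- function(qm, design, covariates = NULL, shrink = TRUE,
                       tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$scale != "log2") abort("Batch correction expects a log2-scale matrix.")
  design <- validate_sample_design(design)
  runs <- colnames(qm$values)
  missing_runs <- setdiff(runs, design$run_id)
  if (length(missing_runs)) {
    abort(sprintf("Design lacks run(s) present in the matrix: %s.",
                  paste(head(missing_runs, 3), collapse = ", ")))
  }
  design <- design[match(runs, design$run_id), ]
  batch <- factor(design$batch)
  if (nlevels(batch) < 1L) abort("Need at least one batch.")
  n_i <- table(batch)
  if (any(n_i < 2L)) {
    abort(sprintf("Every batch needs >= 2 runs; too small: %s.",
                  paste(names(n_i)[n_i < 2], collapse = ", ")))
  }

  B <- vapply(levels(batch), function(l) as.numeric(batch == l),
              numeric(length(batch)))
  C <- build_covariate_matrix(design, covariates)
  X <- cbind(B, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    confounded <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    abort(sprintf("Design is rank deficient; confounded column(s): %s.",
                  paste(confounded, collapse = ", ")))
  }

  Y <- qm$values
  present <- !is.na(Y)
  n_ig <- present %*% B                      # features x batches present counts
  excluded_reason <- rep(NA_character_, nrow(Y))
  excluded_reason[apply(n_ig < 2L, 1L, any)] <- "batch_with_fewer_than_2_runs"

  nb <- nlevels(batch)
  np <- ncol(X)
  feats <- rownames(Y)
  alpha <- sigma2 <- rep(NA_real_, nrow(Y))
  beta <- matrix(NA_real_, nrow(Y), ncol(C),
                 dimnames = list(feats, colnames(C)))
  gamma_raw <- matrix(NA_real_, nrow(Y), nb, dimnames = list(feats, levels(batch)))

  complete_rows <- which(rowSums(present) == ncol(Y) & is.na(excluded_reason))
  if (length(complete_rows)) {
    cf <- qr.coef(qrX, t(Y[complete_rows, , drop = FALSE]))
    fit <- X %*% cf
    res <- t(Y[complete_rows, , drop = FALSE]) - fit
    gamma_raw[complete_rows, ] <- t(cf[seq_len(nb), , drop = FALSE])
    if (ncol(C)) beta[complete_rows, ] <- t(cf[-seq_len(nb), , drop = FALSE])
    sigma2[complete_rows] <- colMeans(res^2)
  }
  partial_rows <- which(rowSums(present) < ncol(Y) & is.na(excluded_reason))
  for (g in partial_rows) {
    ok <- present[g, ]
    fit <- stats::lm.fit(X[ok, , drop = FALSE], Y[g, ok])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0     # aliased covariate level on this feature's runs
    gamma_raw[g, ] <- cf[seq_len(nb)]
    if (ncol(C)) beta[g, ] <- cf[-seq_len(nb)]
    sigma2[g] <- mean(fit$residuals^2)
  }

  zero_var <- is.na(excluded_reason) & (is.na(sigma2) | sigma2 <= 1e-12)
  excluded_reason[zero_var] <- "zero_residual_variance"
  keep <- is.na(excluded_reason)
  if (!any(keep)) abort("No feature is estimable for batch correction.")

  # constraint sum_i n_ig gamma_ig = 0 via the present-count-weighted intercept
  w <- n_ig[keep, , drop = FALSE] / rowSums(n_ig[keep, , drop = FALSE])
  alpha[keep] <- rowSums(w * gamma_raw[keep, , drop = FALSE])
  gamma_centered <- gamma_raw - alpha      # per-feature batch deviations

  # standardized signal retains batch structure
  covar_part <- if (ncol(C)) {
    tcrossprod(replace(beta, is.na(beta), 0), C)
  } else {
    matrix(0, nrow(Y), ncol(Y))
  }
  Z <- (Y - alpha - covar_part) / sqrt(sigma2)
  Z[!present] <- NA_real_

  gamma_hat <- delta2_hat <- matrix(NA_real_, nrow(Y), nb,
                                    dimnames = list(feats, levels(batch)))
  for (i in seq_len(nb)) {
    cols <- batch == levels(batch)[i]
    zb <- Z[, cols, drop = FALSE]
    gamma_hat[, i] <- rowMeans(zb, na.rm = TRUE)
    delta2_hat[, i] <- apply(zb, 1L, stats::var, na.rm = TRUE)
  }

  if (nb == 1L) {
    # no batch structure to remove: the correction reduces to the identity
    shrink <- FALSE
    gamma_hat[keep, ] <- 0
    delta2_hat[keep, ] <- 1
  }
  if (shrink && sum(keep) < 3L) {
    warn("Fewer than 3 estimable features; empirical-Bayes shrinkage disabled.")
    shrink <- FALSE
  }

  hyper <- NULL
  iterations <- 0L
  if (shrink) {
    gh <- gamma_hat[keep, , drop = FALSE]
    d2h <- delta2_hat[keep, , drop = FALSE]
    g_bar <- colMeans(gh)
    tau2_bar <- apply(gh, 2L, stats::var)
    m <- colMeans(d2h)
    s2 <- apply(d2h, 2L, stats::var)
    if (any(s2 <= 0)) abort("Degenerate delta^2 spread across features; cannot form priors.")
    lambda_bar <- (m^2 + 2 * s2) / s2
    theta_bar <- (m^3 + m * s2) / s2
    hyper <- tibble(batch = levels(batch), gamma_bar = g_bar,
                    tau2_bar = tau2_bar, lambda_bar = lambda_bar,
                    theta_bar = theta_bar)

    g_star <- gh
    d2_star <- d2h
    n_keep <- n_ig[keep, , drop = FALSE]
    repeat {
      iterations <- iterations + 1L
      g_new <- (n_keep * rep(tau2_bar, each = nrow(gh)) * gh +
                  d2_star * rep(g_bar, each = nrow(gh))) /
        (n_keep * rep(tau2_bar, each = nrow(gh)) + d2_star)
      sum2 <- matrix(NA_real_, nrow(gh), nb)
      for (i in seq_len(nb)) {
        cols <- batch == levels(batch)[i]
        zb <- Z[keep, cols, drop = FALSE]
        sum2[, i] <- rowSums((zb - g_new[, i])^2, na.rm = TRUE)
      }
      d2_new <- (rep(theta_bar, each = nrow(gh)) + 0.5 * sum2) /
        (n_keep / 2 + rep(lambda_bar, each = nrow(gh)) - 1)
      delta <- max(abs(g_new - g_star))
      g_star <- g_new
      d2_star <- d2_new
      if (delta < tol) break
      if (iterations >= max_iter) {
        abort(sprintf("Empirical-Bayes iteration did not converge in %d steps (last max |change in gamma*| = %.3g).",
                      max_iter, delta))
      }
    }
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    gamma_star[keep, ] <- g_star
    delta2_star[keep, ] <- d2_star
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  structure(
    list(alpha = setNames(alpha, feats), beta = beta,
         sigma = setNames(sqrt(sigma2), feats),
         gamma_hat = gamma_hat, delta2_hat = delta2_hat,
         gamma_star = gamma_star, delta2_star = delta2_star,
         hyper = hyper, shrink = shrink, iterations = iterations,
         tol = tol, converged = TRUE,
         excluded = tibble(precursor_id = feats[!keep],
                           reason = excluded_reason[!keep]),
         batch = setNames(as.character(batch), runs),
         batch_levels = levels(batch), n_i = as.integer(n_i),
         covariate_matrix = C, covariates = covariates),
    class = "combat_model"
  )
}

build_covariate_matrix <- function(design, covariates) {
  if (is.null(covariates) || length(covariates) == 0L) {
    m <- matrix(numeric(0), nrow = nrow(design), ncol = 0L)
    rownames(m) <- design$run_id
    return(m)
  }
  assert_columns(design, covariates, "Sample design")
  df <- design[covariates]
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  constant <- vapply(df, function(x) {
    (is.factor(x) && nlevels(droplevels(x)) < 2L) ||
      (is.numeric(x) && length(unique(x)) < 2L)
  }, logical(1))
  df <- df[!constant]   # constant covariates are absorbed by the batch terms
  if (ncol(df) == 0L) {
    m <- matrix(numeric(0), nrow = nrow(design), ncol = 0L)
    rownames(m) <- design$run_id
    return(m)
  }
  m <- stats::model.matrix(~ ., data = df)[, -1L, drop = FALSE]
  rownames(m) <- design$run_id
  m
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features x %d batches (%s), %d excluded, %d EB iterations\n",
              length(x$alpha), length(x$batch_levels),
              if (x$shrink) "shrunk" else "raw estimates",
              nrow(x$excluded), x$iterations))
  invisible(x)
}

#' Tidy a batch-correction model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, batch): raw and shrunk additive
#'   (`gamma_hat`, `gamma_star`) and multiplicative (`delta2_hat`,
#'   `delta2_star`) batch estimates.
#' @export
tidy.combat_model <- function(x, ...) {
  out <- tidyr::expand_grid(precursor_id = rownames(x$gamma_hat),
                            batch = x$batch_levels)
  ij <- cbind(match(out$precursor_id, rownames(x$gamma_hat)),
              match(out$batch, x$batch_levels))
  out$gamma_hat <- x$gamma_hat[ij]
  out$gamma_star <- x$gamma_star[ij]
  out$delta2_hat <- x$delta2_hat[ij]
  out$delta2_star <- x$delta2_star[ij]
  out
}

#' @export
glance.combat_model <- function(x, ...) {
  tibble(n_features = length(x$alpha) - nrow(x$excluded),
         n_excluded = nrow(x$excluded),
         n_batches = length(x$batch_levels),
         shrink = x$shrink, iterations = x$iterations,
         converged = x$converged, tol = x$tol)
}

#' Apply a fitted batch-correction model
#'
#' Subtracts the estimated batch effects:
#' `y* = (sigma_g / delta*_ig) * (z - gamma*_ig) + alpha_g + X beta_g`.
#' Missing cells stay missing; features excluded at fit time pass through
#' unchanged.
#'
#' @param qm A log2-scale [quant_matrix()] whose runs were part of the model's
#'   design.
#' @param model A [fit_combat()] result.
#' @return The corrected [quant_matrix()].
#' @export
apply_combat <- function(qm, model) {
  stopifnot(inherits(qm, "quant_matrix"), inherits(model, "combat_model"))
  if (qm$scale != "log2") abort("Batch correction expects a log2-scale matrix.")
  runs <- colnames(qm$values)
  unknown <- setdiff(runs, names(model$batch))
  if (length(unknown)) {
    abort(sprintf("Run(s) absent from the fitted design: %s.",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  feats <- rownames(qm$values)
  unknown_f <- setdiff(feats, names(model$alpha))
  if (length(unknown_f)) {
    abort(sprintf("Feature(s) absent from the fitted model: %s.",
                  paste(head(unknown_f, 3), collapse = ", ")))
  }
  Y <- qm$values
  out <- Y
  keep <- setdiff(feats, model$excluded$precursor_id)
  gi <- match(keep, names(model$alpha))
  bi <- match(model$batch[runs], model$batch_levels)
  C <- model$covariate_matrix[runs, , drop = FALSE]
  covar_part <- if (ncol(C)) {
    tcrossprod(replace(model$beta[gi, , drop = FALSE],
                       is.na(model$beta[gi, , drop = FALSE]), 0), C)
  } else {
    matrix(0, length(keep), length(runs))
  }
  stand_mean <- model$alpha[gi] + covar_part
  z <- (Y[keep, , drop = FALSE] - stand_mean) / model$sigma[gi]
  g_star <- model$gamma_star[gi, bi, drop = FALSE]
  d_star <- sqrt(model$delta2_star[gi, bi, drop = FALSE])
  out[keep, ] <- (model$sigma[gi] / d_star) * (z - g_star) + stand_mean
  out[is.na(Y)] <- NA_real_
  quant_matrix(out, "log2", qm$mapping)
}
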