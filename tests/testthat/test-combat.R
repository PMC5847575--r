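# brute-force oracle for the no-shrink, no-covariate corrector: standardize
# each feature within batch, then restore the pooled location/scale
standardize_oracle <- function(Y, batch) {
  n <- ncol(Y)
  out <- Y
  for (g in seq_len(nrow(Y))) {
    bm <- tapply(Y[g, ], batch, mean)
    alpha <- sum(table(batch) * bm) / n
    sig <- sqrt(mean((Y[g, ] - bm[batch])^2))
    z <- (Y[g, ] - alpha) / sig
    zm <- tapply(z, batch, mean)
    zv <- tapply(z, batch, var)
    out[g, ] <- sig / sqrt(zv[batch]) * (z - zm[batch]) + alpha
  }
  out
}

two_batch_design <- function(n, covariate = NULL) {
  d <- toy_design(n, n_batches = 2)
  if (!is.null(covariate)) d$strain <- covariate
  d
}

test_that("a single batch with raw estimates is the identity correction", {
  set.seed(10)
  Y <- matrix(rnorm(40, 12, 1), 10, 4,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("r%02d", 1:4)))
  d <- toy_design(4, n_batches = 1)
  m <- fit_combat(make_qm(Y), d, shrink = FALSE)
  expect_equal(max(abs(m$gamma_star)), 0, tolerance = 1e-9)
  corr <- apply_combat(make_qm(Y), m)
  expect_equal(corr$values, Y, tolerance = 1e-9)
})

test_that("two batches, one feature: corrected batch means equal the pooled mean", {
  Y <- matrix(c(9.5, 10.2, 10.3, 11.5, 12.2, 12.3), 1, 6,
              dimnames = list("f1", sprintf("r%02d", 1:6)))
  d <- two_batch_design(6)
  m <- fit_combat(make_qm(Y), d, shrink = FALSE)
  corr <- apply_combat(make_qm(Y), m)
  pooled <- mean(Y)
  expect_equal(mean(corr$values[1, 1:3]), pooled, tolerance = 1e-9)
  expect_equal(mean(corr$values[1, 4:6]), pooled, tolerance = 1e-9)
  expect_equal(var(corr$values[1, 1:3]), var(corr$values[1, 4:6]),
               tolerance = 1e-9)
})

test_that("no-shrink correction equals the standardization oracle on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n_f <- sample(3:10, 1)
    n_r <- sample(8:20, 1)
    Y <- matrix(rnorm(n_f * n_r, 10, 1), n_f, n_r,
                dimnames = list(sprintf("f%02d", 1:n_f), sprintf("r%02d", 1:n_r)))
    batch <- sprintf("b%d", ceiling(seq_len(n_r) / (n_r / 2)))
    d <- tibble::tibble(run_id = colnames(Y), batch = batch,
                        acq_order = seq_len(n_r), sample_type = "study",
                        strain = "s", replicate_id = 1)
    m <- fit_combat(make_qm(Y), d, shrink = FALSE)
    corr <- apply_combat(make_qm(Y), m)
    expect_equal(corr$values, standardize_oracle(Y, batch), tolerance = 1e-9)
  }
})

test_that("shrinkage is a contraction between the raw estimate and the prior mean", {
  set.seed(20)
  Y <- matrix(rnorm(200 * 16, 12, 1), 200, 16,
              dimnames = list(sprintf("f%03d", 1:200), sprintf("r%02d", 1:16)))
  Y <- Y + outer(rnorm(200, 0, 0.5), rep(c(-1, 1), each = 8))
  d <- two_batch_design(16)
  m <- fit_combat(make_qm(Y), d, shrink = TRUE)
  td <- tidy(m)
  g_bar <- setNames(m$hyper$gamma_bar, m$hyper$batch)[td$batch]
  # gamma* lies in the segment [gamma_hat, gamma_bar]
  expect_true(all((td$gamma_star - g_bar) * (td$gamma_hat - g_bar) >= -1e-12))
  expect_true(all(abs(td$gamma_star - g_bar) <= abs(td$gamma_hat - g_bar) + 1e-12))
  expect_true(all(abs(td$gamma_star) <=
                    pmax(abs(td$gamma_hat), abs(g_bar)) + 1e-12))
})

test_that("the corrector agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(11)
  n <- 24; G <- 60
  batch <- rep(c("b1", "b2"), each = 12)
  geno <- rep(rep(c("g1", "g2", "QC"), each = 4), 2)
  Y <- matrix(rnorm(G * n, 12, 1), G, n,
              dimnames = list(sprintf("f%02d", 1:G), sprintf("r%02d", 1:n)))
  Y <- Y + outer(rnorm(G, 0, 0.6), as.numeric(batch == "b2") * 2 - 1) +
    outer(rnorm(G, 0, 0.4), as.numeric(geno == "g2"))
  d <- tibble::tibble(run_id = colnames(Y), batch = batch, acq_order = 1:n,
                      sample_type = ifelse(geno == "QC", "QC", "study"),
                      condition = geno, replicate_id = 1)
  m <- fit_combat(make_qm(Y), d, covariates = "condition", shrink = TRUE)
  corr <- apply_combat(make_qm(Y), m)
  ref <- sva::ComBat(Y, batch = factor(batch),
                     mod = stats::model.matrix(~ condition, data = d),
                     par.prior = TRUE, prior.plots = FALSE)
  expect_equal(corr$values, ref, tolerance = 1e-8)
})

test_that("planted additive batch offsets are recovered with high correlation", {
  set.seed(30)
  G <- 500; n <- 30
  truth <- rnorm(G, 0, 0.5)
  batch <- rep(c("b1", "b2"), each = n / 2)
  Y <- matrix(rnorm(G * n, 10, 0.3), G, n,
              dimnames = list(sprintf("f%03d", 1:G), sprintf("r%02d", 1:n))) +
    outer(truth, as.numeric(batch == "b2"))
  d <- tibble::tibble(run_id = colnames(Y), batch = batch, acq_order = 1:n,
                      sample_type = "study", strain = "s", replicate_id = 1)
  m <- fit_combat(make_qm(Y), d, shrink = TRUE)
  # gamma* is on the standardized scale; correlation is scale-free
  expect_gt(cor(m$gamma_star[, "b2"], truth), 0.9)
})

test_that("covariate contrasts survive the correction", {
  set.seed(40)
  G <- 80; n <- 24
  beta <- rnorm(G, 0, 0.8)
  batch <- rep(c("b1", "b2"), each = 12)
  geno <- rep(rep(c("g1", "g2"), each = 6), 2)
  Y <- matrix(rnorm(G * n, 10, 0.2), G, n,
              dimnames = list(sprintf("f%02d", 1:G), sprintf("r%02d", 1:n))) +
    outer(rnorm(G, 0, 1), as.numeric(batch == "b2")) +
    outer(beta, as.numeric(geno == "g2"))
  d <- tibble::tibble(run_id = colnames(Y), batch = batch, acq_order = 1:n,
                      sample_type = "study", strain = geno, replicate_id = 1)
  corr <- apply_combat(make_qm(Y), fit_combat(make_qm(Y), d,
                                              covariates = "strain"))
  diff_corr <- rowMeans(corr$values[, geno == "g2"]) -
    rowMeans(corr$values[, geno == "g1"])
  expect_gt(cor(diff_corr, beta), 0.95)
  expect_lt(median(abs(diff_corr - beta)), 0.2)
})

test_that("missing cells stay missing and thin features pass through flagged", {
  set.seed(50)
  Y <- matrix(rnorm(8 * 10, 10, 1), 8, 10,
              dimnames = list(sprintf("f%02d", 1:8), sprintf("r%02d", 1:10)))
  Y[1, 2] <- NA
  Y[2, 6:10] <- NA   # batch b2 has < 2 measurements for f02
  Y[2, 6] <- 11
  d <- two_batch_design(10)
  m <- fit_combat(make_qm(Y), d, shrink = FALSE)
  expect_equal(m$excluded$precursor_id, "f02")
  corr <- apply_combat(make_qm(Y), m)
  expect_identical(is.na(corr$values), is.na(Y))
  expect_equal(corr$values[2, ], Y[2, ])  # passthrough
})

test_that("confounded designs and foreign runs are rejected with clear errors", {
  set.seed(60)
  Y <- matrix(rnorm(40, 10, 1), 4, 10,
              dimnames = list(sprintf("f%d", 1:4), sprintf("r%02d", 1:10)))
  d <- two_batch_design(10)
  d$strain <- d$batch   # covariate identical to batch
  expect_error(fit_combat(make_qm(Y), d, covariates = "strain"),
               "rank deficient")
  d2 <- two_batch_design(10)
  m <- fit_combat(make_qm(Y), d2, shrink = FALSE)
  Y2 <- Y; colnames(Y2)[1] <- "alien"
  expect_error(apply_combat(make_qm(Y2), m), "absent from the fitted design")
  expect_error(fit_combat(make_qm(Y), d2, shrink = TRUE, tol = 0, max_iter = 1),
               "did not converge")
})
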