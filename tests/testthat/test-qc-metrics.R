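test_that("CVs match hand computations and respect the two-value minimum", {
  Y <- rbind(flat = c(10, 10, 10, 10),
             pair = c(8, 12, NA, NA),
             lone = c(5, NA, NA, NA))
  colnames(Y) <- sprintf("r%02d", 1:4)
  d <- tibble::tibble(run_id = colnames(Y), batch = "b1", acq_order = 1:4,
                      sample_type = "QC", strain = "QC", replicate_id = 1:4)
  cv <- cv_table(make_qm(Y, "linear"), d, grouping = "qc_inter")
  expect_equal(cv$cv[cv$precursor_id == "flat"], 0)
  expect_equal(cv$cv[cv$precursor_id == "pair"], 100 * 2 * sqrt(2) / 10,
               tolerance = 1e-12)
  expect_true(is.na(cv$cv[cv$precursor_id == "lone"]))
})

test_that("CV is invariant to rescaling a group and matches the lognormal closed form", {
  set.seed(31)
  Y <- matrix(exp(rnorm(50 * 6, 8, 0.5)), 50, 6,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("r%d", 1:6)))
  d <- tibble::tibble(run_id = colnames(Y), batch = "b1", acq_order = 1:6,
                      sample_type = "QC", strain = "QC", replicate_id = 1:6)
  cv1 <- cv_table(make_qm(Y, "linear"), d, grouping = "qc_inter")
  cv2 <- cv_table(make_qm(Y * 1e3, "linear"), d, grouping = "qc_inter")
  expect_equal(cv2$cv, cv1$cv, tolerance = 1e-9)

  sigma <- 0.1
  set.seed(32)
  Y2 <- matrix(2^rnorm(500 * 50, 10, sigma), 500, 50,
               dimnames = list(sprintf("f%03d", 1:500), sprintf("r%02d", 1:50)))
  d2 <- tibble::tibble(run_id = colnames(Y2), batch = "b1", acq_order = 1:50,
                       sample_type = "QC", strain = "QC", replicate_id = 1:50)
  cv <- cv_table(make_qm(Y2, "linear"), d2, grouping = "qc_inter")
  expect_equal(median(cv$cv) / 100, lognormal_cv(sigma), tolerance = 0.05)
})

test_that("variability reduction reproduces its defining arithmetic", {
  expect_equal(variability_reduction(39.7, 22.3), 100 * (39.7 - 22.3) / 39.7,
               tolerance = 1e-12)
  expect_equal(round(variability_reduction(39.7, 22.3), 1), 43.8)
  expect_equal(variability_reduction(10, 10), 0)
  expect_lt(variability_reduction(10, 12), 0)
  expect_error(variability_reduction(0, 5), "zero or undefined")
})

test_that("variability reduction on CV tables uses the total-CV medians", {
  sim <- small_sim()
  qm <- pivot_to_matrix(sim$report[!sim$report$is_standard, ], "linear")
  cv <- cv_table(qm, sim$design)
  expect_equal(variability_reduction(cv, cv), 0)
  mismatched <- cv[-(1:3), ]
  expect_error(variability_reduction(cv, mismatched), "same features")
})

test_that("QC groups show intra-batch CV below cross-batch CV under batch effects", {
  p <- truth_params(n_proteins = 60, n_strains = 4, replicates_per_strain = 3,
                    qc_every = c(3, 3), batch_add_sd = 0.35, seed = 88)
  sim <- simulate_dia(p)
  qm <- pivot_to_matrix(sim$report[!sim$report$is_standard, ], "linear")
  norm <- robust_sum_normalize(qm)
  cv <- cv_table(norm$matrix, sim$design)
  s <- cv_summary(cv)
  expect_lt(s$median_cv[s$group_type == "qc_intra"],
            s$median_cv[s$group_type == "qc_inter"])
})

test_that("batch diagnostics quantify planted batch structure and its removal", {
  set.seed(41)
  G <- 120; n <- 24
  batch <- rep(c("b1", "b2"), each = 12)
  Y <- matrix(rnorm(G * n, 10, 0.3), G, n,
              dimnames = list(sprintf("f%03d", 1:G), sprintf("r%02d", 1:n))) +
    outer(rnorm(G, 0, 1.2), as.numeric(batch == "b2"))
  d <- toy_design(n, n_batches = 2)
  qm <- make_qm(Y)
  before <- batch_diagnostics(qm, d)
  after <- batch_diagnostics(apply_combat(qm, fit_combat(qm, d)), d)
  expect_gt(before$silhouette, 0.2)
  expect_gt(before$silhouette, after$silhouette)
  expect_gt(median(before$r2$batch_r2), median(after$r2$batch_r2))
})

test_that("shuffled batch labels give near-zero silhouette", {
  set.seed(42)
  G <- 80; n <- 24
  Y <- matrix(rnorm(G * n, 10, 1), G, n,
              dimnames = list(sprintf("f%02d", 1:G), sprintf("r%02d", 1:n)))
  sils <- vapply(1:20, function(i) {
    d <- toy_design(n, n_batches = 2)
    d$batch <- sample(d$batch)
    batch_diagnostics(make_qm(Y), d)$silhouette
  }, numeric(1))
  expect_lt(mean(abs(sils)), 0.1)
  expect_lt(max(abs(sils)), 0.3)
})

test_that("degenerate diagnostics inputs error cleanly", {
  Y <- matrix(rnorm(20), 4, 5,
              dimnames = list(sprintf("f%d", 1:4), sprintf("r%02d", 1:5)))
  d <- toy_design(5, n_batches = 1)
  expect_error(batch_diagnostics(make_qm(Y), d), ">= 2 batches")
  d2 <- toy_design(5, n_batches = 2)
  expect_error(cv_table(make_qm(2^Y, "linear"),
                        d2[d2$sample_type == "QC", ], grouping = "qc_intra"),
               "No group")
})
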