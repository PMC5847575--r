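# build a standards-only report from a run x standard RT matrix
standards_report <- function(rt_by_run, ref = irt_reference()) {
  runs <- rownames(rt_by_run)
  idx <- which(!is.na(rt_by_run), arr.ind = TRUE)
  tibble::tibble(
    run_id = runs[idx[, "row"]],
    precursor_id = paste0(colnames(rt_by_run)[idx[, "col"]], "/2"),
    protein_id = "iRT_standard",
    intensity = 1e5,
    qvalue = 1e-4,
    rt_observed = rt_by_run[idx],
    is_standard = TRUE
  )
}

test_that("an exactly linear run recovers slope, intercept and zero residual", {
  ref <- irt_reference()
  rt <- matrix(2 * ref$irt + 300, nrow = 1,
               dimnames = list("r1", ref$peptide_id))
  # a second run so rt_stability preconditions hold elsewhere
  rt <- rbind(rt, r2 = 2 * ref$irt + 300)
  rownames(rt) <- c("r1", "r2")
  cal <- fit_rt_calibration(standards_report(rt))
  row <- cal$runs[cal$runs$run_id == "r1", ]
  expect_equal(row$slope, 2, tolerance = 1e-12)
  expect_equal(row$intercept, 300, tolerance = 1e-9)
  expect_equal(row$residual_sd, 0, tolerance = 1e-9)
  expect_true(row$fitted)
})

test_that("OLS matches the hand-solved normal equations with an outlier standard", {
  ref <- irt_reference()[1:6, ]
  x <- ref$irt
  y <- 1.8 * x + 250
  y[4] <- y[4] + 10   # one 10-second outlier
  rt <- matrix(y, nrow = 1, dimnames = list("r1", ref$peptide_id))
  rt <- rbind(rt, r2 = y); rownames(rt) <- c("r1", "r2")
  cal <- fit_rt_calibration(standards_report(rt, ref), reference = ref)
  # independent oracle: closed-form normal-equation solution
  slope_hat <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  intercept_hat <- mean(y) - slope_hat * mean(x)
  row <- cal$runs[cal$runs$run_id == "r1", ]
  expect_equal(row$slope, slope_hat, tolerance = 1e-12)
  expect_equal(row$intercept, intercept_hat, tolerance = 1e-12)
  expect_equal(row$n_standards, 6L)
})

test_that("runs without enough standards are flagged unfit, all-unfit errors", {
  ref <- irt_reference()
  rt <- matrix(c(2 * ref$irt[1:5] + 300, rep(NA, 6),
                 500, rep(NA, 10)),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("good", "bad"), ref$peptide_id))
  cal <- fit_rt_calibration(standards_report(rt))
  expect_true(cal$runs$fitted[cal$runs$run_id == "good"])
  expect_false(cal$runs$fitted[cal$runs$run_id == "bad"])
  expect_error(to_irt(cal, "bad", 500), "unfit")
  one <- matrix(c(500, rep(NA, 10)), nrow = 1,
                dimnames = list("r1", ref$peptide_id))
  expect_error(fit_rt_calibration(standards_report(one)), "calibrated")
})

test_that("to_irt inverts the fitted map", {
  ref <- irt_reference()
  rt <- matrix(rep(2 * ref$irt + 300, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("r1", "r2"), ref$peptide_id))
  cal <- fit_rt_calibration(standards_report(rt))
  expect_equal(to_irt(cal, "r1", 500), 100, tolerance = 1e-9)
  x <- c(-20, 0, 55.5, 99)
  rt_fwd <- cal$runs$intercept[1] + cal$runs$slope[1] * x
  expect_equal(to_irt(cal, "r1", rt_fwd), x, tolerance = 1e-9)
  # vectorized equals elementwise
  expect_equal(to_irt(cal, "r1", rt_fwd),
               vapply(rt_fwd, function(v) to_irt(cal, "r1", v), numeric(1)))
  expect_error(to_irt(cal, "nope", 1), "not in calibration")
})

test_that("calibrating a run against its own standards gives the identity map", {
  ref <- irt_reference()
  set.seed(3)
  obs <- 25 * ref$irt + 400 + rnorm(11, 0, 5)
  rt <- matrix(rep(obs, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("r1", "r2"), ref$peptide_id))
  self_ref <- tibble::tibble(peptide_id = ref$peptide_id, irt = obs)
  cal <- fit_rt_calibration(standards_report(rt, self_ref), reference = self_ref)
  expect_equal(cal$runs$slope[1], 1, tolerance = 1e-9)
  expect_equal(cal$runs$intercept[1], 0, tolerance = 1e-9)
})

test_that("rt_stability reports per-standard SD/CV and is order-invariant", {
  ref <- irt_reference()
  rt <- matrix(rep(2 * ref$irt + 300, 3), nrow = 3, byrow = TRUE,
               dimnames = list(c("r1", "r2", "r3"), ref$peptide_id))
  stab <- rt_stability(standards_report(rt))
  expect_equal(max(stab$per_standard$sd_seconds), 0)
  expect_equal(max(stab$per_standard$cv_percent), 0)

  rt2 <- matrix(c(100, 102), nrow = 2,
                dimnames = list(c("r1", "r2"), ref$peptide_id[6]))
  rep2 <- standards_report(rt2)
  # need a second standard for calibration; add a fixed far point
  rt2b <- cbind(rt2, matrix(c(2000, 2002), 2,
                            dimnames = list(NULL, ref$peptide_id[11])))
  stab2 <- rt_stability(standards_report(rt2b))
  expect_equal(stab2$per_standard$sd_seconds, rep(sqrt(2), 2), tolerance = 1e-12)

  sim <- small_sim()
  shuffled <- sim$report[sample.int(nrow(sim$report)), ]
  a <- rt_stability(sim$report)
  b <- rt_stability(shuffled)
  expect_equal(b$per_standard$cv_percent, a$per_standard$cv_percent)
})

test_that("the robust calibration resists a gross outlier better than OLS", {
  ref <- irt_reference()
  y <- 24 * ref$irt + 400
  y[2] <- y[2] + 500
  rt <- matrix(rep(y, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("r1", "r2"), ref$peptide_id))
  rep <- standards_report(rt)
  ols <- fit_rt_calibration(rep, method = "ols")
  rob <- fit_rt_calibration(rep, method = "robust")
  expect_lt(abs(rob$runs$slope[1] - 24), abs(ols$runs$slope[1] - 24))
  expect_equal(rob$runs$slope[1], 24, tolerance = 1e-6)
})
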