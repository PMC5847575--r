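test_that("standard SWATH schemes give the published window counts", {
  wide <- design_windows(400, 1250, 25, t_acc = 0.100)
  expect_equal(wide$n_windows, 34L)
  narrow <- design_windows(400, 850, 16, t_acc = 0.040)
  expect_equal(narrow$n_windows, 29L)
  single <- design_windows(400, 500, 100)
  expect_equal(single$n_windows, 1L)
  expect_equal(single$windows$mz_end, 500)
})

test_that("window tilings are contiguous and cover the range", {
  for (args in list(c(400, 1250, 25), c(400, 850, 16), c(395.5, 1003.2, 7.8))) {
    s <- design_windows(args[1], args[2], args[3])
    w <- s$windows
    expect_equal(w$mz_start[1], args[1])
    expect_equal(w$mz_start[-1], w$mz_end[-nrow(w)], tolerance = 1e-9)
    expect_gte(w$mz_end[nrow(w)], args[2])
    expect_lt(w$mz_start[nrow(w)], args[2])
  }
  expect_error(design_windows(400, 850, -5), "width")
  expect_error(design_windows(850, 400, 25), "mz_high")
})

test_that("window count shrinks with width; cycle time grows with windows and dwell", {
  widths <- c(5, 10, 16, 25, 50)
  counts <- vapply(widths, function(w) design_windows(400, 850, w)$n_windows,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  cycles_n <- vapply(widths, function(w) design_windows(400, 850, w, t_acc = 0.04)$t_cycle,
                     numeric(1))
  expect_true(all(diff(cycles_n) < 0))
  cycles_acc <- vapply(c(0.02, 0.04, 0.1), function(a) {
    design_windows(400, 850, 16, t_acc = a)$t_cycle
  }, numeric(1))
  expect_true(all(diff(cycles_acc) > 0))
})

test_that("points per peak follow the Gaussian base-width arithmetic", {
  # 29 x 16 Th windows at 40 ms dwell with 0.14 s overhead: 1.3 s cycle
  s <- design_windows(400, 850, 16, t_acc = 0.040, t_survey = 0.14)
  expect_equal(s$t_cycle, 1.30, tolerance = 1e-9)
  peak <- peak_model(fwhm = 12)
  expect_equal(peak$base_width, 12 * 4 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  ppp <- points_per_peak(s, peak)
  expect_equal(ppp, peak$base_width / 1.3, tolerance = 1e-12)
  expect_equal(ppp, 15.7, tolerance = 0.02)
  expect_gt(ppp, 11)

  # cycle equal to the base width: exactly one point
  s1 <- design_windows(400, 500, 100, t_acc = peak$base_width, t_survey = 0)
  expect_equal(points_per_peak(s1, peak), 1, tolerance = 1e-12)

  # halving the cycle doubles the sampling
  half <- design_windows(400, 850, 16, t_acc = 0.020, t_survey = 0.07)
  expect_equal(points_per_peak(half, peak), 2 * ppp, tolerance = 1e-9)
})

test_that("peak capacity follows the closed form and its limits", {
  pc <- peak_capacity(3600, 12)
  expect_equal(pc, 1 + 3600 / (12 * 4 / (2 * sqrt(2 * log(2)))), tolerance = 1e-12)
  expect_equal(pc, 177.6, tolerance = 0.05)
  expect_equal(peak_capacity(3600, 1e9), 1, tolerance = 1e-5)
  expect_equal(peak_capacity(7200, 12) - 1, 2 * (pc - 1), tolerance = 1e-9)
})

test_that("mass-range coverage counts precursors and proteins correctly", {
  lib <- tibble::tibble(
    mz = c(450, 500, 600, 700, 800, 820, 840, 900, 1000, 1100),
    protein_id = c("A", "A", "B", "B", "C", "C", "D", "A", "B", "D")
  )
  cov <- mass_range_coverage(lib, 400, 850)
  expect_equal(cov$precursor_fraction, 0.7)
  expect_equal(cov$protein_fraction, 1.0)
  full <- mass_range_coverage(lib, 0, 2000)
  expect_equal(c(full$precursor_fraction, full$protein_fraction), c(1, 1))
  # protein fraction can fall below precursor fraction
  lib2 <- tibble::tibble(mz = c(500, 510, 900), protein_id = c("A", "A", "B"))
  cov2 <- mass_range_coverage(lib2, 400, 850)
  expect_equal(cov2$precursor_fraction, 2 / 3)
  expect_equal(cov2$protein_fraction, 1 / 2)
  expect_lt(cov2$protein_fraction, cov2$precursor_fraction)
  expect_error(mass_range_coverage(lib[0, ], 400, 850), "Empty")
})

test_that("coverage is monotone as the range widens", {
  set.seed(51)
  lib <- tibble::tibble(mz = runif(200, 300, 1300),
                        protein_id = sample(sprintf("P%02d", 1:40), 200, TRUE))
  highs <- seq(500, 1300, by = 100)
  cov <- vapply(highs, function(h) {
    unlist(mass_range_coverage(lib, 400, h)[1, c("precursor_fraction", "protein_fraction")])
  }, numeric(2))
  expect_true(all(diff(cov[1, ]) >= 0))
  expect_true(all(diff(cov[2, ]) >= 0))
})
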