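test_that("an anti-correlated peptide is eliminated from a trio", {
  x <- seq_len(10)
  Y <- rbind(pep1 = x + 10, pep2 = x * 1.1 + 10, pep3 = -x + 30)
  colnames(Y) <- sprintf("r%02d", 1:10)
  qm <- make_qm(Y, proteins = rep("PROT", 3))
  g <- select_peptides(qm, rho_min = 0.5, min_overlap = 4)
  expect_setequal(g$selected$PROT, c("pep1", "pep2"))
  aud <- tidy(g)
  expect_false(aud$kept[aud$precursor_id == "pep3"])
  expect_equal(aud$removal_round[aud$precursor_id == "pep3"], 1L)
})

test_that("two-peptide proteins keep all members and carry the unselected flag", {
  Y <- rbind(pep1 = 1:6, pep2 = -(1:6))
  colnames(Y) <- sprintf("r%d", 1:6)
  qm <- make_qm(Y * 1.0, proteins = rep("PROT", 2))
  g <- select_peptides(qm, rho_min = 0.5, min_overlap = 4)
  expect_setequal(g$selected$PROT, c("pep1", "pep2"))
  expect_true(all(tidy(g)$unselected))
})

test_that("a planted independent-noise peptide is the one removed", {
  set.seed(21)
  n <- 40
  profile <- rnorm(n, 12, 1)
  Y <- t(vapply(1:5, function(i) profile + rnorm(n, 0, 0.3), numeric(n)))
  Y <- rbind(Y, rnorm(n, 12, 1))   # decorrelated peptide
  rownames(Y) <- sprintf("pep%d", 1:6)
  colnames(Y) <- sprintf("r%02d", 1:n)
  qm <- make_qm(Y, proteins = rep("PROT", 6))
  g <- select_peptides(qm, rho_min = 0.5)
  expect_setequal(g$selected$PROT, sprintf("pep%d", 1:5))
  # brute-force check: the removed member had the minimal mean pairwise correlation
  cm <- cor(t(Y))
  diag(cm) <- NA
  expect_equal(which.min(rowMeans(cm, na.rm = TRUE)), c(pep6 = 6L))
})

test_that("selection is invariant to member input order", {
  set.seed(22)
  Y <- matrix(rnorm(6 * 20, 10, 1), 6, 20,
              dimnames = list(sprintf("pep%d", 1:6), sprintf("r%02d", 1:20)))
  Y[1:4, ] <- Y[1:4, ] + rep(3 * sin(seq_len(20)), each = 4)
  qm1 <- make_qm(Y, proteins = rep("PROT", 6))
  perm <- c(4, 2, 6, 1, 3, 5)
  qm2 <- make_qm(Y[perm, ], proteins = rep("PROT", 6))
  g1 <- select_peptides(qm1, rho_min = 0.5)
  g2 <- select_peptides(qm2, rho_min = 0.5)
  expect_setequal(g1$selected$PROT, g2$selected$PROT)
})

test_that("pairs with too little overlap score missing and are removed first", {
  Y <- rbind(pep1 = c(1:8, NA, NA), pep2 = c(1:8 + 0.1, NA, NA),
             pep3 = c(NA, NA, NA, NA, NA, NA, NA, NA, 5, 6))
  colnames(Y) <- sprintf("r%02d", 1:10)
  qm <- make_qm(Y, proteins = rep("PROT", 3))
  g <- select_peptides(qm, rho_min = 0.5, min_overlap = 6)
  expect_setequal(g$selected$PROT, c("pep1", "pep2"))
})

test_that("geometric rollup matches hand-computed values", {
  Y <- rbind(pepA = c(4, 4, 4), pepB = c(16, 16, NA))
  colnames(Y) <- sprintf("r%d", 1:3)
  qm <- make_qm(Y, "linear", proteins = rep("PROT", 2))
  pm <- rollup_geometric(qm, min_present_fraction = 0.5)
  expect_equal(unname(pm$values["PROT", ]), c(8, 8, 4))

  # single-peptide protein: identity
  qm1 <- make_qm(Y[1, , drop = FALSE], "linear", proteins = "SOLO")
  expect_equal(unname(rollup_geometric(qm1)$values["SOLO", ]), c(4, 4, 4))

  # three peptides, one missing, min_present_fraction 0.5: mean of the present two
  Y3 <- rbind(p1 = c(2, 2), p2 = c(8, 8), p3 = c(NA, 32))
  colnames(Y3) <- c("r1", "r2")
  qm3 <- make_qm(Y3, "linear", proteins = rep("PROT", 3))
  pm3 <- rollup_geometric(qm3, min_present_fraction = 0.5)
  expect_equal(unname(pm3$values["PROT", "r1"]), 4)        # gm(2, 8)
  expect_equal(unname(pm3$values["PROT", "r2"]), 8)        # gm(2, 8, 32)
})

test_that("below the presence threshold the protein value is missing", {
  Y3 <- rbind(p1 = c(2, NA), p2 = c(8, NA), p3 = c(4, 32))
  colnames(Y3) <- c("r1", "r2")
  qm3 <- make_qm(Y3, "linear", proteins = rep("PROT", 3))
  pm <- rollup_geometric(qm3, min_present_fraction = 0.5)
  expect_true(is.na(pm$values["PROT", "r2"]))
})

test_that("log2 of the protein value equals the mean of member log2 values", {
  set.seed(23)
  Y <- matrix(exp(rnorm(12 * 6, 8, 1)), 12, 6,
              dimnames = list(sprintf("pep%02d", 1:12), sprintf("r%d", 1:6)))
  qm <- make_qm(Y, "linear", proteins = rep(c("A", "B", "C"), each = 4))
  pm <- rollup_geometric(qm, min_present_fraction = 0)
  for (p in c("A", "B", "C")) {
    members <- rownames(Y)[qm$mapping$protein_id == p]
    expect_equal(log2(pm$values[p, ]), colMeans(log2(Y[members, ])),
                 tolerance = 1e-12)
  }
})

test_that("rollup is equivariant under global rescaling", {
  set.seed(24)
  Y <- matrix(exp(rnorm(8 * 5, 8, 1)), 8, 5,
              dimnames = list(sprintf("pep%d", 1:8), sprintf("r%d", 1:5)))
  qm <- make_qm(Y, "linear", proteins = rep(c("A", "B"), each = 4))
  pm1 <- rollup_geometric(qm)
  pm2 <- rollup_geometric(make_qm(Y * 3.7, "linear",
                                  proteins = rep(c("A", "B"), each = 4)))
  expect_equal(pm2$values, pm1$values * 3.7, tolerance = 1e-9)
})

test_that("groups referencing absent precursors are an error", {
  Y <- matrix(1:12 * 1.0, 4, 3,
              dimnames = list(sprintf("pep%d", 1:4), sprintf("r%d", 1:3)))
  qm <- make_qm(Y, "log2", proteins = rep("PROT", 4))
  g <- select_peptides(qm, min_overlap = 2)
  qm_small <- make_qm(Y[1:2, ], "log2", proteins = rep("PROT", 2))
  expect_error(rollup_geometric(qm_small, g), "absent from the matrix")
})

test_that("rolled-up proteins track truth at least as well as a median peptide", {
  set.seed(25)
  n <- 30
  better <- 0L
  for (i in 1:40) {
    truth <- rnorm(n, 12, 1)
    Y <- t(vapply(1:4, function(j) truth + rnorm(n, 0, 0.6), numeric(n)))
    rownames(Y) <- sprintf("pep%d", 1:4)
    colnames(Y) <- sprintf("r%02d", 1:n)
    qm <- make_qm(Y, "log2", proteins = rep("P", 4))
    pm <- rollup_geometric(qm, select_peptides(qm, rho_min = 0))
    r_prot <- cor(pm$values["P", ], truth)
    r_peps <- apply(Y, 1, cor, truth)
    if (r_prot >= median(r_peps)) better <- better + 1L
  }
  expect_gte(better, 36L)
})
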