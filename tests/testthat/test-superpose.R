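test_that("superposing a structure on an exact rigid copy gives zero RMSD", {
  m <- make_ca_model(n = 10, jitter = 0.3, seed = 4)
  tr <- random_rigid_transform(11)
  m2 <- transform_model(m, tr)
  pairing <- data.frame(chain_a = "A", resno_a = 1:10,
                        chain_b = "A", resno_b = 1:10)
  res <- superpose_calpha(m, m2, pairing)
  expect_lt(res$overall_rmsd, 1e-9)
  expect_true(all(res$per_residue_rmsd$rmsd < 1e-9))
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
})

test_that("RMSD is invariant under rigid pre-transforms of either input", {
  m1 <- make_ca_model(n = 12, jitter = 0.4, seed = 5)
  m2 <- make_ca_model(n = 12, jitter = 0.4, seed = 6)
  pairing <- data.frame(chain_a = "A", resno_a = 1:12,
                        chain_b = "A", resno_b = 1:12)
  base <- superpose_calpha(m1, m2, pairing)$overall_rmsd
  for (s in 1:5) {
    r1 <- superpose_calpha(transform_model(m1, random_rigid_transform(s)),
                           m2, pairing)$overall_rmsd
    r2 <- superpose_calpha(m1,
                           transform_model(m2,
                                           random_rigid_transform(s + 50)),
                           pairing)$overall_rmsd
    expect_equal(r1, base, tolerance = 1e-6)
    expect_equal(r2, base, tolerance = 1e-6)
  }
})

test_that("overall RMSD is consistent with the per-residue profile", {
  m1 <- make_ca_model(n = 9, jitter = 0.5, seed = 7)
  m2 <- make_ca_model(n = 9, jitter = 0.5, seed = 8)
  pairing <- data.frame(chain_a = "A", resno_a = 1:9,
                        chain_b = "A", resno_b = 1:9)
  res <- superpose_calpha(m1, m2, pairing)
  expect_equal(res$overall_rmsd^2, mean(res$per_residue_rmsd$rmsd^2),
               tolerance = 1e-12)
})

test_that("closed-form solution beats a brute-force rotation grid", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(4:10, 1)
    X <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    tr <- random_rigid_transform(s + 100)
    Y <- apply_rigid(X, tr) + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
    fit <- kabsch(X, Y)
    oracle <- grid_superpose_rmsd(X, Y, step_deg = 15)
    expect_lte(fit$rmsd, oracle + 1e-9)
    # with a fine grid on a small case the two agree closely
    if (n <= 6) {
      fine <- grid_superpose_rmsd(X, Y, step_deg = 6)
      expect_lt(abs(fit$rmsd - fine), 0.05)
    }
  }
})

test_that("degenerate collinear inputs are flagged but still solved", {
  X <- cbind(1:5, 0, 0)
  Y <- cbind(0, 1:5, 0)
  expect_warning(
    res <- superpose_calpha(
      read_structure(write_pdb_fixture(vapply(1:5, function(i)
        pdb_line(i, "CA", "ALA", "A", i, X[i, 1], X[i, 2], X[i, 3],
                 element = "C"), character(1)))),
      read_structure(write_pdb_fixture(vapply(1:5, function(i)
        pdb_line(i, "CA", "ALA", "A", i, Y[i, 1], Y[i, 2], Y[i, 3],
                 element = "C"), character(1)))),
      data.frame(chain_a = "A", resno_a = 1:5,
                 chain_b = "A", resno_b = 1:5)),
    "degenerate")
  expect_lt(res$overall_rmsd, 1e-9)
})

test_that("pairing requires at least three residue pairs with CA atoms", {
  m <- make_ca_model(n = 5)
  expect_error(superpose_calpha(m, m, data.frame(
    chain_a = "A", resno_a = 1:2, chain_b = "A", resno_b = 1:2)),
    "at least 3")
  expect_error(superpose_calpha(m, m, data.frame(
    chain_a = "A", resno_a = c(1, 2, 99), chain_b = "A",
    resno_b = c(1, 2, 99))), "no CA atom")
})

test_that("sequence alignment recovers the residue pairing across a gap", {
  seqA <- c("MET", "LYS", "TRP", "VAL", "PHE", "GLY", "LEU", "TYR", "SER",
            "ALA")
  # same protein with two residues missing in the middle, renumbered
  keep <- c(1:4, 7:10)
  m1 <- make_ca_model(n = 10, seq3 = seqA, jitter = 0.2, seed = 9)
  lines <- vapply(seq_along(keep), function(i) {
    at <- m1$atoms[keep[i], ]
    pdb_line(i, "CA", at$resid, "B", i + 100, at$x, at$y, at$z,
             element = "C")
  }, character(1))
  m2 <- read_structure(write_pdb_fixture(lines))
  pairing <- align_ca_pairs(m1, m2, "A", "B")
  expect_equal(nrow(pairing), 8)
  expect_equal(pairing$resno_a, keep)
  expect_equal(pairing$resno_b, seq_along(keep) + 100)
  res <- superpose_calpha(m1, m2, pairing)
  expect_lt(res$overall_rmsd, 1e-9)
})

test_that("profile report flags only residues at or above 2 Angstrom", {
  m1 <- make_ca_model(n = 8, jitter = 0, seed = 1)
  m2 <- make_ca_model(n = 8, jitter = 0, seed = 1)
  # displace one residue far enough that it stays flagged after refitting
  m2$atoms$x[5] <- m2$atoms$x[5] + 5
  pairing <- data.frame(chain_a = "A", resno_a = 1:8,
                        chain_b = "A", resno_b = 1:8)
  res <- superpose_calpha(m1, m2, pairing)
  rep <- rmsd_profile_report(res, out = tempfile(fileext = ".tsv"))
  expect_equal(sum(rep$divergent), 1)
  # all-zero profile flags nothing
  res0 <- superpose_calpha(m1, m1, pairing)
  expect_equal(sum(rmsd_profile_report(res0)$divergent), 0)
})
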