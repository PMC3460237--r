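test_that("toy pockets are deterministic and exactly on the stated radius", {
  spec <- fixture_spec(seed = 13, cavity_radius = 6, n_shell = 60,
                      include_probe = FALSE)
  d1 <- tempfile("p1"); d2 <- tempfile("p2")
  p1 <- make_toy_pocket(spec, dir = d1)
  p2 <- make_toy_pocket(spec, dir = d2)
  expect_identical(readLines(p1$pdb), readLines(p2$pdb))   # byte-identical
  expect_equal(nrow(p1$query$volumes), 60)
  shell <- p1$model$atoms[p1$model$atoms$chain == "S", ]
  r <- sqrt(shell$x^2 + shell$y^2 + shell$z^2)
  expect_lt(max(abs(r - 6)), 1e-6)
  # infeasible geometry is rejected
  expect_error(fixture_spec(cavity_radius = 2.0), "exceed")
})

test_that("sealed shells leave no gap an atom center could slip through", {
  spec <- fixture_spec(seed = 13, cavity_radius = 4.2, sealed = TRUE,
                       include_probe = FALSE)
  q <- make_toy_pocket(spec)$query
  C <- as.matrix(q$volumes[, c("x", "y", "z")])
  set.seed(99)
  rr <- runif(4000, 4.2 - 0.5, 4.2 + 1.2)
  u <- matrix(rnorm(12000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  samp <- u * rr
  d2min <- apply(pocketfunnel:::cross_dist2(samp, C), 1, min)
  expect_lt(sqrt(max(d2min)), 0.8)
})

test_that("pose generators reproduce their planted distances on readback", {
  dir <- tempfile("ps")
  ps <- make_pose_set(fixture_spec(seed = 31, n_poses = 8, n_hbond = 1),
                      dir = dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  pl <- load_poses(ps$poses_file, score_field = "SCORE")
  cfg <- filter_config()
  for (p in pl$poses) {
    planted <- ps$truth$planted_dist[ps$truth$id == p$id]
    expect_equal(cation_pi_distance(p, ps$receptor, cfg), planted,
                 tolerance = 1e-9)
  }
  # the three boundary poses encode the cutoff semantics
  expect_equal(ps$truth$expect_keep[1:3],
               ps$truth$planted_dist[1:3] <= 5.5 + 1e-9)
})

test_that("match fixtures carry provable verdict labels", {
  for (kind in c("pass", "fail_sealed", "fail_plug")) {
    fx <- make_match_fixture(64, kind)
    expect_s3_class(fx$query, "PharmacophoreQuery")
    expect_equal(nrow(fx$coords), if (kind == "fail_sealed") 4 else 3)
    expect_equal(fx$expected, kind == "pass")
    # ligand really is collinear (oracle precondition)
    d <- fx$coords
    v1 <- d[2, ] - d[1, ]; v2 <- d[3, ] - d[1, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_equal(abs(cosang), 1, tolerance = 1e-9)
  }
})

test_that("the funnel fixture regenerates identically from its seed", {
  d1 <- tempfile("ff1"); d2 <- tempfile("ff2")
  f1 <- make_funnel_fixture(d1, seed = 3)
  f2 <- make_funnel_fixture(d2, seed = 3)
  for (f in c("library.smi", "query.txt", "poses.sdf", "refs.smi",
              "pocket.pdb")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_identical(f1$expected, f2$expected)
})
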