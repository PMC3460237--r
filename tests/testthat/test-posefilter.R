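# one shared small planted pose set for this file
ps_dir <- tempfile("poseset")
ps <- make_pose_set(fixture_spec(seed = 21, n_poses = 12, n_hbond = 2),
                    dir = ps_dir)
loaded <- load_poses(ps$poses_file, format = "sdf", score_field = "SCORE")

test_that("pose loading assigns per-ligand ranks and skips unscored poses", {
  expect_length(loaded$poses, 14)
  expect_true(all(vapply(loaded$poses, `[[`, integer(1), "rank") == 1))

  # a file where one pose misses the score field
  rec <- pocketfunnel:::pose_ligand_record("L1")
  path <- tempfile(fileext = ".sdf")
  write_ligands_sdf(list(rec, rec, rec), path,
                    coords_list = ps$coords[1:3],
                    data_list = list(list(SCORE = "10.0"),
                                     list(OTHER = "x"),
                                     list(SCORE = "12.0")))
  out <- load_poses(path, score_field = "SCORE")
  expect_length(out$poses, 2)
  expect_equal(nrow(out$skipped), 1)
  # same ligand id: ranks follow descending score
  scores <- vapply(out$poses, `[[`, numeric(1), "score")
  ranks <- vapply(out$poses, `[[`, integer(1), "rank")
  expect_equal(ranks[order(-scores)], 1:2)

  expect_error(load_poses(tempfile(fileext = ".sdf")))
})

test_that("pose coordinates survive a write/read round trip", {
  for (i in c(1, 5, 14)) {
    got <- as.matrix(loaded$poses[[i]]$atoms[, c("x", "y", "z")])
    expect_lt(max(abs(got - ps$coords[[i]])), 1e-4 + 1e-9)
  }
})

test_that("cation-pi distances match planted values and direct norms", {
  cfg <- filter_config()
  for (i in seq_along(loaded$poses)) {
    p <- loaded$poses[[i]]
    d <- cation_pi_distance(p, ps$receptor, cfg)
    expect_equal(d, ps$truth$planted_dist[ps$truth$id == p$id],
                 tolerance = 1e-9)
    # direct-norm oracle
    ref <- as.numeric(get_atom(ps$receptor,
                               atom_address("A", 145, "CD2"))[
                                 1, c("x", "y", "z")])
    pts <- as.matrix(p$atoms[p$cationic, c("x", "y", "z")])
    expect_equal(d, min(sqrt(colSums((t(pts) - ref)^2))), tolerance = 1e-12)
  }
  # coincident nitrogen gives zero
  p0 <- loaded$poses[[1]]
  ref <- as.numeric(get_atom(ps$receptor, atom_address("A", 145, "CD2"))[
    1, c("x", "y", "z")])
  p0$atoms[p0$cationic[1], c("x", "y", "z")] <- as.list(ref)
  expect_equal(cation_pi_distance(p0, ps$receptor, filter_config()), 0)
})

test_that("the distance cutoff keeps at-or-below and discards above", {
  fl <- apply_filters(loaded$poses, ps$receptor, filter_config())
  m <- match(ps$truth$id, fl$report$ligand)
  expect_equal(fl$report$kept[m], ps$truth$expect_keep)
  # the boundary pose at exactly 5.5 A is kept (<= semantics)
  b_idx <- which(abs(ps$truth$planted_dist - 5.5) < 1e-3)
  if (length(b_idx)) {
    keep_at_boundary <- ps$truth$planted_dist[b_idx] <= 5.5 + 1e-9
    expect_equal(fl$report$kept[m][b_idx], keep_at_boundary)
  }
  # a pose at 5.6 A fails with capi_pass FALSE but still gets a report
  far <- which(ps$truth$planted_dist > 5.55)[1]
  expect_false(fl$report$capi_pass[m][far])
  expect_true(is.finite(fl$report$containment_max_dist[m][far]))
})

test_that("containment discards poses outside the pocket sphere", {
  p <- loaded$poses[[1]]
  ctr <- as.numeric(get_atom(ps$receptor, atom_address("A", 145, "NE1"))[
    1, c("x", "y", "z")])
  # plant one carbon 12.5 A from the center (radius 10 + margin 2)
  p$atoms[2, c("x", "y", "z")] <- as.list(ctr + c(12.5, 0, 0))
  fl <- apply_filters(list(p), ps$receptor, filter_config())
  expect_false(fl$report$containment_pass[1])
  expect_false(fl$report$kept[1])
})

test_that("hydrogen bonds match planted geometry and the brute-force scan", {
  cfg <- filter_config()
  fl <- apply_filters(loaded$poses, ps$receptor, cfg)
  m <- match(ps$truth$id, fl$report$ligand)
  got_hb <- vapply(fl$hbonds[m], nrow, integer(1)) > 0
  expect_equal(got_hb, ps$truth$expect_hbond)
  # named-target flag on the planted donor
  hb_rows <- which(ps$truth$expect_hbond)
  for (i in hb_rows) {
    hb <- fl$hbonds[[m[i]]]
    expect_true("W145_backbone_O" %in% hb$target)
    expect_true(all(hb$distance <= cfg$hbond_max_da + 1e-9))
    expect_true(all(hb$angle >= cfg$hbond_min_angle - 1e-9))
  }
  # all-pairs brute-force agreement on every pose
  for (i in seq_along(loaded$poses)) {
    expect_equal(nrow(fl$hbonds[[i]]),
                 brute_hbond_scan(loaded$poses[[i]], ps$receptor),
                 label = loaded$poses[[i]]$id)
  }
  # far-apart donor/acceptor yields nothing
  p <- loaded$poses[[1]]
  p$atoms$x <- p$atoms$x + 50
  expect_equal(nrow(detect_hbonds(p, ps$receptor, cfg)), 0)
})

test_that("kept set equals the conjunction of the individual filters", {
  fl <- apply_filters(loaded$poses, ps$receptor, filter_config())
  with(fl$report, expect_equal(kept, capi_pass & containment_pass &
                                 n_clashes == 0))
})

test_that("relaxing cutoffs never shrinks the kept set", {
  base <- apply_filters(loaded$poses, ps$receptor, filter_config())
  relax <- list(
    filter_config(capi_max = 6.5),
    filter_config(containment_margin = 5),
    filter_config(clash_scale = 0.5))
  for (cfg in relax) {
    r <- apply_filters(loaded$poses, ps$receptor, cfg)
    expect_true(all(base$report$kept <= r$report$kept))
  }
})

test_that("shortlisting ranks, caps per ligand and breaks ties stably", {
  fl <- apply_filters(loaded$poses, ps$receptor, filter_config())
  top3 <- rank_and_shortlist(fl$kept, fl$report, top_n = 3)
  expect_equal(nrow(top3), 3)
  expect_true(all(diff(top3$score) <= 0))
  expect_error(rank_and_shortlist(fl$kept, fl$report, top_n = 0),
               "positive")

  # 5 ligands x 4 poses, cap 3: 15 rows even with a huge top_n
  rep4 <- do.call(rbind, lapply(1:5, function(li)
    data.frame(pose = paste0("L", li, "/", 1:4), ligand = paste0("L", li),
               tag = "", rank = 1:4, score = 50 - li - (1:4) / 10,
               kept = TRUE)))
  out <- rank_and_shortlist(list(), rep4, top_n = 400, per_ligand_cap = 3)
  expect_equal(nrow(out), 15)

  # equal scores: deterministic order by (ligand, rank)
  rep_tie <- data.frame(pose = c("b/1", "a/1"), ligand = c("b", "a"),
                        tag = "", rank = c(1, 1), score = c(7, 7),
                        kept = TRUE)
  o1 <- rank_and_shortlist(list(), rep_tie, top_n = 2)
  o2 <- rank_and_shortlist(list(), rep_tie[2:1, ], top_n = 2)
  expect_equal(o1$ligand, c("a", "b"))
  expect_equal(o1$ligand, o2$ligand)
})
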