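toy_receptor <- function(res_positions) {
  # one single-atom pseudo-residue per row
  rows <- do.call(rbind, lapply(seq_len(nrow(res_positions)), function(i)
    data.frame(chain = "S", resno = i, insert = "", resid = "EXV",
               elety = "C", element = "C", x = res_positions[i, 1],
               y = res_positions[i, 2], z = res_positions[i, 3],
               het = FALSE, stringsAsFactors = FALSE)))
  pocketfunnel:::new_structure_model(rows, "toy")
}

test_that("query construction selects residues by the shell cutoff", {
  rec <- toy_receptor(rbind(c(6.9, 0, 0), c(7.1, 0, 0)))
  lig <- data.frame(element = "N", x = 0, y = 0, z = 0)
  q <- build_query(rec, lig, cationic_atom = 1, shell_cutoff = 7.0)
  expect_equal(nrow(q$volumes), 1)        # 6.9 in, 7.1 out
  # boundary: exactly at the cutoff counts as inside
  recb <- toy_receptor(rbind(c(7.0, 0, 0)))
  qb <- build_query(recb, lig, cationic_atom = 1, shell_cutoff = 7.0)
  expect_equal(nrow(qb$volumes), 1)
  expect_error(build_query(rec, lig, cationic_atom = 1, shell_cutoff = 0),
               "no residue")
})

test_that("a single-atom cationic ligand matches any open query", {
  fx <- make_match_fixture(42, "pass")
  mr <- match_conformer(matrix(c(0, 0, 0), 1, 3), 1L, fx$query)
  expect_true(mr$matched)
  expect_true(verify_placement(matrix(c(0, 0, 0), 1, 3), 1, fx$query,
                               mr$placement))
})

test_that("matcher agrees with the brute-force oracle on planted fixtures", {
  kinds <- c("pass", "fail_sealed", "pass", "fail_plug", "pass",
             "fail_sealed")
  for (i in seq_along(kinds)) {
    fx <- make_match_fixture(300 + i, kinds[i])
    mr <- match_conformer(fx$coords, fx$cationic_row, fx$query)
    orc <- match_linear_oracle(fx$coords, fx$query)
    expect_equal(mr$matched, fx$expected, label = paste("matcher", i))
    expect_equal(orc, fx$expected, label = paste("oracle", i))
    if (mr$matched)
      expect_true(verify_placement(fx$coords, fx$cationic_row, fx$query,
                                   mr$placement))
  }
})

test_that("verdicts are stable when the search resolution is doubled", {
  for (i in 1:4) {
    kind <- if (i %% 2) "pass" else "fail_sealed"
    fx <- make_match_fixture(400 + i, kind)
    coarse <- match_conformer(fx$coords, 1L, fx$query,
                              spacing = 0.5, rot_deg = 30)
    fine <- match_conformer(fx$coords, 1L, fx$query,
                            spacing = 0.25, rot_deg = 15)
    expect_equal(coarse$matched, fine$matched, label = paste(kind, i))
  }
})

test_that("relaxing the query never shrinks the pass set", {
  fx <- make_match_fixture(55, "pass")
  q <- fx$query
  # a small set of rigid ligands of growing size
  ligs <- lapply(c(1.5, 2.5, 3.5, 4.5, 5.5), function(L)
    rbind(c(0, 0, 0), c(L / 2, 0, 0), c(L, 0, 0)))
  verdict <- function(query) vapply(ligs, function(xyz)
    match_conformer(xyz, 1L, query)$matched, logical(1))
  base <- verdict(q)

  q_bigfeat <- q; q_bigfeat$feature$radius <- 3.5
  expect_true(all(base <= verdict(q_bigfeat)))

  q_smallev <- q; q_smallev$volumes$radius <- 0.4
  expect_true(all(base <= verdict(q_smallev)))

  q_fewer <- q; q_fewer$volumes <- q$volumes[seq_len(20), ]
  expect_true(all(base <= verdict(q_fewer)))
})

test_that("library screening passes a ligand when any conformer matches", {
  sc <- screen_library(list(), make_match_fixture(1, "pass")$query)
  expect_length(sc$passed, 0)

  fx <- make_match_fixture(77, "pass")
  rec <- standardize(mol_from_smiles("CN(C)C", "trimethylamine"))
  cs <- generate_conformers(rec, n_max = 2)
  big <- standardize(mol_from_smiles(
    "C[N+](C)(C)Cc1c2ccccc2cc2ccccc12", "anthratma"))
  # screen the small amine against the roomy cavity: passes
  out <- screen_library(list(cs), fx$query)
  expect_equal(out$passed, "trimethylamine")
  expect_true(any(out$results$matched))
})

test_that("queries survive a text serialization round trip", {
  fx <- make_match_fixture(9, "pass")
  path <- tempfile(fileext = ".txt")
  write_query(fx$query, path)
  q2 <- read_query(path)
  expect_equal(q2$feature$center, fx$query$feature$center)
  expect_equal(q2$feature$radius, fx$query$feature$radius)
  expect_equal(nrow(q2$volumes), nrow(fx$query$volumes))
  expect_equal(q2$volumes$x, fx$query$volumes$x)
  expect_equal(q2$shell_cutoff, fx$query$shell_cutoff)
})
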