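test_that("PDB parsing loads atoms, chains and preserves addressing", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0, element = "C"),
    pdb_line(3, "C", "GLY", "A", 1, 2.0, 1.42, 0)))
  m <- read_structure(path)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$chains, "A")

  expect_error(read_structure(tempfile()), "not found")
})

test_that("alternate locations resolve to highest occupancy, ties by letter", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, alt = "A", occ = 0.6,
             element = "C"),
    pdb_line(2, "CA", "ALA", "A", 1, 5, 0, 0, alt = "B", occ = 0.4,
             element = "C"),
    pdb_line(3, "CA", "ALA", "A", 2, 9, 0, 0, alt = "B", occ = 0.5,
             element = "C"),
    pdb_line(4, "CA", "ALA", "A", 2, 7, 0, 0, alt = "A", occ = 0.5,
             element = "C"),
    pdb_line(5, "CA", "ALA", "A", 3, 1, 0, 0, alt = "A", occ = 0.3,
             element = "C"),
    pdb_line(6, "CA", "ALA", "A", 3, 4, 0, 0, alt = "B", occ = 0.7,
             element = "C")))
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 0)   # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$resno == 2], 7)   # tie: altloc A wins
  expect_equal(m$atoms$x[m$atoms$resno == 3], 4)   # higher-occupancy B wins
})

test_that("two-chain fixture exposes all CA atoms in both chains", {
  lines <- character()
  s <- 0
  for (ch in c("A", "B")) for (r in 1:10) {
    s <- s + 1
    lines <- c(lines, pdb_line(s, "CA", "ALA", ch, r, r * 3, (ch == "B") * 8,
                               0, element = "C"))
  }
  m <- read_structure(write_pdb_fixture(lines))
  expect_setequal(m$chains, c("A", "B"))
  expect_equal(sum(m$atoms$elety == "CA"), 20)
})

test_that("mmCIF input parses through the same model", {
  cif <- c(
    "data_mini", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id",
                            "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 N N . GLY A 1 1 ? 0.0 0.0 0.0 1.00 0.00 ? 1 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 1.458 0.0 0.0 1.00 0.00 ? 1 GLY A CA 1",
    "ATOM 3 C C . GLY A 1 1 ? 2.009 1.42 0.0 1.00 0.00 ? 1 GLY A C 1")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 3)
  expect_true("CA" %in% m$atoms$elety)
})

test_that("receptor preparation strips hetero records and adds polar H", {
  # one TYR residue with a water and a hetero ligand
  lines <- c(
    pdb_line(1, "N", "TYR", "A", 1, 0.0, 0.0, 0.0),
    pdb_line(2, "CA", "TYR", "A", 1, 1.46, 0.0, 0.0, element = "C"),
    pdb_line(3, "C", "TYR", "A", 1, 2.0, 1.42, 0.0),
    pdb_line(4, "CB", "TYR", "A", 1, 2.0, -1.2, 0.6, element = "C"),
    pdb_line(5, "CZ", "TYR", "A", 1, 3.5, -2.9, 1.4, element = "C"),
    pdb_line(6, "OH", "TYR", "A", 1, 4.4, -3.8, 1.9),
    pdb_line(7, "O", "HOH", "W", 101, 9, 9, 9, het = TRUE),
    pdb_line(8, "C1", "LIG", "L", 201, -8, 0, 3, het = TRUE))
  m <- read_structure(write_pdb_fixture(lines))
  prep <- prepare_receptor(m, keep_chains = "A")
  expect_false(any(prep$atoms$het))
  expect_false(any(prep$atoms$resid %in% c("HOH", "LIG")))
  # exactly one hydroxyl hydrogen at the ideal O-H length
  h <- prep$atoms[prep$atoms$element == "H" & prep$atoms$elety == "HOH", ]
  expect_equal(nrow(h), 1)
  oh <- prep$atoms[prep$atoms$elety == "OH", ]
  dOH <- sqrt(sum((as.numeric(h[1, c("x", "y", "z")]) -
                     as.numeric(oh[1, c("x", "y", "z")]))^2))
  expect_equal(dOH, 0.96, tolerance = 1e-6)
  expect_error(prepare_receptor(m, keep_chains = character()), "empty")
})

test_that("pocket extraction agrees with a brute-force distance scan", {
  pocket <- make_toy_pocket(fixture_spec(seed = 3, cavity_radius = 5,
                                         n_shell = 40))
  m <- pocket$model
  ctr <- atom_address("A", 145, "NE1")
  for (radius in c(0, 3, 6, 50)) {
    pk <- extract_pocket(m, ctr, radius)
    # brute force: all residues with >= 1 heavy atom within radius
    cpos <- as.numeric(get_atom(m, ctr)[1, c("x", "y", "z")])
    a <- m$atoms[m$atoms$element != "H", ]
    d <- sqrt((a$x - cpos[1])^2 + (a$y - cpos[2])^2 + (a$z - cpos[3])^2)
    expect_setequal(
      paste(pk$member_residues$chain, pk$member_residues$resno),
      unique(paste(a$chain, a$resno)[d <= radius]))
  }
  # degenerate radius keeps only the owning residue
  pk0 <- extract_pocket(m, ctr, 0)
  expect_equal(nrow(pk0$member_residues), 1)
  expect_equal(pk0$member_residues$resno, 145)
  # radius covering everything keeps every residue
  pk_all <- extract_pocket(m, ctr, 1e3)
  expect_equal(nrow(pk_all$member_residues),
               length(unique(paste(m$atoms$chain, m$atoms$resno))))
  expect_error(extract_pocket(m, atom_address("Z", 1, "XX")), "not found")
})
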