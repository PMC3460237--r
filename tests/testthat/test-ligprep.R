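test_that("standardization applies the acid/base rules", {
  # counter-ion removal + carboxylate
  ac <- standardize(mol_from_smiles("CC(=O)[O-].[Na+]", "acetate"))
  expect_equal(nrow(ac$atoms), 4)
  expect_equal(sum(ac$atoms$charge), -1)
  expect_length(ac$cationic, 0)

  # neutral acid gets deprotonated
  ha <- standardize(mol_from_smiles("CC(=O)O", "aceticacid"))
  expect_equal(sum(ha$atoms$charge), -1)

  # secondary aliphatic amine protonated
  pip <- standardize(mol_from_smiles("C1CCNCC1", "piperidine"))
  expect_equal(sum(pip$atoms$charge), 1)
  expect_length(pip$cationic, 1)

  # bridged amine protonated, pyridine-type aromatic N untouched
  epi <- standardize(mol_from_smiles("C1CC2CCC1NC2c1ccc(Cl)nc1",
                                     "epibatidine"))
  expect_length(epi$cationic, 1)
  n_idx <- which(epi$atoms$element == "N")
  arom_n <- n_idx[epi$atoms$arom[n_idx]]
  expect_equal(epi$atoms$charge[arom_n], 0)

  # amide and aniline nitrogens are not strong bases
  bza <- standardize(mol_from_smiles("NC(=O)c1ccccc1", "benzamide"))
  expect_length(bza$cationic, 0)
  ani <- standardize(mol_from_smiles("Nc1ccccc1", "aniline"))
  expect_length(ani$cationic, 0)
})

test_that("cationic-center detection covers quaternary and excludes nitro", {
  tma <- standardize(mol_from_smiles("C[N+](C)(C)C", "tma"))
  expect_length(tma$cationic, 1)
  bz <- standardize(mol_from_smiles("c1ccccc1", "benzene"))
  expect_length(bz$cationic, 0)
  dia <- standardize(mol_from_smiles("NCCCCN", "putrescine"))
  expect_length(dia$cationic, 2)
  nitro <- standardize(mol_from_smiles("O=[N+]([O-])c1ccccc1",
                                       "nitrobenzene"))
  expect_length(nitro$cationic, 0)
})

test_that("standardization is idempotent over a molecule pool", {
  for (s in smiles_pool) {
    r1 <- standardize(mol_from_smiles(s, "m"))
    r2 <- standardize(r1)
    expect_identical(r1$atoms, r2$atoms, label = s)
    expect_identical(r1$cationic, r2$cationic, label = s)
  }
})

test_that("stereocenter enumeration is combinatorial with all centers assigned", {
  # no unassigned centers: the molecule itself
  one <- enumerate_stereoisomers(standardize(mol_from_smiles("CCO", "eth")))
  expect_length(one, 1)

  # two centers -> four isomers
  two <- standardize(mol_from_smiles("CC(O)C(N)CC", "diol"))
  expect_length(find_stereocenters(two), 2)
  iso <- enumerate_stereoisomers(two)
  expect_length(iso, 4)
  for (x in iso) {
    expect_true(all(x$stereo$assigned))
    expect_true(grepl("#", x$id))
  }

  # enumeration count never exceeds 2^k and honors the cap
  big <- standardize(mol_from_smiles("CC(O)C(N)C(C)C(O)CC", "poly"))
  k <- length(find_stereocenters(big))
  expect_gte(k, 3)
  expect_warning(capped <- enumerate_stereoisomers(big, max_centers = 2),
                 "enumerating")
  expect_length(capped, 4)
  full <- enumerate_stereoisomers(big, max_centers = 6)
  expect_lte(length(full), 2^k)
})

test_that("conformer generation finds rotamers and respects limits", {
  but <- standardize(mol_from_smiles("CCCC", "butane"))
  cs <- generate_conformers(but, dedup_rmsd = 0.5)
  expect_gte(length(cs$conformers), 2)       # anti + gauche
  expect_true(all(conformers_valid(cs)))

  one <- generate_conformers(but, n_max = 1)
  expect_length(one$conformers, 1)

  ada <- standardize(mol_from_smiles("C1C2CC3CC1CC(C2)C3", "adamantane"))
  rigid <- generate_conformers(ada)
  expect_length(rigid$conformers, 1)

  # deterministic under a fixed seed
  cs2 <- generate_conformers(but, dedup_rmsd = 0.5)
  expect_identical(cs$conformers, cs2$conformers)
})

test_that("every conformer preserves bonded connectivity bounds", {
  for (s in c("CCCCO", "CC(C)CC", "c1ccccc1CC", "C1CCNCC1")) {
    cs <- generate_conformers(standardize(mol_from_smiles(s, "m")),
                              n_max = 10)
    expect_true(all(conformers_valid(cs)), label = s)
  }
})

test_that("ligand reading logs rejects instead of failing the library", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO good1", "not_a_smiles((( bad1", "CCN good2"), path)
  lib <- read_ligands(path)
  expect_length(lib$records, 2)
  expect_equal(nrow(lib$rejected), 1)
  expect_equal(lib$rejected$id, "bad1")
})
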