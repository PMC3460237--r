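toy_fp <- function(bits, id = "toy", nbits = 8) {
  structure(list(id = id, bits = as.integer(bits), nbits = nbits,
                 radius = 2, n_features = length(bits)),
            class = "Fingerprint")
}

test_that("fingerprints are invariant to atom ordering", {
  pairs <- list(c("OCC", "CCO"), c("Cc1ccccc1", "c1ccccc1C"),
                c("N(C)C", "CNC"), c("C(C)(C)O", "CC(C)O"))
  for (p in pairs) {
    f1 <- fingerprint(standardize(mol_from_smiles(p[1], "a")))
    f2 <- fingerprint(standardize(mol_from_smiles(p[2], "b")))
    expect_identical(f1$bits, f2$bits, label = paste(p, collapse = " vs "))
  }
})

test_that("different molecules give different fingerprints", {
  eth <- fingerprint(mol_from_smiles("CC", "ethane"))
  etoh <- fingerprint(mol_from_smiles("CCO", "ethanol"))
  expect_false(identical(eth$bits, etoh$bits))
  expect_gt(length(fingerprint(mol_from_smiles("C", "methane"))$bits), 0)
})

test_that("tanimoto satisfies its axioms across a random pool", {
  recs <- lapply(smiles_pool, function(s)
    standardize(mol_from_smiles(s, s)))
  fps <- lapply(recs, fingerprint)
  set.seed(123)
  for (k in 1:100) {
    i <- sample(length(fps), 1); j <- sample(length(fps), 1)
    t_ij <- tanimoto(fps[[i]], fps[[j]])
    expect_gte(t_ij, 0); expect_lte(t_ij, 1)
    expect_equal(t_ij, tanimoto(fps[[j]], fps[[i]]))
  }
  for (f in fps) expect_equal(tanimoto(f, f), 1.0)
})

test_that("tanimoto matches set arithmetic on hand-built bit sets", {
  expect_equal(tanimoto(toy_fp(c(1, 2, 3)), toy_fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(toy_fp(c(1, 2)), toy_fp(c(5, 6))), 0.0)
  expect_equal(tanimoto(toy_fp(integer()), toy_fp(integer())), 1.0)
  expect_error(tanimoto(toy_fp(1, nbits = 8), toy_fp(1, nbits = 16)),
               "mismatch")
})

test_that("novelty screening equals a brute-force pairwise scan", {
  cand <- lapply(smiles_pool[1:6], function(s)
    standardize(mol_from_smiles(s, paste0("c_", s))))
  refs <- lapply(smiles_pool[7:14], function(s)
    standardize(mol_from_smiles(s, paste0("r_", s))))
  hits <- novelty_screen(cand, refs, threshold = 0.40)
  fps_c <- lapply(cand, fingerprint)
  fps_r <- lapply(refs, fingerprint)
  for (i in seq_along(cand)) {
    sims <- vapply(fps_r, tanimoto, numeric(1), a = fps_c[[i]])
    expect_equal(hits$tanimoto[i], max(sims))
    expect_equal(hits$best_reference[i], refs[[which.max(sims)]]$id)
    expect_equal(hits$classified_known[i], max(sims) >= 0.40)
  }
  # identical candidate/reference molecule scores 1 and is "known"
  hits2 <- novelty_screen(cand[1], cand[1], threshold = 0.40)
  expect_equal(hits2$tanimoto, 1.0)
  expect_true(hits2$classified_known)
  expect_error(novelty_screen(cand, list()), "empty")
})

test_that("raising the threshold never increases the known count", {
  cand <- lapply(smiles_pool[1:8], function(s)
    standardize(mol_from_smiles(s, s)))
  refs <- lapply(smiles_pool[9:16], function(s)
    standardize(mol_from_smiles(s, s)))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    sum(novelty_screen(cand, refs, threshold = th)$classified_known),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold classification reproduces the reported hit split", {
  scores <- utils::read.delim(system.file("extdata",
                                          "hit_similarity_scores.tsv",
                                          package = "pocketfunnel"))
  known <- classify_known(scores$ecfp4_best_known, threshold = 0.40)
  expect_equal(sum(known), 1)
  expect_equal(as.character(scores$compound[known]), "29")
  expect_true(all(scores$ecfp4_best_known[!known] <= 0.33))
})

test_that("reference-set building applies the weight and affinity filters", {
  df <- data.frame(
    smiles = c("CCO", "CCN", "CCCC", "CC(C)N"),
    id = c("a", "b", "c", "d"),
    affinity_um = c(5, 50, 1, NA))
  refs <- build_reference_set(df, mw_max = 500, affinity_max = 10)
  expect_setequal(vapply(refs, `[[`, character(1), "id"), c("a", "c"))
})
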