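#' Circular-fingerprint similarity and novelty screening
#'
#' Hashed extended-connectivity (circular) fingerprints of radius 2
#' (ECFP-4-class), folded to a configurable bit length, with Tanimoto
#' similarity against a known-ligand reference set. Different
#' implementations of this fingerprint family are not bit-compatible, so
#' similarity values should be compared within one implementation; the
#' parameters are recorded in every output for auditability.
#'
#' @name similarity
NULL

#' Compute a hashed circular fingerprint
#'
#' Atom environments of radius 0..`radius` are identified by iterative
#' neighborhood hashing (initial invariants: atomic number, heavy degree,
#' hydrogen count, formal charge, ring and aromatic flags) and folded into
#' `nbits` bits. The bit set is independent of the input atom ordering.
#'
#' @param mol a `ligand_record`.
#' @param radius environment radius (default 2, i.e. diameter 4).
#' @param nbits folded length (default 2048).
#' @return a `Fingerprint`: list with `id`, `bits` (sorted 0-based bit
#'   indices), `nbits`, `radius`, `n_features`.
#' @export
fingerprint <- function(mol, radius = 2, nbits = 2048) {
  at <- mol$atoms
  heavy <- which(at$element != "H")
  if (!length(heavy)) stop("cannot fingerprint an empty molecule")
  nb <- neighbor_table(mol)
  inv <- vapply(seq_len(nrow(at)), function(i) hash_ints(c(
    atomic_number(at$element[i]), at$charge[i] + 10, at$nH[i],
    nrow(nb[[i]]), as.integer(at$ring[i]), as.integer(at$arom[i])
  )), numeric(1))
  ids <- inv[heavy]
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- cur
    for (i in heavy) {
      m <- nb[[i]]
      js <- m[at$element[m[, "j"]] != "H", , drop = FALSE]
      if (!nrow(js)) { nxt[i] <- hash_ints(c(r, cur[i])); next }
      pairs <- cbind(js[, "order"], cur[js[, "j"]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      nxt[i] <- hash_ints(c(r, cur[i], as.numeric(t(pairs))))
    }
    cur <- nxt
    ids <- c(ids, cur[heavy])
  }
  ids <- unique(ids)
  structure(list(id = mol$id, bits = sort(unique(as.integer(ids %% nbits))),
                 nbits = nbits, radius = radius, n_features = length(ids)),
            class = "Fingerprint")
}

#' @export
print.Fingerprint <- function(x, ...) {
  cat("Fingerprint <", x$id, ">: ", length(x$bits), " bits set of ",
      x$nbits, " (radius ", x$radius, ", ", x$n_features, " features)\n",
      sep = "")
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both bit sets are
#' empty. Errors when the fingerprints were computed with different
#' parameters.
#'
#' @param a,b `Fingerprint` objects.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (a$nbits != b$nbits || a$radius != b$radius)
    stop("fingerprint parameter mismatch (nbits/radius)")
  u <- length(union(a$bits, b$bits))
  if (u == 0) return(1.0)
  length(intersect(a$bits, b$bits)) / u
}

#' Classify candidates as known-like or novel against a reference set
#'
#' For each candidate, finds the maximum Tanimoto similarity over the
#' reference ligands; candidates at or above `threshold` are classified as
#' chemically known, the rest as novel.
#'
#' @param candidates list of `ligand_record`s.
#' @param references non-empty list of `ligand_record`s (known ligands).
#' @param threshold known/novel threshold (default 0.40).
#' @param radius,nbits fingerprint parameters.
#' @return data frame: `query`, `best_reference`, `tanimoto`,
#'   `classified_known`, plus fingerprint parameters as attributes.
#' @export
novelty_screen <- function(candidates, references, threshold = 0.40,
                           radius = 2, nbits = 2048) {
  if (!length(references)) stop("reference set must not be empty")
  fps_ref <- lapply(references, fingerprint, radius = radius, nbits = nbits)
  rows <- lapply(candidates, function(cand) {
    fp <- fingerprint(cand, radius = radius, nbits = nbits)
    sims <- vapply(fps_ref, tanimoto, numeric(1), a = fp)
    best <- which.max(sims)
    data.frame(query = cand$id,
               best_reference = references[[best]]$id,
               tanimoto = sims[best],
               classified_known = sims[best] >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fingerprint") <- paste0("circular r", radius, "/", nbits,
                                     " bits")
  attr(out, "threshold") <- threshold
  out
}

#' Classify precomputed similarity scores at a threshold
#'
#' Applies the known/novel classification to similarity values computed
#' elsewhere (e.g. reported best-reference scores).
#'
#' @param scores numeric vector of maximum-similarity values.
#' @param threshold classification threshold (default 0.40).
#' @return logical vector: TRUE = known-like.
#' @export
classify_known <- function(scores, threshold = 0.40) {
  scores >= threshold
}

#' Build a known-ligand reference set from annotated molecules
#'
#' Applies the standard inclusion filters for the novelty reference set:
#' molecular weight below `mw_max` and affinity (Ki or EC50) at or below
#' `affinity_max` (micromolar).
#'
#' @param df data frame with columns `smiles`, `id`, `affinity_um`
#'   (micromolar affinity; NA drops the row).
#' @param mw_max molecular-weight ceiling (default 500).
#' @param affinity_max affinity ceiling in micromolar (default 10).
#' @return list of standardized `ligand_record`s.
#' @export
build_reference_set <- function(df, mw_max = 500, affinity_max = 10) {
  stopifnot(all(c("smiles", "id", "affinity_um") %in% names(df)))
  keep <- !is.na(df$affinity_um) & df$affinity_um <= affinity_max
  df <- df[keep, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(standardize(mol_from_smiles(df$smiles[i], df$id[i])),
                    error = function(e) NULL)
    if (is.null(rec)) next
    mw <- sum(c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06,
                P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904,
                I = 126.90)[rec$atoms$element], na.rm = TRUE) +
      1.008 * sum(rec$atoms$nH)
    if (mw >= mw_max) next
    out[[length(out) + 1]] <- rec
  }
  out
}
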