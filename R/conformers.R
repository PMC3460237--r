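#' Conformer generation
#'
#' Conformers are generated by a pluggable backend. The default backend
#' embeds one 3D structure with a seeded distance-geometry method (RDKit
#' ETKDG through a bundled python helper; deterministic under the seed)
#' and then drives every rotatable bond systematically in 120-degree
#' steps, discarding self-clashing rotamers and de-duplicating by
#' superposed heavy-atom RMSD. This mirrors the systematic-search style
#' of library preparation tools while staying fully reproducible.
#'
#' @name conformers
NULL

.pf_cache <- new.env(parent = emptyenv())

rdkit_available <- function() {
  if (!is.null(.pf_cache$rdkit)) return(.pf_cache$rdkit)
  ok <- nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", shQuote("import rdkit")),
                             stdout = FALSE, stderr = FALSE)) == 0
  .pf_cache$rdkit <- ok
  ok
}

embed_script <- function() {
  p <- system.file("python", "embed3d.py", package = "pocketfunnel")
  if (!nzchar(p)) stop("embed3d.py helper not found")
  p
}

#' Embed a single 3D structure for a ligand
#'
#' Uses a seeded distance-geometry embedding (RDKit ETKDG through the
#' bundled python helper) so that repeated runs are byte-identical; falls
#' back to OpenBabel's structure generator (not seedable, hence not
#' byte-reproducible) when no python/RDKit is available.
#'
#' @param rec a `ligand_record`.
#' @param seed integer random seed for the embedding.
#' @return heavy-atom coordinate matrix (n x 3) in the record's atom order.
#' @export
embed_mol3d <- function(rec, seed = 1L) {
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(format_sdf_record(rec), tmp_in)
  if (rdkit_available()) {
    status <- suppressWarnings(system2(
      "python", c(embed_script(), tmp_in, tmp_out, as.integer(seed)),
      stdout = FALSE, stderr = FALSE))
  } else if (obabel_available()) {
    status <- suppressWarnings(system2(
      "obabel", c(tmp_in, "-osdf", "--gen3d", "-d", "-O", tmp_out),
      stdout = FALSE, stderr = FALSE))
  } else {
    stop("no 3D embedding backend available (need python+rdkit or obabel)")
  }
  if (status != 0 || !file.exists(tmp_out) || !file.size(tmp_out))
    stop("3D embedding failed for ", rec$id)
  parsed <- ChemmineR::read.SDFset(tmp_out)
  if (!length(parsed)) stop("3D embedding produced no molecule for ", rec$id)
  ab <- ChemmineR::atomblock(parsed[[1]])
  xyz <- unname(ab[, 1:3, drop = FALSE])
  n_heavy <- sum(rec$atoms$element != "H")
  if (nrow(xyz) != n_heavy)
    stop("embedding atom-count mismatch for ", rec$id,
         " (", nrow(xyz), " vs ", n_heavy, " heavy atoms)")
  xyz
}

# bonds whose rotation changes the conformation: single, acyclic,
# both ends with >= 2 heavy neighbors
rotatable_bonds <- function(rec) {
  b <- rec$bonds
  if (!nrow(b)) return(b[0, ])
  g <- mol_graph(rec)
  hdeg <- heavy_degree(rec)
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    if (b$order[i] != 1) next
    a1 <- b$a1[i]; a2 <- b$a2[i]
    if (rec$atoms$element[a1] == "H" || rec$atoms$element[a2] == "H") next
    if (hdeg[a1] < 2 || hdeg[a2] < 2) next
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a1, a2)))
    comp <- igraph::components(g2)$membership
    names(comp) <- igraph::V(g2)$name
    if (comp[as.character(a1)] == comp[as.character(a2)]) next  # in a ring
    keep[i] <- TRUE
  }
  b[keep, , drop = FALSE]
}

# atoms on the a2 side of bond a1-a2
bond_side <- function(rec, a1, a2) {
  g <- mol_graph(rec)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a1, a2)))
  comp <- igraph::components(g2)$membership
  names(comp) <- igraph::V(g2)$name
  as.integer(names(comp)[comp == comp[as.character(a2)]])
}

rotate_about_bond <- function(xyz, p1, p2, side, angle) {
  R <- rotation_about_axis(p2 - p1, angle)
  xyz[side, ] <- sweep(tcrossprod(sweep(xyz[side, , drop = FALSE], 2, p1),
                                  R), 2, p1, "+")
  xyz
}

# self-clash: heavy-atom pairs >= 4 bonds apart closer than
# 0.6 * (vdw_i + vdw_j)
self_clashes <- function(rec_heavy_elements, xyz, graph_dist) {
  n <- nrow(xyz)
  if (n < 5) return(FALSE)
  r <- vdw_radius(rec_heavy_elements)
  d2 <- cross_dist2(xyz, xyz)
  lim <- 0.6 * outer(r, r, "+")
  bad <- d2 < lim^2 & graph_dist >= 4
  any(bad[upper.tri(bad)])
}

#' Generate a conformer set for a ligand
#'
#' @param mol a `ligand_record` (heavy-atom connectivity; implicit H).
#' @param n_max maximum number of conformers kept (default 30).
#' @param dedup_rmsd minimum pairwise superposed heavy-atom RMSD between
#'   retained conformers, Angstrom (default 0.5).
#' @param backend `"torsion"` (systematic torsion driving, default) or
#'   `"embed"` (single embedded conformer).
#' @param max_rotors at most this many rotatable bonds are driven
#'   (3^max_rotors rotamer cap; default 6).
#' @param seed integer seed for the base embedding.
#' @return a `ConformerSet`: list with `ligand`, `conformers` (list of
#'   heavy-atom coordinate matrices) and `generator_tag`.
#' @export
generate_conformers <- function(mol, n_max = 30, dedup_rmsd = 0.5,
                                backend = c("torsion", "embed"),
                                max_rotors = 6, seed = 1L) {
  backend <- match.arg(backend)
  if (n_max < 1) stop("n_max must be >= 1")
  base <- embed_mol3d(mol, seed = seed)
  hidx <- heavy_idx(mol)
  helem <- mol$atoms$element[hidx]
  confs <- list(base)
  if (backend == "torsion") {
    rb <- rotatable_bonds(mol)
    if (nrow(rb) > max_rotors) rb <- rb[seq_len(max_rotors), , drop = FALSE]
    if (nrow(rb)) {
      # map full-molecule atom indices to heavy-atom rows
      hmap <- match(seq_len(nrow(mol$atoms)), hidx)
      gd <- bond_distances(mol)[hidx, hidx, drop = FALSE]
      sides <- lapply(seq_len(nrow(rb)), function(i)
        stats::na.omit(hmap[setdiff(bond_side(mol, rb$a1[i], rb$a2[i]),
                                    c(rb$a1[i], rb$a2[i]))]))
      angles <- c(0, 2 * pi / 3, 4 * pi / 3)
      grid <- as.matrix(expand.grid(rep(list(seq_along(angles)),
                                        nrow(rb))))
      cand <- list()
      for (r in seq_len(nrow(grid))) {
        xyz <- base
        for (bnd in seq_len(nrow(rb))) {
          ang <- angles[grid[r, bnd]]
          if (ang == 0) next
          p1 <- xyz[hmap[rb$a1[bnd]], ]
          p2 <- xyz[hmap[rb$a2[bnd]], ]
          xyz <- rotate_about_bond(xyz, p1, p2, sides[[bnd]], ang)
        }
        if (!self_clashes(helem, xyz, gd)) cand[[length(cand) + 1]] <- xyz
      }
      confs <- cand
      if (!length(confs)) confs <- list(base)
    }
  }
  # de-duplicate by superposed heavy-atom RMSD, deterministic greedy order
  kept <- list()
  for (xyz in confs) {
    dup <- FALSE
    for (k in kept) {
      r <- if (nrow(xyz) >= 3) kabsch(xyz, k)$rmsd else
        sqrt(mean(rowSums((xyz - k)^2)))
      if (r < dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- xyz
    if (length(kept) >= n_max) break
  }
  structure(list(ligand = mol, conformers = kept,
                 generator_tag = paste0(
                   backend, "/",
                   if (rdkit_available()) paste0("etkdg-seed", seed)
                   else "obabel-gen3d")),
            class = "ConformerSet")
}

#' @export
print.ConformerSet <- function(x, ...) {
  cat("ConformerSet <", x$ligand$id, ">: ", length(x$conformers),
      " conformer(s), backend ", x$generator_tag, "\n", sep = "")
  invisible(x)
}

#' Check conformer connectivity plausibility
#'
#' Every bonded heavy-atom pair must lie within chemically plausible bounds
#' (0.7 to 2.0 Angstrom).
#'
#' @param cs a `ConformerSet`.
#' @return logical vector, one per conformer.
#' @export
conformers_valid <- function(cs) {
  rec <- cs$ligand
  hidx <- heavy_idx(rec)
  hmap <- match(seq_len(nrow(rec$atoms)), hidx)
  b <- rec$bonds
  hb <- b[rec$atoms$element[b$a1] != "H" & rec$atoms$element[b$a2] != "H", ,
          drop = FALSE]
  vapply(cs$conformers, function(xyz) {
    if (!nrow(hb)) return(TRUE)
    d <- sqrt(rowSums((xyz[hmap[hb$a1], , drop = FALSE] -
                         xyz[hmap[hb$a2], , drop = FALSE])^2))
    all(d >= 0.7 & d <= 2.0)
  }, logical(1))
}
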