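#' Ligand standardization and screening-library triage
#'
#' Implements the library preparation stage of the funnel: removal of
#' counter-ions and solvent fragments, deterministic protonation-state
#' standardization (strong acids deprotonated, strong bases protonated),
#' detection of cationic centers (quaternary or protonated nitrogens) and
#' combinatorial enumeration of unassigned stereocenters.
#'
#' The acid/base definitions are a fixed, auditable rule list over the
#' molecular graph (not pKa prediction); users can extend or replace the
#' list via the `rules` argument of [standardize()].
#'
#' @name ligprep
NULL

neighbor_table <- function(rec) {
  n <- nrow(rec$atoms)
  nb <- vector("list", n)
  b <- rec$bonds
  for (i in seq_len(nrow(b))) {
    nb[[b$a1[i]]] <- rbind(nb[[b$a1[i]]], c(b$a2[i], b$order[i]))
    nb[[b$a2[i]]] <- rbind(nb[[b$a2[i]]], c(b$a1[i], b$order[i]))
  }
  lapply(nb, function(m) if (is.null(m))
    matrix(integer(), 0, 2, dimnames = list(NULL, c("j", "order")))
    else matrix(m, ncol = 2, dimnames = list(NULL, c("j", "order"))))
}

heavy_degree <- function(rec, nb = neighbor_table(rec)) {
  vapply(seq_len(nrow(rec$atoms)), function(i) {
    js <- nb[[i]][, "j"]
    sum(rec$atoms$element[js] != "H")
  }, numeric(1))
}

# atoms double-bonded to i with element in `to`
double_bonded_to <- function(rec, i, to, nb) {
  m <- nb[[i]]
  js <- m[m[, "order"] == 2, "j"]
  js[rec$atoms$element[js] %in% to]
}

#' Default protonation-state rule list
#'
#' Strong acids (carboxylic, sulfonic, sulfinic, phosphonic; acidic
#' tetrazole N-H) are deprotonated; strong bases (non-amide, non-anilinic
#' aliphatic amines including quaternary ammonium; amidines; guanidines)
#' are protonated. Each rule maps a `ligand_record` to the atom indices it
#' modifies; rules only fire on atoms with formal charge 0, which makes the
#' standardizer idempotent.
#'
#' @return a named list of rules (`action` = "deprotonate"/"protonate",
#'   `find` = function(record) -> atom indices).
#' @export
default_charge_rules <- function() {
  list(
    oxyacid = list(
      action = "deprotonate",
      find = function(rec) {
        nb <- neighbor_table(rec)
        out <- integer()
        for (i in seq_len(nrow(rec$atoms))) {
          if (!rec$atoms$element[i] %in% c("C", "S", "P")) next
          if (rec$atoms$arom[i]) next
          if (!length(double_bonded_to(rec, i, "O", nb))) next
          m <- nb[[i]]
          js <- m[m[, "order"] == 1, "j"]
          oh <- js[rec$atoms$element[js] == "O" & rec$atoms$charge[js] == 0 &
                     rec$atoms$nH[js] >= 1]
          if (length(oh)) out <- c(out, min(oh))  # first acidic proton only
        }
        unique(out)
      }),
    tetrazole = list(
      action = "deprotonate",
      find = function(rec) {
        out <- integer()
        for (ring in rec$rings) {
          if (length(ring) != 5) next
          if (sum(rec$atoms$element[ring] == "N") != 4) next
          nh <- ring[rec$atoms$element[ring] == "N" &
                       rec$atoms$nH[ring] >= 1 &
                       rec$atoms$charge[ring] == 0]
          if (length(nh)) out <- c(out, min(nh))
        }
        unique(out)
      }),
    aliphatic_amine = list(
      action = "protonate",
      find = function(rec) {
        nb <- neighbor_table(rec)
        at <- rec$atoms
        out <- integer()
        for (i in seq_len(nrow(at))) {
          if (at$element[i] != "N" || at$charge[i] != 0 || at$arom[i]) next
          m <- nb[[i]]
          if (nrow(m) && any(m[, "order"] > 1)) next       # imine/nitrile/nitro
          js <- m[, "j"]
          js <- js[at$element[js] != "H"]
          if (length(js) > 4) next
          bad <- FALSE
          for (j in js) {
            if (at$arom[j]) { bad <- TRUE; break }          # aniline-type
            if (at$element[j] %in% c("N", "O", "S", "P")) { bad <- TRUE; break }
            if (at$element[j] == "C" &&
                length(double_bonded_to(rec, j, c("O", "S", "N"), nb))) {
              bad <- TRUE; break                            # amide / amidine C
            }
          }
          if (!bad) out <- c(out, i)
        }
        out
      }),
    amidine_guanidine = list(
      action = "protonate",
      find = function(rec) {
        nb <- neighbor_table(rec)
        at <- rec$atoms
        out <- integer()
        for (i in seq_len(nrow(at))) {
          if (at$element[i] != "N" || at$charge[i] != 0 || at$arom[i]) next
          m <- nb[[i]]
          cs <- m[m[, "order"] == 2, "j"]
          cs <- cs[at$element[cs] == "C" & !at$arom[cs]]
          for (cc in cs) {
            mcc <- nb[[cc]]
            other_n <- mcc[mcc[, "order"] == 1, "j"]
            other_n <- other_n[at$element[other_n] == "N"]
            if (length(double_bonded_to(rec, cc, c("O", "S"), nb))) next
            if (length(other_n)) { out <- c(out, i); break }
          }
        }
        out
      })
  )
}

largest_organic_fragment <- function(rec) {
  g <- mol_graph(rec)
  comp <- igraph::components(g)
  member <- comp$membership[order(as.integer(igraph::V(g)$name))]
  if (comp$no <= 1) return(list(rec = rec, removed = 0L))
  sizes <- tabulate(member, comp$no)
  has_c <- vapply(seq_len(comp$no), function(k)
    any(rec$atoms$element[member == k] == "C"), logical(1))
  cand <- if (any(has_c)) which(has_c) else seq_len(comp$no)
  # largest, ties -> fragment appearing first in the atom order
  first_at <- vapply(cand, function(k) min(which(member == k)), numeric(1))
  best <- cand[order(-sizes[cand], first_at)][1]
  keep <- which(member == best)
  subset_record(rec, keep)
}

subset_record <- function(rec, keep) {
  map <- match(seq_len(nrow(rec$atoms)), keep)
  atoms <- rec$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- rec$bonds
  kb <- !is.na(map[b$a1]) & !is.na(map[b$a2])
  bonds <- data.frame(a1 = map[b$a1[kb]], a2 = map[b$a2[kb]],
                      order = b$order[kb])
  rings <- Filter(Negate(is.null), lapply(rec$rings, function(r) {
    r2 <- map[r]
    if (anyNA(r2)) NULL else r2
  }))
  out <- new_ligand_record(atoms, bonds, id = rec$id, smiles = rec$smiles,
                           source = rec$source,
                           coords = if (!is.null(rec$coords))
                             rec$coords[keep, , drop = FALSE] else NULL,
                           rings = rings)
  list(rec = out, removed = nrow(rec$atoms) - length(keep))
}

#' Standardize a molecule for the screening funnel
#'
#' Keeps the largest organic fragment (dropping counter-ions and solvent),
#' deprotonates strong acids, protonates strong bases, marks quaternary
#' nitrogens as +1 and recomputes formal charges, implicit hydrogen counts
#' and cationic centers. Idempotent: re-standardizing a standardized record
#' is a no-op.
#'
#' @param mol a `ligand_record` (from [mol_from_smiles()] /
#'   [read_ligands()]).
#' @param rules protonation rule list, see [default_charge_rules()].
#' @return the standardized `ligand_record`; `$cationic` holds the indices
#'   of nitrogen atoms with formal charge +1.
#' @export
standardize <- function(mol, rules = default_charge_rules()) {
  fr <- largest_organic_fragment(mol)
  rec <- fr$rec
  for (rule in rules) {
    idx <- rule$find(rec)
    if (!length(idx)) next
    delta <- if (rule$action == "deprotonate") -1L else 1L
    rec$atoms$charge[idx] <- rec$atoms$charge[idx] + delta
    rec$atoms$nH <- compute_implicit_h(rec$atoms, rec$bonds)
  }
  # quaternary nitrogens: four single bonds to heavy atoms
  nb <- neighbor_table(rec)
  hdeg <- heavy_degree(rec, nb)
  for (i in seq_len(nrow(rec$atoms))) {
    if (rec$atoms$element[i] == "N" && rec$atoms$charge[i] == 0 &&
        hdeg[i] == 4 && all(nb[[i]][, "order"] == 1)) {
      rec$atoms$charge[i] <- 1L
    }
  }
  rec$atoms$nH <- compute_implicit_h(rec$atoms, rec$bonds)
  rec$standardized <- TRUE
  rec$fragments_removed <- fr$removed
  rec$cationic <- detect_cationic_centers(rec)
  rec
}

#' Detect cationic centers
#'
#' Returns the indices of nitrogen atoms carrying formal charge +1
#' (quaternary or protonated). An empty result means the ligand is dropped
#' at the cationic-preselection stage of the funnel. Zwitterions count as
#' cationic as long as at least one N+ is present.
#'
#' Nitrogens that are merely formally positive inside a neutral group
#' (nitro, N-oxide, azide) are excluded: a +1 nitrogen bonded to a
#' negatively charged atom is not a basic/quaternary center.
#'
#' @param mol a standardized `ligand_record`.
#' @return integer vector of atom indices (possibly empty).
#' @export
detect_cationic_centers <- function(mol) {
  cand <- which(mol$atoms$element == "N" & mol$atoms$charge == 1)
  if (!length(cand)) return(integer())
  nb <- neighbor_table(mol)
  keep <- vapply(cand, function(i) {
    js <- nb[[i]][, "j"]
    !any(mol$atoms$charge[js] < 0)
  }, logical(1))
  cand[keep]
}

# --- canonical ranks and stereocenters -------------------------------------

hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

#' Canonical atom ranks by iterative neighborhood refinement
#'
#' Morgan-style extended-connectivity ranks: equal rank means the atoms are
#' indistinguishable by element, charge, hydrogen count, aromaticity and
#' iterated neighborhood structure.
#'
#' @param rec a `ligand_record`.
#' @return integer rank per atom.
#' @export
canonical_ranks <- function(rec) {
  at <- rec$atoms
  nb <- neighbor_table(rec)
  inv <- vapply(seq_len(nrow(at)), function(i) hash_ints(c(
    atomic_number(at$element[i]), at$charge[i] + 10, at$nH[i],
    nrow(nb[[i]]), as.integer(at$arom[i]), as.integer(at$ring[i])
  )), numeric(1))
  n_distinct <- length(unique(inv))
  for (iter in seq_len(nrow(at))) {
    inv2 <- vapply(seq_len(nrow(at)), function(i) {
      m <- nb[[i]]
      if (!nrow(m)) return(hash_ints(c(inv[i])))
      pairs <- cbind(m[, "order"], inv[m[, "j"]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_ints(c(inv[i], as.numeric(t(pairs))))
    }, numeric(1))
    nd <- length(unique(inv2))
    inv <- inv2
    if (nd == n_distinct && iter > 2) break
    n_distinct <- nd
  }
  match(inv, sort(unique(inv)))
}

# branch signature of neighbor `start` with the center atom removed
branch_signature <- function(rec, center, start, nb) {
  n <- nrow(rec$atoms)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in nb[[i]][, "j"]) {
      if (j == center || !is.na(dist[j])) next
      dist[j] <- dist[i] + 1L
      queue <- c(queue, j)
    }
  }
  reach <- which(!is.na(dist))
  at <- rec$atoms
  key <- cbind(dist[reach], atomic_number(at$element[reach]),
               at$charge[reach] + 10, at$nH[reach])
  key <- key[do.call(order, as.data.frame(key)), , drop = FALSE]
  hash_ints(as.numeric(t(key)))
}

#' Find candidate tetrahedral stereocenters
#'
#' A carbon with four distinct substituents (implicit hydrogen counting as
#' one) is a candidate stereocenter; distinctness is decided by hashed
#' branch signatures with the center removed. CIP priorities are not
#' computed, so rare para-stereocenters that depend on remote
#' configurations are not detected.
#'
#' @param mol a `ligand_record`.
#' @return integer vector of atom indices.
#' @export
find_stereocenters <- function(mol) {
  at <- mol$atoms
  nb <- neighbor_table(mol)
  out <- integer()
  for (i in seq_len(nrow(at))) {
    if (at$element[i] != "C" || at$arom[i]) next
    m <- nb[[i]]
    if (nrow(m) == 0 || any(m[, "order"] > 1)) next
    js <- m[, "j"]
    n_sub <- length(js) + at$nH[i]
    if (n_sub != 4 || at$nH[i] > 1) next
    sigs <- vapply(js, function(j) branch_signature(mol, i, j, nb),
                   numeric(1))
    if (anyDuplicated(sigs)) next
    out <- c(out, i)
  }
  out
}

#' Enumerate stereoisomers of unassigned stereocenters
#'
#' Expands every unassigned stereocenter combinatorially (2^k parity
#' assignments); already-assigned centers are preserved. Molecules with
#' more than `max_centers` unassigned centers are truncated to the first
#' `max_centers` (with a warning), bounding the expansion at
#' `2^max_centers` isomers.
#'
#' @param mol a standardized `ligand_record`.
#' @param max_centers maximum number of centers expanded (default 5).
#' @return list of `ligand_record`s; each has all enumerated centers
#'   assigned and an id of the form `"<id>#<i>"` (a single-element list with
#'   the input when there is nothing to enumerate).
#' @export
enumerate_stereoisomers <- function(mol, max_centers = 5) {
  centers <- find_stereocenters(mol)
  assigned <- mol$stereo$atom[mol$stereo$assigned]
  todo <- setdiff(centers, assigned)
  if (!length(todo)) {
    mol$stereo <- data.frame(atom = centers,
                             assigned = centers %in% assigned,
                             parity = ifelse(centers %in% assigned,
                                             mol$stereo$parity[
                                               match(centers, mol$stereo$atom)],
                                             0L))
    return(list(mol))
  }
  if (length(todo) > max_centers) {
    warning(mol$id, ": ", length(todo), " unassigned stereocenters, ",
            "enumerating the first ", max_centers)
    todo <- todo[seq_len(max_centers)]
  }
  k <- length(todo)
  grid <- as.matrix(expand.grid(rep(list(c(1L, 2L)), k)))
  lapply(seq_len(nrow(grid)), function(r) {
    iso <- mol
    iso$stereo <- rbind(
      mol$stereo[mol$stereo$assigned, , drop = FALSE],
      data.frame(atom = todo, assigned = TRUE, parity = grid[r, ]))
    iso$stereo <- iso$stereo[order(iso$stereo$atom), , drop = FALSE]
    iso$id <- paste0(mol$id, "#", r)
    iso$parent_id <- mol$id
    iso
  })
}
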