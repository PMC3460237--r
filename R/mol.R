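#' Small-molecule representation
#'
#' Ligands are held as `ligand_record` objects: an atom table (element,
#' formal charge, implicit hydrogen count, ring and aromatic flags), a bond
#' table (atom indices, integer order), stereocenter bookkeeping and the
#' indices of cationic centers. Connectivity comes from standard SMILES /
#' SDF input parsed with ChemmineR (OpenBabel underneath); formal charges
#' are taken from `M CHG` blocks when present, otherwise from atom-line
#' charge codes.
#'
#' @name mol
NULL

# MDL atom-line charge codes -> formal charge
.mdl_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                 `5` = -1, `6` = -2, `7` = -3)

default_valence <- function(element, charge, bondsum) {
  v <- switch(element,
    H = 1, B = 3, C = 4, Si = 4,
    N = 3 + charge, P = if (bondsum > 3 + charge) 5 else 3 + charge,
    O = 2 + charge,
    S = if (bondsum > 4) 6 else if (bondsum > 2) 4 else 2 + min(charge, 0),
    F = 1, Cl = 1, Br = 1, I = 1,
    0)
  max(v, 0)
}

compute_implicit_h <- function(atoms, bonds) {
  bondsum <- numeric(nrow(atoms))
  if (nrow(bonds)) {
    ord <- pmin(bonds$order, 3)
    for (i in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + ord[i]
      bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + ord[i]
    }
  }
  nH <- vapply(seq_len(nrow(atoms)), function(i) {
    v <- default_valence(atoms$element[i], atoms$charge[i], bondsum[i])
    max(0, v - bondsum[i])
  }, numeric(1))
  # explicit hydrogens consume implicit slots of their heavy neighbor
  nH[atoms$element == "H"] <- 0
  nH
}

new_ligand_record <- function(atoms, bonds, id = "mol", smiles = NA_character_,
                              source = "constructed", coords = NULL,
                              rings = list()) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (!nrow(atoms)) stop("empty molecule")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$ring)) atoms$ring <- FALSE
  if (is.null(atoms$arom)) atoms$arom <- FALSE
  if (nrow(bonds)) {
    stopifnot(all(bonds$a1 >= 1 & bonds$a1 <= nrow(atoms)),
              all(bonds$a2 >= 1 & bonds$a2 <= nrow(atoms)))
  }
  atoms$nH <- compute_implicit_h(atoms, bonds)
  rec <- structure(
    list(id = id, atoms = atoms, bonds = bonds,
         stereo = data.frame(atom = integer(), assigned = logical(),
                             parity = integer()),
         cationic = integer(), smiles = smiles, source = source,
         coords = coords, rings = rings, standardized = FALSE),
    class = "ligand_record")
  rec
}

#' @export
print.ligand_record <- function(x, ...) {
  cat("ligand_record <", x$id, ">: ", nrow(x$atoms), " atoms (",
      sum(x$atoms$element != "H"), " heavy), ", nrow(x$bonds), " bonds, ",
      "net charge ", sum(x$atoms$charge),
      if (x$standardized) ", standardized" else "", "\n", sep = "")
  invisible(x)
}

mol_graph <- function(rec) {
  igraph::graph_from_data_frame(
    d = if (nrow(rec$bonds)) rec$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(rec$atoms))))
}

bond_distances <- function(rec) {
  g <- mol_graph(rec)
  d <- igraph::distances(g)
  idx <- as.integer(igraph::V(g)$name)
  d[order(idx), order(idx), drop = FALSE]
}

heavy_idx <- function(rec) which(rec$atoms$element != "H")

# --- parsing ---------------------------------------------------------------

sdf_charges <- function(sdfstr_lines, natoms, code_col) {
  chg_lines <- grep("^M  CHG", sdfstr_lines, value = TRUE)
  charge <- rep(0L, natoms)
  if (length(chg_lines)) {
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) {
        charge[f[2 * k]] <- f[2 * k + 1]
      }
    }
  } else if (!is.null(code_col)) {
    charge <- unname(.mdl_charge[as.character(code_col)])
    charge[is.na(charge)] <- 0L
  }
  as.integer(charge)
}

sdf_to_record <- function(sdf, id = NULL, raw_lines = NULL,
                          source = "sdf") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  natoms <- nrow(ab)
  coords <- unname(ab[, 1:3, drop = FALSE])
  code_col <- if ("C5" %in% colnames(ab)) ab[, "C5"] else NULL
  if (is.null(raw_lines)) raw_lines <- as.character(ChemmineR::sdf2str(sdf))
  charge <- sdf_charges(raw_lines, natoms, code_col)
  bonds <- if (is.matrix(bb) && nrow(bb)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(a1 = integer(), a2 = integer(), order = integer())
  atoms <- data.frame(element = element, charge = charge,
                      stringsAsFactors = FALSE)
  # ring perception via ChemmineR; aromaticity from kekulized bond orders
  # (Hueckel-style), since rings(arom=TRUE) misflags saturated 5-rings
  ring <- rep(FALSE, natoms); arom <- rep(FALSE, natoms)
  ring_sets <- list()
  ri <- tryCatch(ChemmineR::rings(sdf, upper = 8, type = "all"),
                 error = function(e) NULL)
  if (!is.null(ri) && length(ri)) {
    ring_list <- if (is.list(ri) && !is.null(ri$RINGS)) ri$RINGS else ri
    for (j in seq_along(ring_list)) {
      members <- as.integer(sub("^.*_", "", ring_list[[j]]))
      ring_sets[[length(ring_sets) + 1]] <- members
      ring[members] <- TRUE
      if (perceive_aromatic_ring(members, element, bonds)) arom[members] <- TRUE
    }
  }
  atoms$ring <- ring
  atoms$arom <- arom
  if (is.null(id)) {
    id <- ChemmineR::sdfid(sdf)
    if (!length(id) || is.na(id) || id == "") id <- "mol"
  }
  new_ligand_record(atoms, bonds, id = id, source = source,
                    coords = coords, rings = ring_sets)
}

obabel_available <- function() nzchar(Sys.which("obabel"))

# Hueckel-style aromaticity for one ring of a kekulized connection table:
# every ring atom must either take part in a double bond (contributing one
# pi electron) or be a heteroatom donating its lone pair (two); aromatic
# when the pi count satisfies 4n + 2.
perceive_aromatic_ring <- function(members, element, bonds) {
  if (length(members) < 5 || length(members) > 7) return(FALSE)
  pi <- 0
  for (i in members) {
    dbl <- bonds$order[bonds$a1 == i | bonds$a2 == i] >= 2
    if (any(dbl)) pi <- pi + 1
    else if (element[i] %in% c("N", "O", "S")) pi <- pi + 2
    else return(FALSE)
  }
  pi %% 4 == 2
}

# minimal V2000 fallback for records ChemmineR rejects (e.g. single-atom
# or zero-bond molecules)
parse_v2000 <- function(lines, id = "mol", source = "sdf") {
  if (length(lines) < 4) stop("truncated SDF record")
  na <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  if (is.na(na) || na < 1) stop("no atoms in SDF record")
  at_lines <- lines[4 + seq_len(na)]
  element <- trimws(substr(at_lines, 32, 34))
  codes <- suppressWarnings(as.integer(substr(at_lines, 37, 39)))
  codes[is.na(codes)] <- 0L
  coords <- cbind(as.numeric(substr(at_lines, 1, 10)),
                  as.numeric(substr(at_lines, 11, 20)),
                  as.numeric(substr(at_lines, 21, 30)))
  bonds <- if (!is.na(nb) && nb > 0) {
    b_lines <- lines[4 + na + seq_len(nb)]
    data.frame(a1 = as.integer(substr(b_lines, 1, 3)),
               a2 = as.integer(substr(b_lines, 4, 6)),
               order = as.integer(substr(b_lines, 7, 9)))
  } else data.frame(a1 = integer(), a2 = integer(), order = integer())
  atoms <- data.frame(element = element,
                      charge = sdf_charges(lines, na, codes),
                      ring = FALSE, arom = FALSE, stringsAsFactors = FALSE)
  new_ligand_record(atoms, bonds, id = id, source = source,
                    coords = coords)
}

#' Parse a SMILES string into a ligand record
#'
#' @param smiles a single SMILES string.
#' @param id molecule identifier.
#' @return a `ligand_record`, or an error if the molecule does not sanitize.
#' @export
mol_from_smiles <- function(smiles, id = "mol") {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for SMILES input")
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, " ", id),
      options = data.frame(names = "gen2D", args = ""))),
    error = function(e) stop("cannot parse SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4 || !any(grepl("V2000", lines)))
    stop("cannot parse SMILES '", smiles, "'")
  sdfset <- suppressWarnings(tryCatch(ChemmineR::read.SDFset(lines),
                                      error = function(e) NULL))
  rec <- if (!is.null(sdfset) && length(sdfset) &&
             ChemmineR::validSDF(sdfset)[1]) {
    sdf_to_record(sdfset[[1]], id = id, raw_lines = lines,
                  source = "smiles")
  } else {
    parse_v2000(lines, id = id, source = "smiles")
  }
  rec$smiles <- smiles
  rec
}

#' Read a ligand library
#'
#' Reads a SMILES file (one molecule per line: `SMILES id`, whitespace
#' separated, `#` comments allowed) or an SDF file. Molecules that fail to
#' parse are collected in a rejection table instead of aborting the read.
#'
#' @param path input file.
#' @param format `"auto"`, `"smiles"` or `"sdf"`.
#' @return list with `records` (list of `ligand_record`) and `rejected`
#'   (data frame: id, stage, reason).
#' @export
read_ligands <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol", "sd")) "sdf" else "smiles"
  }
  records <- list(); rejects <- list()
  reject <- function(id, reason) {
    rejects[[length(rejects) + 1]] <<- data.frame(
      id = id, stage = "parse", reason = reason, stringsAsFactors = FALSE)
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\\s+")[[1]]
      id <- if (length(f) >= 2) f[2] else paste0("mol", i)
      rec <- tryCatch(mol_from_smiles(f[1], id = id), error = function(e) e)
      if (inherits(rec, "error")) reject(id, conditionMessage(rec))
      else records[[length(records) + 1]] <- rec
    }
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    raw <- readLines(path, warn = FALSE)
    # split raw records to recover M CHG blocks ChemmineR does not keep
    ends <- grep("^\\$\\$\\$\\$", raw)
    starts <- c(1, head(ends, -1) + 1)
    valid <- ChemmineR::validSDF(sdfset)
    for (k in seq_along(sdfset)) {
      rl <- raw[starts[k]:ends[min(k, length(ends))]]
      rec <- if (valid[k]) {
        tryCatch(sdf_to_record(sdfset[[k]], raw_lines = rl,
                               source = "sdf"),
                 error = function(e) e)
      } else {
        tryCatch(parse_v2000(rl, id = trimws(rl[1]), source = "sdf"),
                 error = function(e) e)
      }
      if (inherits(rec, "error")) {
        reject(paste0("record", k), conditionMessage(rec))
      } else {
        rec$record_index <- k
        records[[length(records) + 1]] <- rec
      }
    }
  }
  list(records = records,
       rejected = if (length(rejects)) do.call(rbind, rejects) else
         data.frame(id = character(), stage = character(),
                    reason = character()))
}

# --- writing ---------------------------------------------------------------

format_sdf_record <- function(rec, coords = NULL, name = rec$id,
                              data = list()) {
  atoms <- rec$atoms
  if (is.null(coords)) coords <- rec$coords
  if (is.null(coords)) coords <- matrix(0, nrow(atoms), 3)
  n <- nrow(atoms); nb <- nrow(rec$bonds)
  lines <- c(name, "  pocketfunnel", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[i, 1], coords[i, 2], coords[i, 3],
                              atoms$element[i]))
  }
  for (i in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", rec$bonds$a1[i],
                              rec$bonds$a2[i], min(rec$bonds$order[i], 3)))
  }
  chg <- which(atoms$charge != 0)
  while (length(chg)) {
    take <- head(chg, 8)
    chg <- chg[-seq_along(take)]
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(take)),
                             paste0(sprintf("%4d%4d", take,
                                            atoms$charge[take]),
                                    collapse = "")))
  }
  lines <- c(lines, "M  END")
  for (nm in names(data)) {
    lines <- c(lines, paste0(">  <", nm, ">"), as.character(data[[nm]]), "")
  }
  c(lines, "$$$$")
}

#' Write ligand records (with coordinates) to an SDF file
#'
#' @param records list of `ligand_record`s; each uses its own `coords`
#'   unless `coords_list` is given.
#' @param path output file.
#' @param coords_list optional list of coordinate matrices, parallel to
#'   `records`.
#' @param data_list optional list of named data-field lists per record.
#' @export
write_ligands_sdf <- function(records, path, coords_list = NULL,
                              data_list = NULL) {
  out <- character()
  for (i in seq_along(records)) {
    out <- c(out, format_sdf_record(
      records[[i]],
      coords = if (!is.null(coords_list)) coords_list[[i]] else NULL,
      data = if (!is.null(data_list)) data_list[[i]] else list()))
  }
  writeLines(out, path)
  invisible(path)
}
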