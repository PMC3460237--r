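#' Receptor structure input and preparation
#'
#' Structures are held as a `StructureModel`: a flat atom table with
#' chain / author residue number / insertion-code / atom-name addressing, a
#' source identifier and the set of chains. Alternate locations are resolved
#' at read time (highest occupancy wins, ties broken by altloc letter), so
#' `(chain, resno, insert, atom)` is unique.
#'
#' @name structio
NULL

new_structure_model <- function(atoms, source_id = "unknown") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure model")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atomic coordinates")
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, source_id = source_id,
         chains = sort(unique(atoms$chain))),
    class = "StructureModel"
  )
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel <", x$source_id, ">: ", nrow(x$atoms), " atoms, ",
      "chains {", paste(x$chains, collapse = ","), "}, ",
      sum(x$atoms$het), " hetero atoms\n", sep = "")
  invisible(x)
}

# Guess the element symbol from a PDB atom name when the element column is
# absent or blank.
guess_element <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*$|[0-9'\"]", "", elety))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "SE", "CA")
  # within standard residues CA is a carbon (alpha carbon), so only treat a
  # two-letter symbol as such for known non-carbon names
  out <- substr(e, 1, 1)
  is2 <- e %in% setdiff(two, "CA")
  out[is2] <- paste0(substr(e[is2], 1, 1), tolower(substr(e[is2], 2, 2)))
  out
}

resolve_altlocs <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  # highest occupancy first, ties by altloc letter order, then file order
  ord <- order(key, -occ, alt, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "\r")), , drop = FALSE]
  atoms[order(atoms$chain, atoms$resno, atoms$insert,
              seq_len(nrow(atoms))), , drop = FALSE]
}

#' Read a receptor structure from PDB or mmCIF
#'
#' Loads all ATOM/HETATM records of the first model, resolves alternate
#' locations to the highest-occupancy copy (ties broken by altloc letter)
#' and preserves author residue numbering and insertion codes.
#'
#' @param path file path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                         rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  a <- parsed$atom
  if (is.null(a) || !nrow(a)) stop("no atoms in model: ", path)
  element <- a$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(a))
  blank <- is.na(element) | element == ""
  element[blank] <- guess_element(a$elety[blank])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 10)))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    element = element,
    x = a$x, y = a$y, z = a$z,
    o = if (!is.null(a$o)) a$o else 1,
    alt = if (!is.null(a$alt)) a$alt else "",
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altlocs(atoms)
  atoms$o <- NULL
  atoms$alt <- NULL
  new_structure_model(atoms,
                      source_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Address and retrieve single atoms
#'
#' Atoms are addressed by chain, author residue number, PDB atom name and
#' (optionally) insertion code.
#'
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param atom PDB atom name (e.g. `"CA"`, `"NE1"`).
#' @param insert insertion code (default none).
#' @return `atom_address()`: an address list; `get_atom()`: the matching
#'   one-row atom table (error if absent).
#' @export
atom_address <- function(chain, resno, atom, insert = "") {
  list(chain = chain, resno = resno, atom = atom, insert = insert)
}

#' @rdname atom_address
#' @param model a `StructureModel`.
#' @param address an atom address.
#' @export
get_atom <- function(model, address) {
  a <- model$atoms
  hit <- a$chain == address$chain & a$resno == address$resno &
    a$elety == address$atom &
    a$insert == (address$insert %||% "")
  if (!any(hit)) stop("atom not found: ", address$chain, "/",
                      address$resno, "/", address$atom)
  a[which(hit)[1], , drop = FALSE]
}

heavy_atoms <- function(model) {
  model$atoms[model$atoms$element != "H", , drop = FALSE]
}

#' Prepare a receptor for screening
#'
#' Removes all hetero records (bound ligands, waters, ions), restricts the
#' model to the requested chains and places polar hydrogens with idealized
#' geometry on the donors needed for hydrogen-bond detection: backbone N-H,
#' hydroxyl O-H of Ser/Thr/Tyr (oriented toward the nearest acceptor),
#' the Trp indole N-H, and side-chain amide N-H2 of Asn/Gln. No energy
#' minimization is performed.
#'
#' @param model a `StructureModel`.
#' @param keep_chains chain identifiers to retain.
#' @return a `StructureModel` with hetero atoms removed and polar hydrogens
#'   appended (hydrogen rows carry `elety` of the form `"H<parent>"`).
#' @export
prepare_receptor <- function(model, keep_chains = model$chains) {
  if (!length(keep_chains)) stop("keep_chains must not be empty")
  bad <- setdiff(keep_chains, model$chains)
  if (length(bad)) stop("chains not in model: ", paste(bad, collapse = ","))
  a <- model$atoms
  a <- a[!a$het & a$chain %in% keep_chains & a$element != "H", , drop = FALSE]
  if (!nrow(a)) stop("no protein atoms left after chain/het filtering")
  h <- place_polar_hydrogens(a)
  out <- rbind(a, h)
  new_structure_model(out, source_id = paste0(model$source_id, "_prepared"))
}

# idealized bond lengths (Angstrom)
.NH_LEN <- 1.01
.OH_LEN <- 0.96

hydrogen_row <- function(parent, hname, pos) {
  data.frame(chain = parent$chain, resno = parent$resno,
             insert = parent$insert, resid = parent$resid,
             elety = hname, element = "H",
             x = pos[1], y = pos[2], z = pos[3], het = FALSE,
             stringsAsFactors = FALSE)
}

coords_of <- function(df) as.matrix(df[, c("x", "y", "z")])

place_polar_hydrogens <- function(a) {
  hs <- list()
  xyz <- coords_of(a)
  reskey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  res_index <- split(seq_len(nrow(a)), reskey)
  # ordered residue list per chain for backbone connectivity
  res_tab <- a[!duplicated(reskey), c("chain", "resno", "insert", "resid")]
  find_atom <- function(key, name) {
    idx <- res_index[[key]]
    idx[match(name, a$elety[idx])]
  }
  pos <- function(i) xyz[i, ]
  add <- function(parent_i, hname, p) {
    hs[[length(hs) + 1]] <<- hydrogen_row(a[parent_i, ], hname, p)
  }
  keys <- unique(reskey)
  for (k in keys) {
    idx <- res_index[[k]]
    resid <- a$resid[idx[1]]
    # --- backbone amide N-H (not proline, needs previous C within bond range)
    iN <- find_atom(k, "N"); iCA <- find_atom(k, "CA")
    if (!is.na(iN) && !is.na(iCA) && resid != "PRO") {
      same_chain <- which(a$chain == a$chain[iN] & a$elety == "C")
      if (length(same_chain)) {
        d2 <- colSums((t(xyz[same_chain, , drop = FALSE]) - pos(iN))^2)
        j <- same_chain[which.min(d2)]
        if (min(d2) < 1.8^2 && !(j %in% idx)) {
          dir <- unitv(unitv(pos(iN) - pos(iCA)) + unitv(pos(iN) - pos(j)))
          add(iN, "H", pos(iN) + .NH_LEN * dir)
        }
      }
    }
    # --- hydroxyls: Ser OG, Thr OG1, Tyr OH
    oh <- switch(resid, SER = c("OG", "CB"), THR = c("OG1", "CB"),
                 TYR = c("OH", "CZ"), NULL)
    if (!is.null(oh)) {
      iO <- find_atom(k, oh[1]); iC <- find_atom(k, oh[2])
      if (!is.na(iO) && !is.na(iC)) {
        # orient toward the nearest acceptor (N/O of another residue)
        acc <- which((a$element %in% c("N", "O")) & reskey != k)
        dir <- NULL
        if (length(acc)) {
          d2 <- colSums((t(xyz[acc, , drop = FALSE]) - pos(iO))^2)
          j <- acc[which.min(d2)]
          if (min(d2) < 3.5^2) dir <- unitv(pos(j) - pos(iO))
        }
        if (is.null(dir)) dir <- unitv(pos(iO) - pos(iC))
        add(iO, paste0("H", oh[1]), pos(iO) + .OH_LEN * dir)
      }
    }
    # --- Trp indole N-H
    if (resid == "TRP") {
      iNE <- find_atom(k, "NE1"); iCD <- find_atom(k, "CD1")
      iCE <- find_atom(k, "CE2")
      if (!is.na(iNE) && !is.na(iCD) && !is.na(iCE)) {
        dir <- unitv(unitv(pos(iNE) - pos(iCD)) + unitv(pos(iNE) - pos(iCE)))
        add(iNE, "HE1", pos(iNE) + .NH_LEN * dir)
      }
    }
    # --- side-chain amides: Asn (CG,OD1,ND2), Gln (CD,OE1,NE2)
    am <- switch(resid, ASN = c("CG", "OD1", "ND2"),
                 GLN = c("CD", "OE1", "NE2"), NULL)
    if (!is.null(am)) {
      iC <- find_atom(k, am[1]); iO <- find_atom(k, am[2])
      iNm <- find_atom(k, am[3])
      if (!is.na(iC) && !is.na(iO) && !is.na(iNm)) {
        u <- unitv(pos(iNm) - pos(iC))
        w <- unitv(pracma_cross(u, pos(iO) - pos(iC)))
        v <- pracma_cross(w, u)
        for (s in c(1, -1)) {
          dir <- unitv(0.5 * u + s * (sqrt(3) / 2) * v)
          add(iNm, paste0("H", am[3], if (s > 0) "1" else "2"),
              pos(iNm) + .NH_LEN * dir)
        }
      }
    }
  }
  if (!length(hs)) {
    return(a[0, c("chain", "resno", "insert", "resid", "elety", "element",
                  "x", "y", "z", "het")])
  }
  do.call(rbind, hs)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Extract a binding pocket around a center atom
#'
#' A residue belongs to the pocket if at least one of its heavy atoms lies
#' within `radius` (inclusive) of the center atom. The member list is
#' ordered by (chain, residue number).
#'
#' @param model a `StructureModel`.
#' @param center an atom address, e.g. `atom_address("A", 145, "NE1")`.
#' @param radius pocket radius in Angstrom (default 10).
#' @return a `PocketDefinition`: list with `center_atom`, `radius`,
#'   `member_residues` (data frame) and `atom_rows` (row indices of member
#'   residue atoms in `model$atoms`).
#' @export
extract_pocket <- function(model, center, radius = 10.0) {
  if (radius < 0) stop("radius must be >= 0")
  ctr <- get_atom(model, center)
  cpos <- as.numeric(ctr[1, c("x", "y", "z")])
  a <- model$atoms
  heavy <- a$element != "H"
  d2 <- (a$x - cpos[1])^2 + (a$y - cpos[2])^2 + (a$z - cpos[3])^2
  hit <- heavy & d2 <= radius^2 + 1e-12
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  member <- unique(key[hit])
  rows <- which(key %in% member)
  res <- a[rows, c("chain", "resno", "insert", "resid")]
  res <- res[!duplicated(paste(res$chain, res$resno, res$insert)), ]
  res <- res[order(res$chain, res$resno, res$insert), ]
  rownames(res) <- NULL
  structure(list(center_atom = center, radius = radius,
                 member_residues = res, atom_rows = rows),
            class = "PocketDefinition")
}
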