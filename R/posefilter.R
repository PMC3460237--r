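#' Post-docking pose filtering and ranking
#'
#' Docking poses and their scores come from an external program; this
#' module ingests them and applies the deterministic post-processing
#' filters: a cation-pi distance cutoff between the ligand's cationic
#' nitrogen and the reference tryptophan ring atom (CD2 as centroid proxy,
#' default cutoff 5.5 Angstrom, kept when the distance is <= the cutoff),
#' pocket containment, intra-/intermolecular steric clashes, and
#' hydrogen-bond annotation (annotation only; hydrogen bonds are preferred,
#' not required). Visual inspection is replaced by the ranked, annotated
#' shortlist.
#'
#' @name posefilter
NULL

new_pose <- function(id, atoms, bonds, score, tag = "", rank = NA_integer_) {
  structure(list(id = id, tag = tag, rank = rank, score = score,
                 atoms = atoms, bonds = bonds,
                 cationic = which(atoms$element == "N" & atoms$charge == 1)),
            class = "Pose")
}

#' @export
print.Pose <- function(x, ...) {
  cat("Pose <", x$id, if (nzchar(x$tag)) paste0("/", x$tag), ">: ",
      nrow(x$atoms), " atoms, score ", x$score, ", rank ", x$rank,
      "\n", sep = "")
  invisible(x)
}

#' Load docking poses with scores
#'
#' Reads an SDF (or mol2) multi-pose file. The docking score is taken from
#' the named SDF data field (`score_field`); poses without a parseable
#' score are skipped with a logged reason. Poses are grouped by ligand id
#' (molecule name; an optional `#tag` suffix after the name separates
#' stereoisomer tags) and ranked per ligand by descending score.
#'
#' @param path pose file.
#' @param format `"sdf"` or `"mol2"`.
#' @param score_field name of the score property (SDF data field). For
#'   mol2, a `# SCORE: <value>` comment preceding each molecule is used.
#' @param higher_is_better score convention (default TRUE, recorded).
#' @return list with `poses` (list of `Pose`), `skipped` (data frame) and
#'   `score_convention`.
#' @export
load_poses <- function(path, format = c("sdf", "mol2"),
                       score_field = "SCORE", higher_is_better = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("pose file not found: ", path)
  poses <- list(); skipped <- list()
  skip <- function(id, reason)
    skipped[[length(skipped) + 1]] <<- data.frame(
      id = id, reason = reason, stringsAsFactors = FALSE)
  if (format == "sdf") {
    lib <- read_ligands(path, format = "sdf")
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    rec_index <- vapply(lib$records, function(r)
      r$record_index %||% NA_integer_, integer(1))
    for (ri in seq_along(lib$records)) {
      k <- rec_index[ri]
      rec <- lib$records[[ri]]
      db <- ChemmineR::datablock(sdfset[[k]])
      name <- ChemmineR::sdfid(sdfset[[k]])
      if (!length(name) || is.na(name)) name <- rec$id
      sc <- suppressWarnings(as.numeric(db[score_field]))
      if (!length(sc) || is.na(sc)) {
        skip(name, paste0("missing or unparseable score field '",
                          score_field, "'"))
        next
      }
      id <- sub("#.*$", "", name)
      tag <- if (grepl("#", name)) sub("^[^#]*#", "", name) else ""
      atoms <- rec$atoms
      atoms$x <- rec$coords[, 1]; atoms$y <- rec$coords[, 2]
      atoms$z <- rec$coords[, 3]
      poses[[length(poses) + 1]] <- new_pose(id, atoms, rec$bonds, sc, tag)
    }
  } else {
    poses <- load_poses_mol2(path, skip)
  }
  if (!length(poses)) stop("no usable poses in ", path)
  # per-ligand ranks by score
  ids <- vapply(poses, `[[`, character(1), "id")
  scores <- vapply(poses, `[[`, numeric(1), "score")
  for (id in unique(ids)) {
    sel <- which(ids == id)
    ord <- sel[order(if (higher_is_better) -scores[sel] else scores[sel],
                     sel)]
    for (r in seq_along(ord)) poses[[ord[r]]]$rank <- r
  }
  list(poses = poses,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(id = character(), reason = character()),
       score_convention = if (higher_is_better) "higher" else "lower")
}

# minimal multi-molecule mol2 reader built on bio3d's single-molecule one
load_poses_mol2 <- function(path, skip) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("no @<TRIPOS>MOLECULE records in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  poses <- list()
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:ends[i]]
    name <- trimws(blk[2])
    sc_line <- grep("SCORE:", blk, value = TRUE)
    sc <- suppressWarnings(as.numeric(sub(".*SCORE:\\s*", "", sc_line[1])))
    if (!length(sc_line) || is.na(sc)) { skip(name, "missing SCORE comment"); next }
    tf <- tempfile(fileext = ".mol2")
    writeLines(blk, tf)
    m <- tryCatch(bio3d::read.mol2(tf), error = function(e) NULL)
    unlink(tf)
    if (is.null(m)) { skip(name, "unparseable mol2 record"); next }
    at <- m$atom
    element <- sub("\\..*$", "", at$elena)
    charge <- ifelse(grepl("\\.4$", at$elena) & element == "N", 1L, 0L)
    atoms <- data.frame(element = element, charge = charge,
                        x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    bonds <- if (!is.null(m$bond))
      data.frame(a1 = m$bond$origin, a2 = m$bond$target,
                 order = suppressWarnings(
                   ifelse(is.na(as.integer(m$bond$type)), 1L,
                          as.integer(m$bond$type))))
    else data.frame(a1 = integer(), a2 = integer(), order = integer())
    id <- sub("#.*$", "", name)
    tag <- if (grepl("#", name)) sub("^[^#]*#", "", name) else ""
    poses[[length(poses) + 1]] <- new_pose(id, atoms, bonds, sc, tag)
  }
  poses
}

#' Filter configuration for post-docking processing
#'
#' @param capi_reference atom address of the cation-pi reference (default
#'   W145 CD2 on chain A); use [atom_address()].
#' @param capi_max cation-pi distance cutoff, Angstrom (default 5.5; poses
#'   with a larger minimum distance are discarded).
#' @param use_ring_centroid measure to the true 6-ring centroid of the
#'   reference tryptophan instead of the CD2 proxy (default FALSE).
#' @param containment_center atom address of the pocket center (default
#'   W145 NE1 on chain A).
#' @param containment_radius,containment_margin pocket sphere, Angstrom
#'   (defaults 10 + 2): every ligand heavy atom must lie within
#'   radius + margin of the center.
#' @param clash_scale clash when an interatomic distance is below
#'   `clash_scale * (vdw_i + vdw_j)` (default 0.7).
#' @param hbond_max_da donor-acceptor distance cutoff, Angstrom (3.5).
#' @param hbond_min_angle minimum D-H...A angle, degrees (120).
#' @param hbond_targets data frame naming special receptor partners
#'   (columns `name`, `resno`, `atom`); defaults to the W145 backbone
#'   carbonyl, Y91 hydroxyl, W53 indole NH and Q114 side-chain amide.
#' @param contact_radius aromatic-cavity contact shell, Angstrom (4.5).
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(capi_reference = atom_address("A", 145, "CD2"),
                          capi_max = 5.5,
                          use_ring_centroid = FALSE,
                          containment_center = atom_address("A", 145, "NE1"),
                          containment_radius = 10.0,
                          containment_margin = 2.0,
                          clash_scale = 0.7,
                          hbond_max_da = 3.5,
                          hbond_min_angle = 120,
                          hbond_targets = default_hbond_targets(),
                          contact_radius = 4.5) {
  stopifnot(capi_max > 0, containment_radius > 0, containment_margin >= 0,
            clash_scale > 0, hbond_max_da > 0, hbond_min_angle > 0)
  structure(list(capi_reference = capi_reference, capi_max = capi_max,
                 use_ring_centroid = use_ring_centroid,
                 containment_center = containment_center,
                 containment_radius = containment_radius,
                 containment_margin = containment_margin,
                 clash_scale = clash_scale, hbond_max_da = hbond_max_da,
                 hbond_min_angle = hbond_min_angle,
                 hbond_targets = hbond_targets,
                 contact_radius = contact_radius),
            class = "FilterConfig")
}

#' @rdname filter_config
#' @export
default_hbond_targets <- function() {
  data.frame(
    name = c("W145_backbone_O", "Y91_OH", "W53_NE1H", "Q114_amide",
             "Q114_amide"),
    resno = c(145, 91, 53, 114, 114),
    atom = c("O", "OH", "NE1", "NE2", "OE1"),
    stringsAsFactors = FALSE)
}

capi_reference_point <- function(receptor, cfg) {
  if (isTRUE(cfg$use_ring_centroid)) {
    ref <- cfg$capi_reference
    ring_atoms <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
    pts <- do.call(rbind, lapply(ring_atoms, function(an) {
      tryCatch(as.numeric(get_atom(receptor,
                                   atom_address(ref$chain, ref$resno, an,
                                                ref$insert))[
                                     1, c("x", "y", "z")]),
               error = function(e) NULL)
    }))
    if (is.null(pts) || nrow(pts) < 3)
      stop("cannot build ring centroid for the cation-pi reference")
    colMeans(pts)
  } else {
    as.numeric(get_atom(receptor, cfg$capi_reference)[1, c("x", "y", "z")])
  }
}

#' Minimum cation-pi distance of a pose
#'
#' The minimum, over the pose's cationic nitrogen atoms, of the Euclidean
#' distance to the reference atom (W145 CD2 by default).
#'
#' @param pose a `Pose`.
#' @param receptor prepared `StructureModel`.
#' @param cfg a `FilterConfig` (or an atom address for `reference`).
#' @return distance in Angstrom.
#' @export
cation_pi_distance <- function(pose, receptor, cfg = filter_config()) {
  if (!length(pose$cationic))
    stop("pose ", pose$id, " has no cationic nitrogen")
  ref <- capi_reference_point(receptor, cfg)
  pts <- as.matrix(pose$atoms[pose$cationic, c("x", "y", "z")])
  min(sqrt(colSums((t(pts) - ref)^2)))
}

pose_heavy <- function(pose) pose$atoms$element != "H"

pose_clashes <- function(pose, receptor, cfg) {
  lig <- pose$atoms[pose_heavy(pose), , drop = FALSE]
  lig_rows <- which(pose_heavy(pose))
  rec <- heavy_atoms(receptor)
  rl <- vdw_radius(lig$element)
  rr <- vdw_radius(rec$element)
  d2 <- cross_dist2(as.matrix(lig[, c("x", "y", "z")]),
                    as.matrix(rec[, c("x", "y", "z")]))
  lim <- cfg$clash_scale * outer(rl, rr, "+")
  inter <- which(d2 < lim^2, arr.ind = TRUE)
  inter_df <- if (nrow(inter)) data.frame(
    type = "inter",
    ligand_atom = lig_rows[inter[, 1]],
    partner = paste0(rec$chain[inter[, 2]], rec$resno[inter[, 2]], "/",
                     rec$elety[inter[, 2]]),
    distance = sqrt(d2[inter]),
    stringsAsFactors = FALSE) else NULL
  # intramolecular: nonbonded pairs >= 4 bonds apart
  intra_df <- NULL
  if (nrow(pose$bonds) && nrow(lig) > 4) {
    rec_dummy <- list(atoms = pose$atoms, bonds = pose$bonds)
    gd <- bond_distances(rec_dummy)[lig_rows, lig_rows, drop = FALSE]
    dd2 <- cross_dist2(as.matrix(lig[, c("x", "y", "z")]),
                       as.matrix(lig[, c("x", "y", "z")]))
    liml <- cfg$clash_scale * outer(rl, rl, "+")
    bad <- which(dd2 < liml^2 & gd >= 4 & upper.tri(gd), arr.ind = TRUE)
    if (nrow(bad)) intra_df <- data.frame(
      type = "intra",
      ligand_atom = lig_rows[bad[, 1]],
      partner = paste0("atom", lig_rows[bad[, 2]]),
      distance = sqrt(dd2[bad]),
      stringsAsFactors = FALSE)
  }
  out <- rbind(inter_df, intra_df)
  if (is.null(out)) data.frame(type = character(), ligand_atom = integer(),
                               partner = character(), distance = numeric())
  else out
}

pose_containment <- function(pose, receptor, cfg) {
  ctr <- as.numeric(get_atom(receptor, cfg$containment_center)[
    1, c("x", "y", "z")])
  lig <- pose$atoms[pose_heavy(pose), , drop = FALSE]
  dmax <- sqrt(max(colSums((t(as.matrix(lig[, c("x", "y", "z")])) - ctr)^2)))
  list(pass = dmax <= cfg$containment_radius + cfg$containment_margin + 1e-9,
       max_dist = dmax)
}

contact_residues <- function(pose, receptor, cfg) {
  lig <- as.matrix(pose$atoms[pose_heavy(pose), c("x", "y", "z")])
  rec <- heavy_atoms(receptor)
  d2 <- cross_dist2(as.matrix(rec[, c("x", "y", "z")]), lig)
  near <- apply(d2, 1, min) <= cfg$contact_radius^2
  sort(unique(paste0(rec$chain[near], rec$resno[near], rec$resid[near])))
}

#' Apply the post-docking filters to a set of poses
#'
#' A pose is kept iff it passes the cation-pi distance filter AND the
#' containment filter AND has no steric clash. Every pose receives a full
#' interaction report regardless of verdict; hydrogen bonds are annotated,
#' never required.
#'
#' @param poses list of `Pose` objects.
#' @param receptor prepared `StructureModel` (polar hydrogens present).
#' @param cfg a `FilterConfig`.
#' @return list with `kept` (list of poses), `report` (one row per pose),
#'   `hbonds` (per-pose list) and `clashes` (per-pose list).
#' @export
apply_filters <- function(poses, receptor, cfg = filter_config()) {
  rows <- list(); hb_all <- list(); cl_all <- list(); keep <- logical()
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    capi <- cation_pi_distance(p, receptor, cfg)
    capi_pass <- capi <= cfg$capi_max + 1e-9
    cont <- pose_containment(p, receptor, cfg)
    cl <- pose_clashes(p, receptor, cfg)
    hb <- detect_hbonds(p, receptor, cfg)
    kept <- capi_pass && cont$pass && nrow(cl) == 0
    rows[[i]] <- data.frame(
      pose = paste0(p$id, if (nzchar(p$tag)) paste0("#", p$tag), "/",
                    p$rank),
      ligand = p$id, tag = p$tag, rank = p$rank, score = p$score,
      capi_dist = capi, capi_pass = capi_pass,
      containment_pass = cont$pass, containment_max_dist = cont$max_dist,
      n_clashes = nrow(cl), n_hbonds = nrow(hb),
      named_hbond = if (nrow(hb)) paste(unique(stats::na.omit(hb$target)),
                                        collapse = ",") else "",
      contacts = paste(contact_residues(p, receptor, cfg), collapse = ","),
      kept = kept, stringsAsFactors = FALSE)
    hb_all[[i]] <- hb; cl_all[[i]] <- cl; keep[i] <- kept
  }
  list(kept = poses[keep],
       report = do.call(rbind, rows),
       hbonds = hb_all, clashes = cl_all)
}

#' Rank kept poses and export the review shortlist
#'
#' Applies the per-ligand pose cap (default 3, by per-ligand score rank),
#' sorts globally by descending score with a deterministic tie-break on
#' (ligand id, pose rank), and returns the top `top_n` rows with their
#' interaction-report fields.
#'
#' @param kept list of kept `Pose`s (from [apply_filters()]).
#' @param report the matching report data frame.
#' @param top_n number of rows exported.
#' @param per_ligand_cap maximum poses per ligand (default 3).
#' @return the shortlist data frame.
#' @export
rank_and_shortlist <- function(kept, report, top_n, per_ligand_cap = 3) {
  if (top_n <= 0) stop("top_n must be positive")
  rep_kept <- report[report$kept, , drop = FALSE]
  rep_kept <- rep_kept[rep_kept$rank <= per_ligand_cap, , drop = FALSE]
  ord <- order(-rep_kept$score, rep_kept$ligand, rep_kept$rank)
  out <- rep_kept[ord, , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
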