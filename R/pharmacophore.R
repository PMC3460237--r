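#' Protein-derived excluded-volume pharmacophore screening
#'
#' The query consists of a single cationic feature sphere (placed at the
#' bound reference ligand's basic nitrogen) plus excluded-volume spheres on
#' every heavy atom of the binding-site residues. A conformer matches when
#' a rigid placement exists that puts a cationic nitrogen inside the
#' feature sphere with no ligand heavy atom inside any excluded volume;
#' ligand atoms are treated as points because the deliberately small
#' excluded-volume radius (default 0.8 Angstrom, below the carbon radius)
#' already encodes the induced-fit tolerance. Distances exactly equal to a
#' cutoff count as inside throughout this module.
#'
#' @name pharmacophore
NULL

#' Build a pharmacophore query from a receptor-ligand complex
#'
#' Selects every residue having at least one heavy atom within
#' `shell_cutoff` of any bound-ligand heavy atom, places an excluded volume
#' of radius `ev_radius` on ALL heavy atoms of those residues, and centers
#' the cationic feature sphere on the given ligand atom.
#'
#' @param receptor a prepared `StructureModel`.
#' @param bound_ligand data frame of bound-ligand atoms with columns
#'   `element`, `x`, `y`, `z` (e.g. the hetero records of a complex).
#' @param cationic_atom index into `bound_ligand` rows, or a length-3
#'   numeric position, marking the ligand's basic nitrogen.
#' @param shell_cutoff residue-selection shell, Angstrom (default 7).
#' @param ev_radius excluded-volume radius, Angstrom (default 0.8).
#' @param feature_radius cationic-feature radius, Angstrom (default 2.5).
#' @return a `PharmacophoreQuery`.
#' @export
build_query <- function(receptor, bound_ligand, cationic_atom,
                        shell_cutoff = 7.0, ev_radius = 0.8,
                        feature_radius = 2.5) {
  if (ev_radius <= 0 || feature_radius <= 0)
    stop("radii must be positive")
  lig <- bound_ligand[bound_ligand$element != "H", , drop = FALSE]
  if (!nrow(lig)) stop("bound ligand has no heavy atoms")
  feat_center <- if (is.numeric(cationic_atom) && length(cationic_atom) == 3)
    cationic_atom else as.numeric(lig[cationic_atom, c("x", "y", "z")])
  a <- receptor$atoms
  heavy <- a$element != "H"
  d2 <- cross_dist2(as.matrix(a[heavy, c("x", "y", "z")]),
                    as.matrix(lig[, c("x", "y", "z")]))
  near <- apply(d2, 1, min) <= shell_cutoff^2 + 1e-12
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  sel_res <- unique(key[heavy][near])
  if (!length(sel_res))
    stop("no residue within ", shell_cutoff,
         " A of the bound ligand; check the receptor/ligand pairing")
  rows <- which(heavy & key %in% sel_res)
  vols <- data.frame(
    x = a$x[rows], y = a$y[rows], z = a$z[rows], radius = ev_radius,
    label = paste0(a$chain[rows], a$resno[rows], "/", a$elety[rows]),
    stringsAsFactors = FALSE)
  structure(
    list(feature = list(center = feat_center, radius = feature_radius),
         volumes = vols, shell_cutoff = shell_cutoff,
         provenance = paste0(receptor$source_id, " shell=", shell_cutoff,
                             " ev=", ev_radius, " feat=", feature_radius)),
    class = "PharmacophoreQuery")
}

#' @export
print.PharmacophoreQuery <- function(x, ...) {
  cat("PharmacophoreQuery: cationic feature r=", x$feature$radius, " A at (",
      paste(round(x$feature$center, 2), collapse = ", "), "), ",
      nrow(x$volumes), " excluded volumes (r=",
      x$volumes$radius[1] %||% NA, " A)\n", sep = "")
  invisible(x)
}

#' Serialize / read a pharmacophore query as inspectable text
#'
#' @param query a `PharmacophoreQuery`.
#' @param path output (input) file path.
#' @export
write_query <- function(query, path) {
  lines <- c(
    "# pocketfunnel pharmacophore query",
    paste0("provenance\t", query$provenance),
    paste0("shell_cutoff\t", query$shell_cutoff),
    paste0("feature\t", paste(c(query$feature$center, query$feature$radius),
                              collapse = "\t")),
    vapply(seq_len(nrow(query$volumes)), function(i)
      paste0("volume\t", paste(c(query$volumes$x[i], query$volumes$y[i],
                                 query$volumes$z[i], query$volumes$radius[i],
                                 query$volumes$label[i]), collapse = "\t")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_query
#' @export
read_query <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  kv <- vapply(fields, `[[`, character(1), 1)
  feat <- as.numeric(fields[[which(kv == "feature")[1]]][2:5])
  vols <- fields[kv == "volume"]
  volumes <- do.call(rbind, lapply(vols, function(f)
    data.frame(x = as.numeric(f[2]), y = as.numeric(f[3]),
               z = as.numeric(f[4]), radius = as.numeric(f[5]),
               label = if (length(f) >= 6) f[6] else "",
               stringsAsFactors = FALSE)))
  structure(
    list(feature = list(center = feat[1:3], radius = feat[4]),
         volumes = volumes,
         shell_cutoff = as.numeric(fields[[which(kv == "shell_cutoff")[1]]][2]),
         provenance = fields[[which(kv == "provenance")[1]]][2]),
    class = "PharmacophoreQuery")
}

# violation count of a placed conformer: atoms whose centers fall inside
# any excluded volume (<= semantics), optionally grown by atom_radius
placement_violations <- function(xyz, query, atom_radius = 0) {
  if (!nrow(query$volumes)) return(0L)
  C <- as.matrix(query$volumes[, c("x", "y", "z")])
  d2 <- cross_dist2(xyz, C)
  lim <- (query$volumes$radius + atom_radius)^2 + 1e-12
  sum(apply(sweep(d2, 2, lim, "<="), 1, any))
}

#' Verify a stored match placement (certificate re-check)
#'
#' Re-applies the rigid placement stored in a `MatchResult` and checks,
#' with no search, that the anchor nitrogen lies inside the feature sphere
#' and that no ligand heavy atom violates an excluded volume.
#'
#' @param xyz heavy-atom conformer coordinates (n x 3).
#' @param cationic_row row index of the anchoring cationic nitrogen.
#' @param query the `PharmacophoreQuery`.
#' @param placement list with `rotation`, `translation` (x' = x R^T + t).
#' @param atom_radius per-ligand-atom radius (default 0).
#' @return TRUE when the certificate is valid.
#' @export
verify_placement <- function(xyz, cationic_row, query, placement,
                             atom_radius = 0) {
  placed <- tcrossprod(xyz, placement$rotation) +
    matrix(placement$translation, nrow(xyz), 3, byrow = TRUE)
  in_feat <- vnorm(placed[cationic_row, ] - query$feature$center) <=
    query$feature$radius + 1e-9
  in_feat && placement_violations(placed, query, atom_radius) == 0
}

#' Search for a rigid placement of a conformer in a pharmacophore query
#'
#' Enumerates anchor positions for each cationic nitrogen on a cubic grid
#' inside the feature sphere crossed with a deterministic quasi-uniform
#' rotation grid, with an optional greedy clash-count descent from the best
#' grid placement. A match stores a certifying placement.
#'
#' @param xyz heavy-atom conformer coordinates (n x 3).
#' @param cationic_rows row indices of cationic nitrogens (>= 1 required).
#' @param query a `PharmacophoreQuery`.
#' @param spacing anchor grid spacing, Angstrom (default 0.5).
#' @param rot_deg nominal rotation resolution, degrees (default 30).
#' @param refine run local descent refinement (default TRUE).
#' @param atom_radius per-ligand-atom radius added to excluded volumes
#'   (default 0: atoms are points).
#' @return a `MatchResult`: list with `matched`, `placement` (rotation +
#'   translation or NULL), `anchor_row`, `violation_count_at_best`.
#' @export
match_conformer <- function(xyz, cationic_rows, query, spacing = 0.5,
                            rot_deg = 30, refine = TRUE, atom_radius = 0) {
  xyz <- as.matrix(xyz)
  if (!length(cationic_rows)) stop("conformer has no cationic center")
  n_rot <- max(1L, as.integer(round((360 / rot_deg)^3 / 24)))
  rots <- rotation_grid(n_rot)
  anchors <- sphere_grid(query$feature$center, query$feature$radius, spacing)
  C <- as.matrix(query$volumes[, c("x", "y", "z")])
  rlim2 <- (query$volumes$radius + atom_radius)^2 + 1e-12
  m <- nrow(xyz)
  best <- list(viol = Inf, placement = NULL, anchor_row = NA_integer_)
  # anchor positions at which atom i (offset o) violates some volume:
  # those within the volume radius of C - o
  atom_viol <- function(o) {
    d2 <- cross_dist2(anchors, sweep(C, 2, o))
    rowSums(sweep(d2, 2, rlim2, "<=")) > 0
  }
  for (crow in cationic_rows) {
    centered <- sweep(xyz, 2, xyz[crow, ])
    # pass 1: existence check with per-atom anchor elimination (cheap
    # early exit for hopeless rotations); remember the deepest rotation
    deep <- list(depth = -1, ri = 1)
    for (ri in seq_along(rots)) {
      A <- tcrossprod(centered, rots[[ri]])     # m x 3, anchor at origin
      alive <- rep(TRUE, nrow(anchors))
      depth <- 0
      for (i in seq_len(m)) {
        v <- atom_viol(A[i, ])
        alive <- alive & !v
        if (!any(alive)) break
        depth <- i
      }
      if (depth == m) {                          # zero-violation placement
        j <- which(alive)[1]
        t_j <- anchors[j, ] - as.numeric(rots[[ri]] %*% xyz[crow, ])
        best <- list(viol = 0,
                     placement = list(rotation = rots[[ri]],
                                      translation = t_j),
                     anchor_row = crow)
        break
      }
      if (depth > deep$depth) deep <- list(depth = depth, ri = ri)
    }
    if (best$viol == 0) break
    # pass 2: violation counts for the most promising rotation only, to
    # seed the local descent refinement
    A <- tcrossprod(centered, rots[[deep$ri]])
    viol <- rowSums(vapply(seq_len(m), function(i)
      as.numeric(atom_viol(A[i, ])), numeric(nrow(anchors))))
    j <- which.min(viol)
    if (viol[j] < best$viol) {
      t_j <- anchors[j, ] - as.numeric(rots[[deep$ri]] %*% xyz[crow, ])
      best <- list(viol = viol[j],
                   placement = list(rotation = rots[[deep$ri]],
                                    translation = t_j),
                   anchor_row = crow)
    }
  }
  if (best$viol > 0 && refine && is.finite(best$viol)) {
    best <- refine_placement(xyz, best, query, spacing, rot_deg, atom_radius)
  }
  matched <- best$viol == 0
  structure(list(matched = matched,
                 placement = if (matched) best$placement else NULL,
                 anchor_row = best$anchor_row,
                 violation_count_at_best = as.integer(best$viol)),
            class = "MatchResult")
}

# greedy descent over small translation/rotation perturbations, keeping the
# anchor nitrogen inside the feature sphere
refine_placement <- function(xyz, best, query, spacing, rot_deg,
                             atom_radius) {
  eval_placement <- function(pl) {
    placed <- tcrossprod(xyz, pl$rotation) +
      matrix(pl$translation, nrow(xyz), 3, byrow = TRUE)
    anchor <- placed[best$anchor_row, ]
    if (vnorm(anchor - query$feature$center) > query$feature$radius + 1e-9)
      return(Inf)
    placement_violations(placed, query, atom_radius)
  }
  cur <- best$placement
  cur_v <- best$viol
  steps <- c(spacing / 2, spacing / 4)
  angs <- c(rot_deg / 2, rot_deg / 4) * pi / 180
  improved <- TRUE
  iter <- 0
  while (improved && cur_v > 0 && iter < 60) {
    improved <- FALSE
    iter <- iter + 1
    for (s in steps) for (ax in 1:3) for (sgn in c(-1, 1)) {
      cand <- cur
      cand$translation[ax] <- cand$translation[ax] + sgn * s
      v <- eval_placement(cand)
      if (v < cur_v) { cur <- cand; cur_v <- v; improved <- TRUE }
    }
    for (aa in angs) for (ax in 1:3) for (sgn in c(-1, 1)) {
      axis <- c(0, 0, 0); axis[ax] <- 1
      Rp <- rotation_about_axis(axis, sgn * aa)
      cand <- cur
      cand$rotation <- Rp %*% cur$rotation
      # rotate about the current anchor position
      anchor <- as.numeric(cur$rotation %*% xyz[best$anchor_row, ]) +
        cur$translation
      cand$translation <- anchor - as.numeric(cand$rotation %*%
                                                xyz[best$anchor_row, ])
      v <- eval_placement(cand)
      if (v < cur_v) { cur <- cand; cur_v <- v; improved <- TRUE }
    }
  }
  list(viol = cur_v, placement = cur, anchor_row = best$anchor_row)
}

#' Screen a conformer library against a pharmacophore query
#'
#' A ligand passes when ANY of its conformers matches the query.
#'
#' @param library list of `ConformerSet`s (standardized, cationic ligands).
#' @param query a `PharmacophoreQuery`.
#' @param ... search settings passed to [match_conformer()].
#' @return list with `passed` (ligand ids) and `results` (per-conformer
#'   table: ligand, conformer, matched, violations).
#' @export
screen_library <- function(library, query, ...) {
  rows <- list()
  passed <- character()
  for (cs in library) {
    rec <- cs$ligand
    hidx <- heavy_idx(rec)
    cat_rows <- match(rec$cationic, hidx)
    cat_rows <- cat_rows[!is.na(cat_rows)]
    lig_pass <- FALSE
    for (ci in seq_along(cs$conformers)) {
      mr <- if (lig_pass) NULL else
        match_conformer(cs$conformers[[ci]], cat_rows, query, ...)
      matched <- !is.null(mr) && mr$matched
      rows[[length(rows) + 1]] <- data.frame(
        ligand = rec$id, conformer = ci,
        matched = if (is.null(mr)) NA else mr$matched,
        violations = if (is.null(mr)) NA_integer_ else
          mr$violation_count_at_best,
        stringsAsFactors = FALSE)
      if (matched) lig_pass <- TRUE
    }
    if (lig_pass) passed <- c(passed, rec$id)
  }
  list(passed = passed,
       results = if (length(rows)) do.call(rbind, rows) else
         data.frame(ligand = character(), conformer = integer(),
                    matched = logical(), violations = integer()))
}
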