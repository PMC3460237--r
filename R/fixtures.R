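#' Synthetic fixtures with planted, machine-checkable outcomes
#'
#' Generators for toy receptors (spherical-shell cavities with a
#' tryptophan-like probe group), pharmacophore queries, pose sets with
#' planted cation-pi distances and hydrogen-bond geometries, and a small
#' screening library whose per-stage funnel bookkeeping is known by
#' construction. Fixtures are chemically minimal: they exercise geometry
#' and bookkeeping, not chemical realism, and every generator is
#' deterministic in its seed.
#'
#' Two cavity styles are used. A sparse shell (default) leaves gaps
#' between excluded volumes and is used for pose fixtures, where only
#' distances matter. A sealed shell (two concentric layers with atom
#' spacing below the diameter of coverage of one excluded volume) makes
#' the cavity wall impassable for point atoms, so that pass/fail
#' pharmacophore verdicts are provable from ligand size alone.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' @param seed integer seed; identical seeds reproduce identical fixtures.
#' @param cavity_radius cavity shell radius, Angstrom (> 2.5).
#' @param n_shell number of shell pseudo-atoms (sparse style).
#' @param sealed build an impassable double shell (spacing 0.9 A).
#' @param include_probe add the tryptophan-like probe group (CD2, NE1,
#'   backbone O anchors).
#' @param probe_dist distance of the probe CD2 atom from the cavity
#'   center (default 0.75 * cavity_radius).
#' @param feature_radius cationic feature radius (default 2.5).
#' @param ev_radius excluded-volume radius (default 0.8).
#' @param n_poses,planted_dists,n_hbond pose-set parameters: number of
#'   distance-planted poses, their cation-pi distances (defaults to
#'   5.4/5.5/5.6 plus seeded draws from 3.5-7.5 A), and the number of
#'   additional hydrogen-bond-planted poses.
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 7, cavity_radius = 6, n_shell = 80,
                         sealed = FALSE, include_probe = TRUE,
                         probe_dist = NULL, feature_radius = 2.5,
                         ev_radius = 0.8, n_poses = 50,
                         planted_dists = NULL, n_hbond = 5) {
  if (cavity_radius <= 2.5) stop("cavity_radius must exceed 2.5 A")
  if (is.null(probe_dist)) probe_dist <- 0.75 * cavity_radius
  structure(as.list(environment()), class = "FixtureSpec")
}

# idealized tryptophan-like probe; CD2 at `dist` along +x from the center,
# indole ring lying in the xy-plane
trp_probe_atoms <- function(dist) {
  local <- rbind(
    CD2 = c(0.00, 0.00, 0.00), CE2 = c(1.37, 0.00, 0.00),
    NE1 = c(1.79, 1.31, 0.00), CD1 = c(0.72, 2.12, 0.00),
    CG  = c(-0.36, 1.33, 0.00), CB  = c(-1.35, 2.25, 0.45),
    CA  = c(-2.55, 1.60, 1.10), N   = c(-3.60, 2.40, 0.90),
    C   = c(-3.00, 0.30, 1.60), O   = c(-2.70, -0.80, 1.20),
    CE3 = c(-0.70, -1.20, 0.00), CZ3 = c(0.00, -2.40, 0.00),
    CH2 = c(1.40, -2.40, 0.00), CZ2 = c(2.10, -1.20, 0.00))
  pos <- sweep(local, 2, c(dist, 0, 0), "+")
  data.frame(chain = "A", resno = 145, insert = "", resid = "TRP",
             elety = rownames(local),
             element = substr(rownames(local), 1, 1),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], het = FALSE,
             stringsAsFactors = FALSE)
}

shell_points <- function(n, radius, seed) {
  pts <- fibonacci_sphere(n) * radius
  # seeded random rotation so different seeds give different shells while
  # every point stays exactly on the sphere
  q <- with_seed(seed, stats::runif(4, -1, 1))
  pts %*% t(quat_to_rot(q))
}

shell_atom_rows <- function(pts, chain, resno0 = 1) {
  data.frame(chain = chain, resno = resno0 + seq_len(nrow(pts)) - 1,
             insert = "", resid = "EXV", elety = "C", element = "C",
             x = pts[, 1], y = pts[, 2], z = pts[, 3], het = FALSE,
             stringsAsFactors = FALSE)
}

#' Build a toy binding pocket and its pharmacophore query
#'
#' A spherical shell of pseudo-residue atoms around a central cationic
#' feature point, optionally with a tryptophan-like probe group supplying
#' the CD2 / NE1 / backbone-O anchor atoms. Sealed shells add a second
#' layer at +0.75 A with 0.9 A atom spacing, making the wall band
#' impassable for atom centers.
#'
#' @param spec a `FixtureSpec`.
#' @param dir if given, the pocket is also written to `<dir>/pocket.pdb`.
#' @return list with `model` (`StructureModel`), `query`
#'   (`PharmacophoreQuery`) and `pdb` (path or NULL).
#' @export
make_toy_pocket <- function(spec, dir = NULL) {
  R <- spec$cavity_radius
  if (spec$sealed) {
    # two layers 0.7 A apart at ~0.8 A point spacing: every point of the
    # radial band [R - 0.5, R + 1.2] lies within < 0.8 A of some shell
    # atom, so the 0.8 A excluded volumes seal the wall for atom centers
    n1 <- ceiling(4 * pi * R^2 / 0.64)
    n2 <- ceiling(4 * pi * (R + 0.7)^2 / 0.64)
    pts <- rbind(shell_points(n1, R, spec$seed),
                 shell_points(n2, R + 0.7, spec$seed + 1))
  } else {
    pts <- shell_points(spec$n_shell, R, spec$seed)
  }
  rows <- shell_atom_rows(pts, chain = "S")
  if (spec$include_probe)
    rows <- rbind(rows, trp_probe_atoms(spec$probe_dist))
  model <- new_structure_model(rows, source_id =
                                 paste0("toy_pocket_seed", spec$seed))
  query <- build_query(
    model, data.frame(element = "N", x = 0, y = 0, z = 0),
    cationic_atom = 1,
    shell_cutoff = max(7.0, R + 1.6), ev_radius = spec$ev_radius,
    feature_radius = spec$feature_radius)
  pdb <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pdb <- file.path(dir, "pocket.pdb")
    write_structure_pdb(model, pdb)
  }
  list(model = model, query = query, pdb = pdb)
}

#' Write a StructureModel as a PDB file
#'
#' @param model a `StructureModel`.
#' @param path output path.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$het[i]) "HETATM" else "ATOM", i,
            substr(a$elety[i], 1, 4), a$resid[i], a$chain[i], a$resno[i],
            a$insert[i], a$x[i], a$y[i], a$z[i], 1.0, 0.0,
            toupper(a$element[i]))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a rigid-ligand / cavity matcher fixture with a known verdict
#'
#' Builds one spherical-cavity query plus a rigid linear three-atom
#' cationic ligand whose pharmacophore verdict is provable by
#' construction: "pass" fixtures use a roomy sparse cavity with the ligand
#' span at least 1 A clear of the wall; "fail" fixtures either seal a
#' too-small cavity (ligand span exceeds the free inner diameter and the
#' wall band is impassable) or plug the entire feature sphere with
#' excluded volumes (no anchor position exists).
#'
#' @param seed fixture seed.
#' @param kind `"pass"`, `"fail_sealed"` or `"fail_plug"`.
#' @return list with `query`, `coords` (3 x 3 linear ligand),
#'   `cationic_row` (1), `expected` (logical) and `kind`.
#' @export
make_match_fixture <- function(seed,
                               kind = c("pass", "fail_sealed",
                                        "fail_plug")) {
  kind <- match.arg(kind)
  draws <- with_seed(seed, stats::runif(6))
  if (kind == "pass") {
    R <- 5.5 + 1.3 * draws[1]
    n <- 60 + floor(40 * draws[2])
    spec <- fixture_spec(seed = seed, cavity_radius = R, n_shell = n,
                         include_probe = FALSE)
    b1 <- 1.2 + 0.4 * draws[3]; b2 <- 1.2 + 0.4 * draws[4]
    expected <- TRUE
  } else if (kind == "fail_sealed") {
    # ligand span 3 x 1.6 = 4.8 A exceeds the free inner diameter
    # 2 * (R - 0.5) ~ 4.2 A of the sealed cavity
    spec <- fixture_spec(seed = seed, cavity_radius = 2.6 + 0.05 * draws[1],
                         sealed = TRUE, include_probe = FALSE)
    b1 <- b2 <- 1.6
    expected <- FALSE
  } else {
    spec <- fixture_spec(seed = seed, cavity_radius = 5.5 + draws[1],
                         n_shell = 80, include_probe = FALSE)
    b1 <- 1.2 + 0.4 * draws[3]; b2 <- 1.2 + 0.4 * draws[4]
    expected <- FALSE
  }
  pocket <- make_toy_pocket(spec)
  query <- pocket$query
  if (kind == "fail_plug") {
    # cover the whole feature sphere: grid spacing 0.9 keeps every point
    # within 0.78 A of a volume center (< ev radius 0.8)
    plug <- sphere_grid(query$feature$center,
                        query$feature$radius + 1.0, 0.9)
    query$volumes <- rbind(query$volumes,
                           data.frame(x = plug[, 1], y = plug[, 2],
                                      z = plug[, 3],
                                      radius = query$volumes$radius[1],
                                      label = "plug"))
  }
  u <- unitv(with_seed(seed + 17, stats::rnorm(3)))
  base <- with_seed(seed + 31, stats::rnorm(3))
  coords <- rbind(base, base + b1 * u, base + (b1 + b2) * u)
  if (kind == "fail_sealed")
    coords <- rbind(coords, base + (b1 + 2 * b2) * u)
  list(query = query, coords = unname(coords), cationic_row = 1L,
       expected = expected, kind = kind,
       spec = spec)
}

#' Brute-force rigid-search oracle for linear ligands
#'
#' Exhaustively enumerates anchor positions of the cationic atom on a fine
#' grid inside the feature sphere crossed with directions of the molecular
#' axis on a spherical grid, and reports whether any placement is free of
#' excluded-volume violations. Written as an independent reference for
#' [match_conformer()]; shares no search code with it.
#'
#' @param coords collinear ligand coordinates (n x 3; atom 1 anchors).
#' @param query a `PharmacophoreQuery`.
#' @param n_dir number of axis directions (default 350).
#' @param spacing anchor grid spacing in Angstrom (default 0.3).
#' @return TRUE if some placement matches.
#' @export
match_linear_oracle <- function(coords, query, n_dir = 350,
                                spacing = 0.3) {
  coords <- as.matrix(coords)
  delta <- sweep(coords, 2, coords[1, ])
  t_off <- sqrt(rowSums(delta^2))
  # confirm collinearity of the fixture ligand
  if (nrow(coords) > 2) {
    u0 <- unitv(coords[2, ] - coords[1, ])
    proj <- delta - outer(as.numeric(delta %*% u0), u0)
    if (max(abs(proj)) > 1e-6) stop("oracle expects a collinear ligand")
  }
  anchors <- sphere_grid(query$feature$center, query$feature$radius,
                         spacing)
  C <- as.matrix(query$volumes[, c("x", "y", "z")])
  rlim2 <- query$volumes$radius^2 + 1e-12
  # atom 1 sits on the anchor itself: eliminate blocked anchors once
  ok0 <- rowSums(sweep(cross_dist2(anchors, C), 2, rlim2, "<=")) == 0
  anchors <- anchors[ok0, , drop = FALSE]
  if (!nrow(anchors)) return(FALSE)
  dirs <- fibonacci_sphere(n_dir)
  rest <- which(t_off > 0)
  if (!length(rest)) return(TRUE)
  for (d in seq_len(n_dir)) {
    u <- dirs[d, ]
    alive <- seq_len(nrow(anchors))
    for (i in rest) {
      Ci <- sweep(C, 2, t_off[i] * u)   # anchor positions hit via atom i
      d2 <- cross_dist2(anchors[alive, , drop = FALSE], Ci)
      good <- rowSums(sweep(d2, 2, rlim2, "<=")) == 0
      alive <- alive[good]
      if (!length(alive)) break
    }
    if (length(alive)) return(TRUE)
  }
  FALSE
}

# --- pose fixtures ---------------------------------------------------------

pose_ligand_record <- function(id) {
  atoms <- data.frame(element = c("N", "C", "C", "H"),
                      charge = c(1L, 0L, 0L, 0L),
                      ring = FALSE, arom = FALSE,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = c(1, 1, 1), a2 = c(2, 3, 4), order = 1L)
  new_ligand_record(atoms, bonds, id = id, source = "fixture")
}

# orthonormal frame completing unit vector u
frame_of <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- unitv(pracma_cross(u, a))
  w <- pracma_cross(u, v)
  list(v = v, w = w)
}

#' Generate a pose set with planted cation-pi and hydrogen-bond geometry
#'
#' Builds `n_poses` poses of a minimal cationic ligand (N+, two carbons,
#' one polar hydrogen) inside the sparse toy pocket, each with its
#' cationic nitrogen planted at an exact distance from the probe CD2 atom,
#' plus `n_hbond` poses whose N-H is aimed at the probe backbone carbonyl
#' O with donor-acceptor distance 2.9 A and D-H...A angle 165 degrees.
#' All poses are clash-free and inside the containment sphere by
#' construction; the truth table lists the expected keep/discard verdict
#' at the 5.5 A cutoff and the expected hydrogen-bond detections.
#'
#' @param spec a `FixtureSpec`.
#' @param dir output directory; writes `pocket.pdb`, `poses.sdf`,
#'   `truth.tsv`.
#' @return list with `pocket`, `poses_file`, `truth`, `receptor`.
#' @export
make_pose_set <- function(spec, dir = NULL) {
  spec$include_probe <- TRUE
  pocket <- make_toy_pocket(spec, dir = dir)
  model <- pocket$model
  rec_heavy <- heavy_atoms(model)
  rec_xyz <- coords_of(rec_heavy)
  cd2 <- as.numeric(get_atom(model, atom_address("A", 145, "CD2"))[
    1, c("x", "y", "z")])
  oxy <- as.numeric(get_atom(model, atom_address("A", 145, "O"))[
    1, c("x", "y", "z")])
  R <- spec$cavity_radius
  dists <- spec$planted_dists
  if (is.null(dists)) {
    extra <- with_seed(spec$seed + 3,
                       stats::runif(max(0, spec$n_poses - 3), 3.5, 7.5))
    dists <- c(5.4, 5.5, 5.6, round(extra, 3))[seq_len(spec$n_poses)]
  }
  # acceptors the planted non-hbond poses must avoid: receptor O atoms
  acceptors <- rec_xyz[rec_heavy$element == "O", , drop = FALSE]
  clash_free <- function(pts) {
    lim2 <- outer(vdw_radius(c("N", "C", "C")), vdw_radius(rec_heavy$element),
                  function(a, b) (0.75 * (a + b))^2)
    all(cross_dist2(pts, rec_xyz) > lim2) &&
      all(sqrt(rowSums(pts^2)) <= R - 2.6)
  }
  dirs <- fibonacci_sphere(1001)
  build_pose <- function(dist) {
    for (k in seq_len(nrow(dirs))) {
      u <- dirs[k, ]
      n_pos <- cd2 + dist * u
      if (vnorm(n_pos) > R - 2.7) next
      fr <- frame_of(u)
      c1 <- n_pos + 1.49 * fr$v
      c2 <- n_pos + 1.49 * unitv(-0.5 * fr$v + 0.86 * fr$w)
      pts <- rbind(n_pos, c1, c2)
      if (!clash_free(pts)) next
      # point the N-H directly away from the nearest acceptor so no
      # hydrogen bond can satisfy the angle criterion
      d2a <- colSums((t(acceptors) - n_pos)^2)
      away <- unitv(n_pos - acceptors[which.min(d2a), ])
      h <- n_pos + 1.01 * away
      return(rbind(pts, h))
    }
    stop("could not place a clash-free pose at distance ", dist)
  }
  coords_list <- list(); ids <- character(); truth <- list()
  for (i in seq_along(dists)) {
    id <- sprintf("P%02d", i)
    # quantize to SDF precision first so the truth distance is exactly
    # what any reader of the pose file will recompute
    xyz <- round(build_pose(dists[i]), 4)
    planted <- vnorm(xyz[1, ] - cd2)
    coords_list[[length(coords_list) + 1]] <- xyz
    ids <- c(ids, id)
    truth[[length(truth) + 1]] <- data.frame(
      id = id, planted_dist = planted,
      expect_keep = planted <= 5.5 + 1e-9,
      expect_hbond = FALSE, expect_hbond_target = "",
      stringsAsFactors = FALSE)
  }
  # hydrogen-bond planted poses: N-H aimed at the probe backbone O
  hb_target_da <- 2.9; hb_angle <- 165
  for (j in seq_len(spec$n_hbond)) {
    id <- sprintf("HB%02d", j)
    placed <- NULL
    for (k in seq_len(nrow(dirs))) {
      w <- dirs[k, ]
      n_pos <- oxy + hb_target_da * w
      if (vnorm(n_pos) > R - 2.7) next
      if (vnorm(n_pos - cd2) > 5.4) next   # keep the pose capi-clean
      e <- unitv(oxy - n_pos)
      fr <- frame_of(e)
      # rotate the N-H away from the N-A line until the D-H...A angle hits
      # the planted value (bisection on the tilt)
      ang_of <- function(alpha) {
        m <- unitv(cos(alpha) * e + sin(alpha) * fr$v)
        hpos <- n_pos + 1.01 * m
        v1 <- n_pos - hpos; v2 <- oxy - hpos
        acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2))) * 180 / pi
      }
      lo <- 0; hi <- pi / 3
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (ang_of(mid) > hb_angle) lo <- mid else hi <- mid
      }
      hdir <- unitv(cos(lo) * e + sin(lo) * fr$v)
      hpos <- n_pos + 1.01 * hdir
      c1 <- n_pos + 1.49 * unitv(-0.6 * e + 0.8 * fr$w)
      c2 <- n_pos + 1.49 * unitv(-0.6 * e - 0.8 * fr$w)
      pts <- rbind(n_pos, c1, c2)
      if (!clash_free(pts)) next
      placed <- rbind(pts, hpos)
      break
    }
    if (is.null(placed)) stop("could not place hydrogen-bond pose ", j)
    placed <- round(placed, 4)
    coords_list[[length(coords_list) + 1]] <- placed
    ids <- c(ids, id)
    truth[[length(truth) + 1]] <- data.frame(
      id = id, planted_dist = vnorm(placed[1, ] - cd2),
      expect_keep = TRUE, expect_hbond = TRUE,
      expect_hbond_target = "W145_backbone_O", stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  scores <- round(40 - 0.07 * seq_along(ids), 4)
  recs <- lapply(ids, pose_ligand_record)
  poses_file <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    poses_file <- file.path(dir, "poses.sdf")
    write_ligands_sdf(recs, poses_file, coords_list = coords_list,
                      data_list = lapply(scores, function(s)
                        list(SCORE = sprintf("%.4f", s))))
    write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  receptor <- prepare_receptor(model)
  list(pocket = pocket, poses_file = poses_file, truth = truth,
       receptor = receptor, coords = coords_list, ids = ids,
       scores = scores)
}

# --- funnel fixture --------------------------------------------------------

funnel_fixture_library <- function() {
  # design labels: cationic? / pharmacophore verdict / unassigned centers
  tab <- rbind(
    c("c1ccccc1",              "benzene",        "0", "-",    "0"),
    c("Oc1ccccc1",             "phenol",         "0", "-",    "0"),
    c("CC(=O)O",               "aceticacid",     "0", "-",    "0"),
    c("c1ccncc1",              "pyridine",       "0", "-",    "0"),
    c("NC(=O)c1ccccc1",        "benzamide",      "0", "-",    "0"),
    c("CC(=O)[O-].[Na+]",      "sodiumacetate",  "0", "-",    "0"),
    c("C[N+](C)(C)C",          "tma",            "1", "pass", "0"),
    c("CN(C)C",                "trimethylamine", "1", "pass", "0"),
    c("CNC",                   "dimethylamine",  "1", "pass", "0"),
    c("CCN",                   "ethylamine",     "1", "pass", "0"),
    c("C1CCNC1",               "pyrrolidine",    "1", "pass", "0"),
    c("C1CCNCC1",              "piperidine",     "1", "pass", "0"),
    c("CN1CCCC1",              "nmp",            "1", "pass", "0"),
    c("CC(C)N",                "isopropylamine", "1", "pass", "0"),
    c("CCC(C)N",               "secbutylamine",  "1", "pass", "1"),
    c("CC(C)C(C)N",            "methylbutamine", "1", "pass", "1"),
    c("CC(O)C(C)N",            "aminobutanol",   "1", "pass", "2"),
    c("CC(N)CO",               "alaninol",       "1", "pass", "1"),
    c("C[N+](C)(C)Cc1ccc2ccccc2c1", "naphtma",   "1", "fail", "0"),
    c("C[N+](C)(C)Cc1c2ccccc2cc2ccccc12", "anthratma", "1", "fail", "0"))
  data.frame(smiles = tab[, 1], id = tab[, 2],
             cationic = tab[, 3] == "1", pharm = tab[, 4],
             n_centers = as.integer(tab[, 5]), stringsAsFactors = FALSE)
}

#' Build the bundled 20-ligand funnel fixture
#'
#' Writes a complete, self-contained funnel input set: a 20-ligand SMILES
#' library with designed per-stage outcomes (6 non-cationic, 12 compact
#' cations that fit the sealed fixture cavity, 2 rigid oversized cations
#' that provably cannot fit), a sealed-cavity pharmacophore query, a
#' sparse probe pocket used as the pose-filter receptor, a planted pose
#' file for the expected stereoisomers and a novelty reference set
#' containing one library member (pyrrolidine). The returned `expected`
#' list holds the designed stage-by-stage bookkeeping.
#'
#' @param dir output directory.
#' @param seed fixture seed (default 7).
#' @return list with `config` (a ready [funnel_config()]), `expected`
#'   (stage counts and tables) and the file paths.
#' @export
make_funnel_fixture <- function(dir, seed = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- funnel_fixture_library()
  lib_path <- file.path(dir, "library.smi")
  writeLines(paste(lib$smiles, lib$id), lib_path)

  # sealed cavity for provable pharmacophore verdicts
  pharm_spec <- fixture_spec(seed = seed, cavity_radius = 4.2,
                             sealed = TRUE, include_probe = FALSE)
  pharm_pocket <- make_toy_pocket(pharm_spec)
  query_path <- file.path(dir, "query.txt")
  write_query(pharm_pocket$query, query_path)

  # sparse probe pocket as the pose-filter receptor
  pose_spec <- fixture_spec(seed = seed + 100, cavity_radius = 6,
                            n_shell = 80, include_probe = TRUE,
                            n_poses = 0, n_hbond = 0)
  pose_pocket <- make_toy_pocket(pose_spec, dir = dir)

  # expected stereoisomer ids of the pharmacophore survivors
  passers <- lib[lib$pharm == "pass", , drop = FALSE]
  iso_ids <- unlist(lapply(seq_len(nrow(passers)), function(i) {
    k <- passers$n_centers[i]
    if (k == 0) passers$id[i]
    else paste0(passers$id[i], "#", seq_len(2^k))
  }))

  # planted poses for ten of those stereoisomers, two poses each
  pose_ids <- iso_ids[c(1:8, 11, 13)]
  pose_dists <- c(4.6, 5.0, 4.8, 5.2, 4.7, 5.9, 4.9, 6.1, 5.1, 5.3,
                  4.5, 6.3, 5.4, 5.0, 4.4, 5.6, 5.2, 6.0, 4.8, 5.7)
  model <- pose_pocket$model
  cd2 <- as.numeric(get_atom(model, atom_address("A", 145, "CD2"))[
    1, c("x", "y", "z")])
  rec_heavy <- heavy_atoms(model)
  rec_xyz <- coords_of(rec_heavy)
  dirs <- fibonacci_sphere(1001)
  place <- function(dist) {
    for (k in seq_len(nrow(dirs))) {
      u <- dirs[k, ]
      n_pos <- cd2 + dist * u
      if (vnorm(n_pos) > pose_spec$cavity_radius - 2.7) next
      fr <- frame_of(u)
      pts <- rbind(n_pos, n_pos + 1.49 * fr$v,
                   n_pos + 1.49 * unitv(-0.5 * fr$v + 0.86 * fr$w))
      lim2 <- outer(vdw_radius(c("N", "C", "C")),
                    vdw_radius(rec_heavy$element),
                    function(a, b) (0.75 * (a + b))^2)
      if (all(cross_dist2(pts, rec_xyz) > lim2)) {
        acc <- rec_xyz[rec_heavy$element == "O", , drop = FALSE]
        d2a <- colSums((t(acc) - n_pos)^2)
        away <- unitv(n_pos - acc[which.min(d2a), ])
        return(rbind(pts, n_pos + 1.01 * away))
      }
    }
    stop("funnel fixture: cannot place pose at ", dist)
  }
  ids <- character(); coords_list <- list(); truth <- list()
  for (i in seq_along(pose_ids)) {
    for (p in 1:2) {
      d <- pose_dists[(i - 1) * 2 + p]
      nm <- paste0(pose_ids[i], if (p == 2) "" else "", "")
      ids <- c(ids, pose_ids[i])
      coords_list[[length(coords_list) + 1]] <- round(place(d), 4)
      truth[[length(truth) + 1]] <- data.frame(
        id = pose_ids[i], pose = p, dist = d,
        keep = d <= 5.5 + 1e-9, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  scores <- round(38 - 0.13 * seq_along(ids), 4)
  poses_path <- file.path(dir, "poses.sdf")
  write_ligands_sdf(lapply(ids, pose_ligand_record), poses_path,
                    coords_list = coords_list,
                    data_list = lapply(scores, function(s)
                      list(SCORE = sprintf("%.4f", s))))

  refs_path <- file.path(dir, "refs.smi")
  writeLines(c("C1CCNC1 ref_pyrrolidine",
               "Cn1cnc2c1c(=O)n(C)c(=O)n2C ref_caffeine",
               "c1ccc2[nH]ccc2c1 ref_indole"), refs_path)

  # designed bookkeeping
  truth$score <- scores
  kept <- truth[truth$keep, , drop = FALSE]
  # per-ligand cap 3 never binds (2 poses per ligand); top 10 by score
  kept <- kept[order(-kept$score, kept$id), , drop = FALSE]
  top <- utils::head(kept, 10)
  shortlist_ligands <- unique(sub("#.*$", "", top$id))
  expected <- list(
    standardize = c(20, 20),
    cationic_selection = c(20, 14),
    pharmacophore_screen = c(14, 12),
    stereo_enumeration = c(12, 18),
    pose_ingestion = c(nrow(truth), nrow(truth)),
    post_filters = c(nrow(truth), sum(truth$keep)),
    shortlist = c(sum(truth$keep), 10),
    novelty_candidates = length(shortlist_ligands),
    novelty_known = "pyrrolidine" %in% shortlist_ligands,
    pose_truth = truth,
    iso_ids = iso_ids)

  config <- funnel_config(
    library = lib_path, query_file = query_path,
    receptor_pdb = pose_pocket$pdb, receptor_chains = c("A", "S"),
    poses = list(path = poses_path, format = "sdf",
                 score_field = "SCORE"),
    novelty_refs = refs_path, novelty_threshold = 0.40,
    n_conformers = 3, match_spacing = 0.5, match_rot_deg = 45,
    shortlist_top_n = 10, per_ligand_cap = 3,
    out_dir = file.path(dir, "out"), seed = seed)
  list(config = config, expected = expected, library = lib,
       paths = list(library = lib_path, query = query_path,
                    poses = poses_path, refs = refs_path,
                    pocket = pose_pocket$pdb))
}
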