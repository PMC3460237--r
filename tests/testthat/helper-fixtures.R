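# shared helpers: tiny synthetic inputs and independent brute-force oracles

pdb_line <- function(serial, elety, resid, chain, resno, x, y, z,
                     het = FALSE, alt = "", occ = 1.0, element = NULL) {
  if (is.null(element)) element <- substr(elety, 1, 1)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, elety, alt, resid, chain,
          resno, x, y, z, occ, 0.0, toupper(element))
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a 10-residue poly-ALA-like CA trace along a gentle helix
make_ca_model <- function(chain = "A", n = 10, seq3 = NULL, offset = 0,
                          jitter = 0, seed = 1) {
  if (is.null(seq3)) seq3 <- rep("ALA", n)
  t <- seq_len(n)
  xyz <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
  if (jitter > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(rnorm(3 * n, sd = jitter), ncol = 3)
  }
  lines <- vapply(seq_len(n), function(i)
    pdb_line(i, "CA", seq3[i], chain, i + offset, xyz[i, 1], xyz[i, 2],
             xyz[i, 3], element = "C"), character(1))
  read_structure(write_pdb_fixture(lines))
}

# independent grid-search superposition oracle: best RMSD over an Euler
# rotation grid with centroid-matching translation
grid_superpose_rmsd <- function(X, Y, step_deg = 12) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  angs <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  half <- seq(0, pi, by = step_deg * pi / 180)
  best <- Inf
  for (a in angs) for (b in half) for (g in angs) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
    R <- Rz1 %*% Ry %*% Rz2
    r <- sqrt(mean(rowSums((tcrossprod(Xc, R) - Yc)^2)))
    if (r < best) best <- r
  }
  best
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  ax <- rnorm(3)
  R <- pocketfunnel:::quat_to_rot(q)
  list(R = R, t = runif(3, -20, 20))
}

apply_rigid <- function(xyz, tr) {
  sweep(tcrossprod(as.matrix(xyz), tr$R), 2, tr$t, "+")
}

transform_model <- function(model, tr) {
  xyz <- apply_rigid(as.matrix(model$atoms[, c("x", "y", "z")]), tr)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# independent all-pairs hydrogen-bond scan (plain loops, no shared code)
brute_hbond_scan <- function(pose, receptor, max_da = 3.5,
                             min_angle = 120) {
  lig <- pose$atoms; rec <- receptor$atoms
  ang <- function(d, h, a) {
    v1 <- d - h; v2 <- a - h
    acos(max(-1, min(1, sum(v1 * v2) /
                       sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  p <- function(df, i) as.numeric(df[i, c("x", "y", "z")])
  found <- 0
  # ligand donor -> receptor acceptor
  for (bi in seq_len(nrow(pose$bonds))) {
    for (sw in 1:2) {
      hB <- if (sw == 1) pose$bonds$a2[bi] else pose$bonds$a1[bi]
      dB <- if (sw == 1) pose$bonds$a1[bi] else pose$bonds$a2[bi]
      if (lig$element[hB] != "H" || !lig$element[dB] %in% c("N", "O")) next
      for (ai in seq_len(nrow(rec))) {
        is_acc <- rec$element[ai] == "O"
        if (!is_acc && rec$element[ai] == "N") {
          d2h <- (rec$x - rec$x[ai])^2 + (rec$y - rec$y[ai])^2 +
            (rec$z - rec$z[ai])^2
          is_acc <- !any(rec$element == "H" & d2h < 1.3^2)
        }
        if (!is_acc) next
        dd <- sqrt(sum((p(lig, dB) - p(rec, ai))^2))
        if (dd <= max_da &&
            ang(p(lig, dB), p(lig, hB), p(rec, ai)) >= min_angle)
          found <- found + 1
      }
    }
  }
  # receptor donor -> ligand acceptor
  lig_has_h <- rep(FALSE, nrow(lig))
  for (bi in seq_len(nrow(pose$bonds))) {
    a1 <- pose$bonds$a1[bi]; a2 <- pose$bonds$a2[bi]
    if (lig$element[a1] == "H") lig_has_h[a2] <- TRUE
    if (lig$element[a2] == "H") lig_has_h[a1] <- TRUE
  }
  for (hi in which(rec$element == "H")) {
    d2 <- (rec$x - rec$x[hi])^2 + (rec$y - rec$y[hi])^2 +
      (rec$z - rec$z[hi])^2
    cand <- which(rec$element %in% c("N", "O") & d2 < 1.3^2)
    if (!length(cand)) next
    di <- cand[which.min(d2[cand])]
    for (ai in seq_len(nrow(lig))) {
      ok <- lig$element[ai] == "O" ||
        (lig$element[ai] == "N" && !lig_has_h[ai] && lig$charge[ai] <= 0)
      if (!ok) next
      dd <- sqrt(sum((p(rec, di) - p(lig, ai))^2))
      if (dd <= max_da &&
          ang(p(rec, di), p(rec, hi), p(lig, ai)) >= min_angle)
        found <- found + 1
    }
  }
  found
}

# small pool of parseable SMILES for property-style tests
smiles_pool <- c(
  "CCO", "CCN", "CCC", "CCCC", "c1ccccc1", "Cc1ccccc1", "c1ccncc1",
  "CC(=O)O", "CC(=O)N", "C1CCNCC1", "C1CCNC1", "CC(C)N", "C[N+](C)(C)C",
  "OCC(O)CO", "CC(N)C(=O)O", "c1cc[nH]c1", "CSC", "CC#N", "ClCCCl",
  "c1ccc2ccccc2c1")
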