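#' Geometric hydrogen-bond detection
#'
#' A hydrogen bond is recorded for every donor-acceptor pair, in both
#' directions (ligand donor -> receptor acceptor and receptor donor ->
#' ligand acceptor), whose donor-acceptor distance is at most
#' `hbond_max_da` and whose D-H...A angle (at the hydrogen) is at least
#' `hbond_min_angle`. Hits on the named receptor targets (W145 backbone
#' carbonyl, Y91 hydroxyl, W53 indole N-H, Q114 side-chain amide by
#' default) are flagged specially.
#'
#' @param pose a `Pose` with explicit polar hydrogens in its atom table.
#' @param receptor prepared `StructureModel` (polar hydrogens placed).
#' @param cfg a `FilterConfig`.
#' @return data frame: donor, hydrogen, acceptor, direction, distance (D-A,
#'   Angstrom), angle (degrees), target (named-target label or NA).
#' @export
detect_hbonds <- function(pose, receptor, cfg = filter_config()) {
  lig <- pose$atoms
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  rec <- receptor$atoms
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])

  # --- ligand donors: N/O with an explicitly bonded H
  lig_donors <- list()
  if (nrow(pose$bonds)) {
    for (bi in seq_len(nrow(pose$bonds))) {
      a1 <- pose$bonds$a1[bi]; a2 <- pose$bonds$a2[bi]
      if (lig$element[a1] == "H" && lig$element[a2] %in% c("N", "O"))
        lig_donors[[length(lig_donors) + 1]] <- c(d = a2, h = a1)
      if (lig$element[a2] == "H" && lig$element[a1] %in% c("N", "O"))
        lig_donors[[length(lig_donors) + 1]] <- c(d = a1, h = a2)
    }
  }
  # --- ligand acceptors: O always; N without bonded H and not cationic
  has_h <- rep(FALSE, nrow(lig))
  for (dn in lig_donors) has_h[dn["d"]] <- TRUE
  lig_acc <- which(lig$element == "O" |
                     (lig$element == "N" & !has_h & lig$charge <= 0))

  # --- receptor donors: placed polar H rows; parent = nearest N/O
  rec_h <- which(rec$element == "H")
  rec_no <- which(rec$element %in% c("N", "O"))
  rec_donors <- list()
  for (h in rec_h) {
    d2 <- colSums((t(rec_xyz[rec_no, , drop = FALSE]) - rec_xyz[h, ])^2)
    p <- rec_no[which.min(d2)]
    if (min(d2) < 1.3^2)
      rec_donors[[length(rec_donors) + 1]] <- c(d = p, h = h)
  }
  # --- receptor acceptors: all O; N without attached H
  rec_don_parents <- vapply(rec_donors, `[[`, numeric(1), "d")
  rec_acc <- which(rec$element == "O" |
                     (rec$element == "N" &
                        !(seq_len(nrow(rec)) %in% rec_don_parents)))

  target_label <- function(rows) {
    tg <- cfg$hbond_targets
    vapply(rows, function(r) {
      hit <- which(tg$resno == rec$resno[r] & tg$atom == rec$elety[r])
      if (length(hit)) tg$name[hit[1]] else NA_character_
    }, character(1))
  }

  angle_deg <- function(d, h, a) {
    v1 <- d - h; v2 <- a - h
    cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }

  out <- list()
  add <- function(donor, hydrogen, acceptor, direction, dist, ang, target) {
    out[[length(out) + 1]] <<- data.frame(
      donor = donor, hydrogen = hydrogen, acceptor = acceptor,
      direction = direction, distance = dist, angle = ang,
      target = target, stringsAsFactors = FALSE)
  }
  # ligand -> receptor
  for (dn in lig_donors) {
    for (a in rec_acc) {
      dist <- vnorm(lig_xyz[dn["d"], ] - rec_xyz[a, ])
      if (dist > cfg$hbond_max_da + 1e-9) next
      ang <- angle_deg(lig_xyz[dn["d"], ], lig_xyz[dn["h"], ], rec_xyz[a, ])
      if (ang < cfg$hbond_min_angle - 1e-9) next
      add(paste0("lig/", dn["d"]), paste0("lig/", dn["h"]),
          paste0(rec$chain[a], rec$resno[a], "/", rec$elety[a]),
          "ligand_donor", dist, ang, target_label(a))
    }
  }
  # receptor -> ligand
  for (dn in rec_donors) {
    for (a in lig_acc) {
      dist <- vnorm(rec_xyz[dn["d"], ] - lig_xyz[a, ])
      if (dist > cfg$hbond_max_da + 1e-9) next
      ang <- angle_deg(rec_xyz[dn["d"], ], rec_xyz[dn["h"], ], lig_xyz[a, ])
      if (ang < cfg$hbond_min_angle - 1e-9) next
      add(paste0(rec$chain[dn["d"]], rec$resno[dn["d"]], "/",
                 rec$elety[dn["d"]]),
          paste0(rec$chain[dn["h"]], rec$resno[dn["h"]], "/",
                 rec$elety[dn["h"]]),
          paste0("lig/", a), "receptor_donor", dist, ang,
          target_label(dn["d"]))
    }
  }
  if (!length(out))
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), direction = character(),
                      distance = numeric(), angle = numeric(),
                      target = character()))
  do.call(rbind, out)
}
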