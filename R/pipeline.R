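#' Funnel orchestration
#'
#' Runs the full hierarchical screen: standardization, cationic
#' preselection, conformer generation with pharmacophore screening, stereo
#' enumeration, export for external docking, ingestion of scored poses,
#' post-docking filters, ranking/shortlisting and the novelty screen.
#' Every stage appends a manifest row (counts in its unit) and every
#' dropped item gets a logged reason, so `input = output + rejections`
#' holds stage by stage. With a fixed seed the whole run, including all
#' written outputs, is byte-reproducible; wall-clock timestamps go to the
#' log stream only, never into the manifest.
#'
#' @name pipeline
NULL

#' Assemble a funnel configuration
#'
#' @param library path to the ligand library (SMILES or SDF).
#' @param query_file path to a serialized pharmacophore query
#'   ([write_query()]), or NULL if `complex` is given.
#' @param complex optional list(`pdb`, `keep_chains`, `ligand_resname`,
#'   `cationic_elety`) from which the query is built.
#' @param receptor_pdb receptor used for post-docking filters (PDB path).
#' @param receptor_chains chains kept when preparing that receptor.
#' @param poses optional list(`path`, `format`, `score_field`); when NULL
#'   the funnel stops after exporting the docking input.
#' @param filters named list of [filter_config()] overrides.
#' @param novelty_refs path to a reference SMILES file for the novelty
#'   screen (NULL disables the stage).
#' @param novelty_threshold known/novel Tanimoto threshold (default 0.40).
#' @param stereo_max_centers cap for stereo enumeration (default 5).
#' @param n_conformers,conf_dedup_rmsd conformer generation settings.
#' @param match_spacing,match_rot_deg pharmacophore search resolution.
#' @param shortlist_top_n,per_ligand_cap ranking settings.
#' @param out_dir output directory (created).
#' @param seed integer seed used for every stochastic component.
#' @return a `funnel_config` list.
#' @export
funnel_config <- function(library, query_file = NULL, complex = NULL,
                          receptor_pdb = NULL, receptor_chains = NULL,
                          poses = NULL, filters = list(),
                          novelty_refs = NULL, novelty_threshold = 0.40,
                          stereo_max_centers = 5, n_conformers = 3,
                          conf_dedup_rmsd = 0.5, match_spacing = 0.5,
                          match_rot_deg = 30, shortlist_top_n = 400,
                          per_ligand_cap = 3, out_dir = tempfile("funnel"),
                          seed = 1L) {
  structure(as.list(environment()), class = "funnel_config")
}

#' Load a funnel configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [funnel_config()].
#' @return a `funnel_config`.
#' @export
read_funnel_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  do.call(funnel_config, cfg)
}

manifest_row <- function(stage, unit, n_in, n_out, params = "") {
  data.frame(stage = stage, unit = unit, n_in = n_in, n_out = n_out,
             params = params, stringsAsFactors = FALSE)
}

#' Run the hierarchical screening funnel
#'
#' @param config a `funnel_config`.
#' @param verbose log stage progress to stderr.
#' @return a `FunnelManifest`: list with `manifest` (stage table),
#'   `rejections`, per-stage outputs and the output directory. All tables
#'   are also written under `config$out_dir`.
#' @export
run_funnel <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "funnel_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); rejections <- list()
  say <- function(...) if (verbose) message("[funnel] ", ...)
  add_rej <- function(df) if (nrow(df))
    rejections[[length(rejections) + 1]] <<- df
  finish <- function(result) {
    result$manifest <- do.call(rbind, manifest)
    result$rejections <- if (length(rejections))
      do.call(rbind, rejections) else
        data.frame(id = character(), stage = character(),
                   reason = character())
    write_tsv(result$manifest, file.path(config$out_dir, "manifest.tsv"))
    write_tsv(result$rejections,
              file.path(config$out_dir, "rejections.tsv"))
    class(result) <- "FunnelManifest"
    result
  }

  # --- stage 1: parse + standardize -----------------------------------
  say("standardize")
  lib <- read_ligands(config$library)
  n_in <- length(lib$records) + nrow(lib$rejected)
  add_rej(lib$rejected)
  std <- lapply(lib$records, function(r)
    tryCatch(standardize(r), error = function(e) NULL))
  failed <- vapply(std, is.null, logical(1))
  for (i in which(failed))
    add_rej(data.frame(id = lib$records[[i]]$id, stage = "standardize",
                       reason = "standardization failed"))
  std <- std[!failed]
  manifest[[1]] <- manifest_row("standardize", "ligands", n_in, length(std))

  # --- stage 2: cationic preselection ---------------------------------
  say("cationic selection")
  is_cat <- vapply(std, function(r) length(r$cationic) > 0, logical(1))
  for (i in which(!is_cat))
    add_rej(data.frame(id = std[[i]]$id, stage = "cationic_selection",
                       reason = "no cationic nitrogen"))
  cations <- std[is_cat]
  manifest[[2]] <- manifest_row("cationic_selection", "ligands",
                                length(std), length(cations))

  # --- stage 3: conformers + pharmacophore screen ---------------------
  say("pharmacophore screen")
  query <- if (!is.null(config$query_file)) read_query(config$query_file)
  else if (!is.null(config$complex)) query_from_complex(config$complex)
  else stop("config needs query_file or complex")
  passed <- list(); match_rows <- list()
  for (rec in cations) {
    cs <- tryCatch(
      generate_conformers(rec, n_max = config$n_conformers,
                          dedup_rmsd = config$conf_dedup_rmsd,
                          seed = config$seed),
      error = function(e) NULL)
    if (is.null(cs)) {
      add_rej(data.frame(id = rec$id, stage = "pharmacophore_screen",
                         reason = "3D embedding failed"))
      next
    }
    sc <- screen_library(list(cs), query, spacing = config$match_spacing,
                         rot_deg = config$match_rot_deg)
    match_rows[[length(match_rows) + 1]] <- sc$results
    if (length(sc$passed)) passed[[length(passed) + 1]] <- rec
    else add_rej(data.frame(id = rec$id, stage = "pharmacophore_screen",
                            reason = "no conformer matches the query"))
  }
  manifest[[3]] <- manifest_row(
    "pharmacophore_screen", "ligands", length(cations), length(passed),
    paste0("spacing=", config$match_spacing, ",rot=", config$match_rot_deg))
  if (length(match_rows))
    write_tsv(do.call(rbind, match_rows),
              file.path(config$out_dir, "pharmacophore_matches.tsv"))

  # --- stage 4: stereoisomer enumeration ------------------------------
  say("stereo enumeration")
  isomers <- list()
  for (rec in passed) {
    iso <- enumerate_stereoisomers(rec, max_centers =
                                     config$stereo_max_centers)
    isomers <- c(isomers, iso)
  }
  manifest[[4]] <- manifest_row("stereo_enumeration", "stereoisomers",
                                length(passed), length(isomers),
                                paste0("max_centers=",
                                       config$stereo_max_centers))
  # export docking input (first conformer per isomer)
  if (length(isomers)) {
    coords <- lapply(isomers, function(r)
      tryCatch(embed_mol3d(r, seed = config$seed), error = function(e)
        matrix(0, sum(r$atoms$element != "H"), 3)))
    hrecs <- isomers
    write_ligands_sdf(hrecs, file.path(config$out_dir,
                                       "docking_input.sdf"),
                      coords_list = coords)
  }
  result <- list(standardized = std, cationic = cations,
                 pharmacophore_passed = passed, stereoisomers = isomers,
                 query = query, out_dir = config$out_dir,
                 seed = config$seed)

  if (is.null(config$poses)) return(finish(result))

  # --- stage 5: pose ingestion ----------------------------------------
  say("pose ingestion")
  receptor <- prepare_receptor(read_structure(config$receptor_pdb),
                               keep_chains = config$receptor_chains %||%
                                 NULL)
  pl <- load_poses(config$poses$path,
                   format = config$poses$format %||% "sdf",
                   score_field = config$poses$score_field %||% "SCORE")
  n_pose_in <- length(pl$poses) + nrow(pl$skipped)
  if (nrow(pl$skipped))
    add_rej(data.frame(id = pl$skipped$id, stage = "pose_ingestion",
                       reason = pl$skipped$reason))
  manifest[[5]] <- manifest_row("pose_ingestion", "poses", n_pose_in,
                                length(pl$poses))

  # --- stage 6: post-docking filters ----------------------------------
  say("post-docking filters")
  fcfg <- do.call(filter_config, config$filters)
  fl <- apply_filters(pl$poses, receptor, fcfg)
  for (i in which(!fl$report$kept)) {
    r <- fl$report[i, ]
    reason <- if (!r$capi_pass) "cation-pi distance above cutoff"
    else if (!r$containment_pass) "outside binding pocket"
    else "steric clash"
    add_rej(data.frame(id = r$pose, stage = "post_filters",
                       reason = reason))
  }
  manifest[[6]] <- manifest_row(
    "post_filters", "poses", length(pl$poses), length(fl$kept),
    paste0("capi<=", fcfg$capi_max, ",contain=", fcfg$containment_radius,
           "+", fcfg$containment_margin, ",clash=", fcfg$clash_scale))
  write_tsv(fl$report, file.path(config$out_dir, "pose_report.tsv"))

  # --- stage 7: ranking + shortlist -----------------------------------
  say("shortlist")
  shortlist <- rank_and_shortlist(fl$kept, fl$report,
                                  top_n = config$shortlist_top_n,
                                  per_ligand_cap = config$per_ligand_cap)
  kept_ids <- fl$report$pose[fl$report$kept]
  for (pid in setdiff(kept_ids, shortlist$pose))
    add_rej(data.frame(id = pid, stage = "shortlist",
                       reason = "below shortlist rank cutoff"))
  manifest[[7]] <- manifest_row(
    "shortlist", "poses", length(fl$kept), nrow(shortlist),
    paste0("top_n=", config$shortlist_top_n, ",cap=",
           config$per_ligand_cap))
  write_tsv(shortlist, file.path(config$out_dir, "shortlist.tsv"))
  result$shortlist <- shortlist
  result$pose_report <- fl$report

  # --- stage 8: novelty screen ----------------------------------------
  if (!is.null(config$novelty_refs)) {
    say("novelty screen")
    cand_ids <- unique(shortlist$ligand)
    cand <- std[vapply(std, function(r) r$id %in% cand_ids, logical(1))]
    refs <- read_ligands(config$novelty_refs)$records
    refs <- lapply(refs, standardize)
    nv <- novelty_screen(cand, refs, threshold = config$novelty_threshold)
    for (i in which(nv$classified_known))
      add_rej(data.frame(id = nv$query[i], stage = "novelty_screen",
                         reason = paste0("similar to known ligand ",
                                         nv$best_reference[i])))
    manifest[[8]] <- manifest_row(
      "novelty_screen", "ligands", length(cand),
      sum(!nv$classified_known),
      paste0("threshold=", config$novelty_threshold))
    write_tsv(nv, file.path(config$out_dir, "novelty.tsv"))
    result$novelty <- nv
  }
  finish(result)
}

query_from_complex <- function(complex) {
  model <- read_structure(complex$pdb)
  lig <- model$atoms[model$atoms$het &
                       model$atoms$resid == complex$ligand_resname, ,
                     drop = FALSE]
  if (!nrow(lig)) stop("bound ligand ", complex$ligand_resname,
                       " not found in ", complex$pdb)
  receptor <- prepare_receptor(model, keep_chains =
                                 complex$keep_chains %||% model$chains)
  cat_idx <- which(lig$elety == (complex$cationic_elety %||% "N1"))
  if (!length(cat_idx)) stop("cationic ligand atom not found")
  build_query(receptor,
              data.frame(element = lig$element, x = lig$x, y = lig$y,
                         z = lig$z),
              cationic_atom = cat_idx[1],
              shell_cutoff = complex$shell_cutoff %||% 7.0,
              ev_radius = complex$ev_radius %||% 0.8,
              feature_radius = complex$feature_radius %||% 2.5)
}

#' @export
print.FunnelManifest <- function(x, ...) {
  cat("FunnelManifest (", nrow(x$manifest), " stages):\n", sep = "")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Write a human-readable funnel report
#'
#' Writes the manifest as TSV plus a text summary with the
#' stereoisomers-per-compound expansion ratio where the unit switches from
#' ligands to stereoisomers.
#'
#' @param manifest a `FunnelManifest` or a bare manifest data frame (e.g.
#'   a pre-filled record of an external campaign).
#' @param out output path stem; writes `<out>.tsv` and `<out>.txt`.
#' @return list with `table` and `text` (invisibly).
#' @export
funnel_report <- function(manifest, out = NULL) {
  tab <- if (inherits(manifest, "FunnelManifest")) manifest$manifest
  else manifest
  stopifnot(all(c("stage", "unit", "n_in", "n_out") %in% names(tab)))
  lines <- c("Hierarchical screening funnel", strrep("-", 32))
  for (i in seq_len(nrow(tab))) {
    ln <- sprintf("%-22s %8d -> %8d %s", tab$stage[i], tab$n_in[i],
                  tab$n_out[i], tab$unit[i])
    if (tab$unit[i] == "stereoisomers" && tab$n_in[i] > 0) {
      ln <- paste0(ln, sprintf("  (%.2f stereoisomers/compound)",
                               tab$n_out[i] / tab$n_in[i]))
    }
    lines <- c(lines, ln)
  }
  if (!is.null(out)) {
    write_tsv(tab[, c("stage", "unit", "n_in", "n_out",
                      intersect("params", names(tab)))],
              paste0(out, ".tsv"))
    writeLines(lines, paste0(out, ".txt"))
  }
  invisible(list(table = tab, text = lines))
}
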