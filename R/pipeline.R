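# Pipeline stage runners: thin orchestration over the module functions,
# reading and writing files, with a config echo log per output directory.
# The same functions back the command-line wrapper in inst/cli/.

write_run_log <- function(out_dir, stage, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("stage: %s", stage),
             sprintf("phoreseed version: %s",
                     as.character(utils::packageVersion("phoreseed"))),
             map_chr(names(config), function(k)
               sprintf("%s: %s", k, paste(format(config[[k]]), collapse = " "))))
  writeLines(lines, file.path(out_dir, paste0(stage, ".log")))
}

#' Generate the synthetic study fixtures on disk
#'
#' Writes a toy complex (`complex.pdb`), one multi-conformer SDF per
#' library ligand (`ligands/`), and a ground-truth table
#' (`truth.tsv`).
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @param n_actives,n_inactives Library composition.
#' @param n_shell_atoms Receptor size of the toy complex.
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, n_actives = 15L,
                         n_inactives = 10L, n_shell_atoms = 60L) {
  dir.create(file.path(out_dir, "ligands"), recursive = TRUE,
             showWarnings = FALSE)
  cx <- make_toy_complex(seed, n_shell_atoms)
  pdb_path <- file.path(out_dir, "complex.pdb")
  write_complex(cx, pdb_path)
  model <- build_model(cx)
  lib <- make_labeled_library(model, n_actives, n_inactives, seed)
  sdf_paths <- map_chr(lib, function(ens) {
    p <- file.path(out_dir, "ligands", paste0(ens$id, ".sdf"))
    write_ligand_ensemble(ens, p)
    p
  })
  truth <- bind_rows(map(lib, function(ens)
    mutate(attr(ens, "truth"), ligand_id = ens$id, activity = ens$activity)))
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(truth[, c("ligand_id", "activity", "conformer", "planted")],
                   truth_path)
  write_run_log(out_dir, "simulate",
                list(seed = seed, n_actives = n_actives,
                     n_inactives = n_inactives,
                     n_shell_atoms = n_shell_atoms))
  invisible(list(complex = pdb_path, ligands = sdf_paths, truth = truth_path))
}

#' Build a pharmacophore model from complex files
#'
#' @param complex_paths PDB paths (first complex seeds the features; the
#'   volume union runs over all).
#' @param out_path Output JSON path.
#' @param feature_spec,radius_map,contact_cutoff,ring_radius See
#'   [build_model()].
#' @return The built [pharmacophore()], invisibly.
#' @export
run_build <- function(complex_paths, out_path,
                      feature_spec = default_feature_spec(),
                      radius_map = radius_map_final(),
                      contact_cutoff = 3.0, ring_radius = 2.5) {
  complexes <- map(complex_paths, read_complex)
  model <- build_model(complexes, feature_spec, radius_map, contact_cutoff,
                       ring_radius)
  write_pharmacophore(model, out_path)
  write_run_log(dirname(out_path), "build",
                list(complexes = complex_paths,
                     radius_map = unclass(radius_map),
                     contact_cutoff = contact_cutoff,
                     ring_radius = ring_radius))
  invisible(model)
}

#' Screen SDF ensembles against a model file
#'
#' @param model_path Pharmacophore JSON.
#' @param sdf_paths Multi-conformer SDF files.
#' @param out_path Output TSV report.
#' @param dE_cutoff Energy cutoff, kcal/mol.
#' @param energy_tag,energy_unit SDF energy field and unit.
#' @return The screen-row tibble, invisibly.
#' @export
run_screen <- function(model_path, sdf_paths, out_path, dE_cutoff = 4.0,
                       energy_tag = "rel_energy",
                       energy_unit = "kcal/mol") {
  if (!file.exists(model_path))
    abort(paste0("pharmacophore file not found: ", model_path))
  model <- read_pharmacophore(model_path)
  ensembles <- map(sdf_paths, function(p) {
    act <- sdf_activity_label(p)
    read_ligand_ensemble(p, energy_tag, energy_unit, activity = act)
  })
  rows <- screen_library(model, ensembles, dE_cutoff)
  write_screen_report(rows, out_path)
  write_run_log(dirname(out_path), "screen",
                list(model = model_path, n_ligands = length(sdf_paths),
                     dE_cutoff = dE_cutoff))
  invisible(rows)
}

# activity travels in an SDF data field when present
sdf_activity_label <- function(path) {
  txt <- readLines(path, warn = FALSE)
  k <- grep("^> *<activity>", txt)
  if (length(k) == 0L) return("unknown")
  val <- trimws(txt[k[1] + 1L])
  if (val %in% c("full", "partial", "inactive")) val else "unknown"
}

#' Tune excluded-volume radii against a labelled library
#'
#' @param model_path Pharmacophore JSON.
#' @param sdf_paths Labelled SDF library (activity data field).
#' @param out_path Output JSON for the tuned model.
#' @param grid List of [radius_map()] candidates.
#' @param dE_cutoff Energy cutoff, kcal/mol.
#' @return The [tune_radii()] result, invisibly.
#' @export
run_tune <- function(model_path, sdf_paths, out_path,
                     grid = default_radius_grid(), dE_cutoff = 4.0) {
  model <- read_pharmacophore(model_path)
  ensembles <- map(sdf_paths, function(p)
    read_ligand_ensemble(p, activity = sdf_activity_label(p)))
  res <- tune_radii(model, ensembles, grid, dE_cutoff)
  tuned <- set_radius_map(model, res$radius_map)
  write_pharmacophore(tuned, out_path)
  readr::write_tsv(res$table, sub("\\.json$", "_grid.tsv", out_path))
  write_run_log(dirname(out_path), "tune",
                list(model = model_path, grid_size = length(grid),
                     best = unclass(res$radius_map), score = res$score))
  invisible(res)
}

#' Default radius-map tuning grid
#'
#' The cross of three aliphatic radii (Bondi 1.2, refined 1.5, and the
#' larger 2.1 used for the D2-style map) with three aromatic/polar radii
#' (1.0, 1.3, 1.9).
#'
#' @return List of nine [radius_map()] objects.
#' @export
default_radius_grid <- function() {
  out <- list()
  for (al in c(1.2, 1.5, 2.1))
    for (ar in c(1.0, 1.3, 1.9))
      out[[length(out) + 1L]] <- radius_map(al, ar, ar)
  out
}

#' Pocket report for a complex file
#'
#' @param complex_path PDB path.
#' @param out_path Output TSV (per-residue table; volume in the log).
#' @param cutoff Pocket cutoff, angstrom.
#' @param helix_refs Optional BW configuration tibble.
#' @param alignment_path,seq_b,index_map Optional conservation inputs.
#' @param grid_spacing,shell Pocket-volume grid parameters.
#' @return The [pocket_report()], invisibly.
#' @export
run_pocket <- function(complex_path, out_path, cutoff = 3.5,
                       helix_refs = NULL, alignment_path = NULL,
                       seq_b = NULL, index_map = identity,
                       grid_spacing = 0.5, shell = 4.0) {
  cx <- read_complex(complex_path)
  cm <- if (!is.null(alignment_path)) read_alignment(alignment_path) else NULL
  rep <- pocket_report(cx, cutoff, helix_refs, cm, seq_b, index_map,
                       grid_spacing, shell)
  out <- mutate(rep$residues, volume = rep$volume)
  readr::write_tsv(out, out_path, na = "")
  write_run_log(dirname(out_path), "pocket",
                list(complex = complex_path, cutoff = cutoff,
                     volume = rep$volume, n_residues = rep$n_residues))
  invisible(rep)
}

#' Compare two pharmacophore models for selectivity analysis
#'
#' Aligns features by label and reports, per position, the kind,
#' essential/optional status in each model and whether the position is
#' conserved (same kind and flag in both); plus the two radius maps.
#'
#' @param model_a,model_b [pharmacophore()] objects or JSON paths.
#' @param out_path Optional TSV for the per-position table.
#' @return List of class `model_comparison`: `positions` tibble,
#'   `radius_maps` tibble, `n_nonconserved`.
#' @export
run_compare <- function(model_a, model_b, out_path = NULL) {
  if (is.character(model_a)) model_a <- read_pharmacophore(model_a)
  if (is.character(model_b)) model_b <- read_pharmacophore(model_b)
  labs <- union(model_a$features$label, model_b$features$label)
  pos <- bind_rows(map(labs, function(l) {
    fa <- model_a$features[model_a$features$label == l, ]
    fb <- model_b$features[model_b$features$label == l, ]
    tibble(label = l,
           kind_a = if (nrow(fa)) fa$kind[1] else NA_character_,
           kind_b = if (nrow(fb)) fb$kind[1] else NA_character_,
           essential_a = if (nrow(fa)) fa$essential[1] else NA,
           essential_b = if (nrow(fb)) fb$essential[1] else NA)
  }))
  pos$conserved <- !is.na(pos$kind_a) & !is.na(pos$kind_b) &
    pos$kind_a == pos$kind_b & pos$essential_a == pos$essential_b
  rm_tbl <- tibble(class = names(radius_map()),
                   model_a = unname(unclass(model_a$radius_map)),
                   model_b = unname(unclass(model_b$radius_map)))
  if (!is.null(out_path)) {
    readr::write_tsv(pos, out_path)
    write_run_log(dirname(out_path), "compare",
                  list(n_positions = nrow(pos),
                       n_nonconserved = sum(!pos$conserved)))
  }
  structure(list(positions = pos, radius_maps = rm_tbl,
                 n_nonconserved = sum(!pos$conserved)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison: %d positions, %d non-conserved>\n",
              nrow(x$positions), x$n_nonconserved))
  invisible(x)
}
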