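# Boundary I/O: PDB complexes, multi-conformer SDF ensembles, pharmacophore
# JSON, screen-report TSV and pairwise alignments.  Units are normalised here
# (angstrom, kcal/mol); nothing downstream converts.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SOL")

new_atom_table <- function(serial, name, element, residue_name, residue_seq,
                           chain, x, y, z, formal_charge = 0L) {
  tibble(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element), residue_name = as.character(residue_name),
    residue_seq = as.integer(residue_seq), chain = as.character(chain),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    is_hydrogen = toupper(as.character(element)) == "H",
    formal_charge = as.integer(formal_charge)
  )
}

#' Construct a receptor-ligand complex
#'
#' A `structure_complex` bundles a receptor atom table, a ligand atom table
#' and the ligand connection table.  Coordinates are Cartesian angstrom;
#' residue numbering is author numbering from the source file.
#'
#' @param receptor,ligand Atom tibbles with columns `serial`, `name`,
#'   `element`, `residue_name`, `residue_seq`, `chain`, `x`, `y`, `z`,
#'   `is_hydrogen`, `formal_charge`.
#' @param ligand_bonds Tibble with columns `a1`, `a2` (1-based indices into
#'   the ligand atom table) and `order` (1, 2, 3 or `"ar"`).
#' @param id Identifier string.
#' @return An object of class `structure_complex`.
#' @export
structure_complex <- function(receptor, ligand, ligand_bonds, id = "complex") {
  receptor <- as_tibble(receptor)
  ligand <- as_tibble(ligand)
  ligand_bonds <- as_tibble(ligand_bonds)
  if (nrow(ligand) == 0L) abort("no ligand residue")
  if (!any(receptor$is_hydrogen)) abort("structure not protonated")
  if (nrow(ligand_bonds) > 0L) {
    idx <- c(ligand_bonds$a1, ligand_bonds$a2)
    if (any(idx < 1L | idx > nrow(ligand)))
      abort("ligand bond indices out of range")
  }
  key <- paste(receptor$chain, receptor$residue_seq, receptor$name)
  if (anyDuplicated(key))
    abort("duplicate (chain, residue_seq, name) among receptor atoms")
  structure(
    list(receptor = receptor, ligand = ligand,
         ligand_bonds = ligand_bonds, id = id),
    class = "structure_complex"
  )
}

#' @export
print.structure_complex <- function(x, ...) {
  cat(sprintf(
    "<structure_complex '%s': %d receptor atoms (%d residues), %d ligand atoms, %d ligand bonds>\n",
    x$id, nrow(x$receptor),
    nrow(distinct(x$receptor, .data$chain, .data$residue_seq)),
    nrow(x$ligand), nrow(x$ligand_bonds)))
  invisible(x)
}

#' Read a protonated receptor-ligand complex from PDB
#'
#' ATOM records become the receptor, HETATM records (waters discarded) the
#' ligand; ligand bond orders are recovered from CONECT multiplicity (a
#' partner listed twice is a double bond).  The receptor must contain at
#' least one hydrogen: models are expected to arrive fully protonated from
#' structure preparation, no protonation engine is applied here.
#'
#' @param path PDB file path.
#' @param ligand_resname Optional residue name selecting the ligand among
#'   HETATM records; defaults to all non-water HETATM records.
#' @return A [structure_complex()].
#' @export
read_complex <- function(path, ligand_resname = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  at$element <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                       trimws(at$elesy),
                       substr(trimws(at$elety), 1, 1))
  at$element <- paste0(toupper(substr(at$element, 1, 1)),
                       tolower(substr(at$element, 2, 2)))
  at$chain[is.na(at$chain)] <- "A"
  at <- at[!(at$resid %in% WATER_RESNAMES), , drop = FALSE]
  is_het <- at$type == "HETATM"
  if (!is.null(ligand_resname)) is_het <- is_het & at$resid == ligand_resname
  if (!any(is_het)) abort("no ligand residue")
  mk <- function(d) new_atom_table(d$eleno, trimws(d$elety), d$element,
                                   d$resid, d$resno, d$chain, d$x, d$y, d$z)
  receptor <- mk(at[!is_het, , drop = FALSE])
  ligand <- mk(at[is_het, , drop = FALSE])
  if (!any(receptor$is_hydrogen)) abort("structure not protonated")
  bonds <- read_conect_bonds(path, ligand$serial)
  structure_complex(receptor, ligand, bonds,
                    id = sub("\\.pdb$", "", basename(path)))
}

# CONECT parsing: multiplicity of a partner encodes bond order (the usual
# convention for small-molecule HET groups).
read_conect_bonds <- function(path, ligand_serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0L)
    return(tibble(a1 = integer(), a2 = integer(), order = integer()))
  pairs <- list()
  for (ln in lines) {
    f <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", ln)),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2L) next
    for (p in f[-1]) pairs[[length(pairs) + 1L]] <- c(f[1], p)
  }
  m <- do.call(rbind, pairs)
  keep <- m[, 1] %in% ligand_serials & m[, 2] %in% ligand_serials
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(tibble(a1 = integer(), a2 = integer(), order = integer()))
  i1 <- match(pmin(m[, 1], m[, 2]), ligand_serials)
  i2 <- match(pmax(m[, 1], m[, 2]), ligand_serials)
  tibble(a1 = i1, a2 = i2) |>
    dplyr::count(.data$a1, .data$a2, name = "mult") |>
    # each bond appears once per direction; CONECT blocks list both atoms
    mutate(order = pmax(1L, as.integer(round(.data$mult / 2)))) |>
    select("a1", "a2", "order") |>
    arrange(.data$a1, .data$a2)
}

#' Write a complex to PDB (with CONECT records for the ligand)
#'
#' @param x A [structure_complex()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_complex <- function(x, path) {
  all_at <- bind_rows(x$receptor, x$ligand)
  type <- c(rep("ATOM", nrow(x$receptor)), rep("HETATM", nrow(x$ligand)))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as_xyz_matrix(all_at))),
    type = type, resno = all_at$residue_seq, resid = all_at$residue_name,
    eleno = all_at$serial, elety = all_at$name, chain = all_at$chain,
    o = rep(1, nrow(all_at)), b = rep(0, nrow(all_at)),
    elesy = all_at$element))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^END", lines)]
  conect <- character()
  if (nrow(x$ligand_bonds) > 0L) {
    adj <- list()
    for (i in seq_len(nrow(x$ligand_bonds))) {
      b <- x$ligand_bonds[i, ]
      s1 <- x$ligand$serial[b$a1]; s2 <- x$ligand$serial[b$a2]
      o <- if (identical(b$order, "ar")) 1L else as.integer(b$order)
      adj[[as.character(s1)]] <- c(adj[[as.character(s1)]], rep(s2, o))
      adj[[as.character(s2)]] <- c(adj[[as.character(s2)]], rep(s1, o))
    }
    conect <- map_chr(names(adj), function(s) {
      paste0("CONECT", paste0(sprintf("%5d", c(as.integer(s), adj[[s]])),
                              collapse = ""))
    })
  }
  writeLines(c(lines, conect, "END"), path)
  invisible(path)
}

#' Construct a multi-conformer ligand ensemble
#'
#' All conformers share one connection table; `rel_energy` is kcal/mol
#' relative to the ensemble minimum (re-based to min = 0 on construction).
#'
#' @param id Ligand identifier.
#' @param atoms Atom tibble (positions ignored; per-conformer coordinates
#'   live in `conformers`).
#' @param bonds Bond tibble (`a1`, `a2`, `order`).
#' @param conformers List of n_atoms x 3 coordinate matrices, angstrom.
#' @param rel_energy Numeric vector, kcal/mol, one value per conformer.
#' @param activity One of `"full"`, `"partial"`, `"inactive"`, `"unknown"`.
#' @return An object of class `ligand_ensemble`.
#' @export
ligand_ensemble <- function(id, atoms, bonds, conformers, rel_energy,
                            activity = "unknown") {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  activity <- match.arg(activity, c("full", "partial", "inactive", "unknown"))
  if (length(conformers) != length(rel_energy))
    abort("one energy per conformer required")
  for (m in conformers) {
    if (!is.matrix(m) || nrow(m) != nrow(atoms) || ncol(m) != 3)
      abort("conformer coordinate block does not match atom count")
  }
  if (length(rel_energy) > 0L) rel_energy <- rel_energy - min(rel_energy)
  structure(
    list(id = id, atoms = atoms, bonds = bonds, conformers = conformers,
         rel_energy = as.numeric(rel_energy), activity = activity),
    class = "ligand_ensemble"
  )
}

#' @export
print.ligand_ensemble <- function(x, ...) {
  cat(sprintf("<ligand_ensemble '%s' (%s): %d atoms, %d conformers, dE 0-%.2f kcal/mol>\n",
              x$id, x$activity, nrow(x$atoms), length(x$conformers),
              if (length(x$rel_energy)) max(x$rel_energy) else 0))
  invisible(x)
}

# per-record "M  CHG" scan; ChemmineR's atom block does not carry these
read_sdf_charges <- function(path) {
  txt <- readLines(path, warn = FALSE)
  rec_id <- cumsum(c(TRUE, head(txt, -1) == "$$$$"))
  chg_lines <- grepl("^M  CHG", txt)
  out <- list()
  for (r in unique(rec_id)) {
    block <- txt[rec_id == r & chg_lines]
    ch <- list()
    for (ln in block) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)),
                                                "\\s+")[[1]]))
      f <- f[!is.na(f)]
      np <- f[1]
      for (k in seq_len(np)) ch[[length(ch) + 1L]] <- f[c(2 * k, 2 * k + 1)]
    }
    out[[r]] <- if (length(ch)) do.call(rbind, ch) else NULL
  }
  out
}

#' Read a multi-conformer ligand ensemble from SDF
#'
#' All records must share one connection table (same elements, same bonds).
#' The named data field supplies per-conformer energies, converted to
#' kcal/mol (kJ/mol divided by 4.184) and re-based so the minimum is zero.
#'
#' @param path Multi-record SDF file.
#' @param energy_tag Name of the SDF data field holding the conformer energy.
#' @param energy_unit `"kcal/mol"` (default) or `"kJ/mol"`.
#' @param activity Activity label to attach.
#' @return A [ligand_ensemble()].
#' @export
read_ligand_ensemble <- function(path, energy_tag = "rel_energy",
                                 energy_unit = c("kcal/mol", "kJ/mol"),
                                 activity = "unknown") {
  energy_unit <- match.arg(energy_unit)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  charges <- read_sdf_charges(path)
  n <- length(sdf)
  if (n == 0L) abort("empty SDF file")
  parse_record <- function(i) {
    s <- sdf[[i]]
    ab <- ChemmineR::atomblock(s)
    bb <- ChemmineR::bondblock(s)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    fc <- integer(length(elements))
    if (!is.null(charges[[i]]))
      fc[charges[[i]][, 1]] <- charges[[i]][, 2]
    db <- ChemmineR::datablock(s)
    if (!(energy_tag %in% names(db))) abort("missing energy property")
    list(elements = elements, coords = coords, bonds = bonds, fc = fc,
         energy = as.numeric(db[[energy_tag]]),
         name = ChemmineR::header(s)[["Molecule_Name"]])
  }
  recs <- map(seq_len(n), parse_record)
  ref <- recs[[1]]
  for (r in recs[-1]) {
    if (!identical(r$elements, ref$elements) ||
        !identical(r$bonds, ref$bonds) || !identical(r$fc, ref$fc))
      abort("ensemble topology mismatch")
  }
  energies <- map_dbl(recs, "energy")
  if (energy_unit == "kJ/mol") energies <- energies / KJ_PER_KCAL
  atoms <- new_atom_table(
    serial = seq_along(ref$elements),
    name = paste0(ref$elements, seq_along(ref$elements)),
    element = ref$elements, residue_name = "LIG", residue_seq = 1L,
    chain = "A", x = ref$coords[, 1], y = ref$coords[, 2],
    z = ref$coords[, 3], formal_charge = ref$fc)
  bonds <- ref$bonds
  bonds$order[bonds$order == 4L] <- "ar"
  ligand_ensemble(
    id = if (nzchar(ref$name)) ref$name else sub("\\.sdf$", "", basename(path)),
    atoms = atoms, bonds = bonds,
    conformers = map(recs, function(r) {
      m <- r$coords; colnames(m) <- c("x", "y", "z"); m
    }),
    rel_energy = energies, activity = activity)
}

#' Write a ligand ensemble as multi-record SDF
#'
#' Emits plain V2000 records (one per conformer) with `M CHG` lines for
#' formal charges and a `rel_energy` data field in kcal/mol.
#'
#' @param x A [ligand_ensemble()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ligand_ensemble <- function(x, path) {
  bonds <- x$bonds
  ord <- ifelse(bonds$order == "ar", 4L, as.integer(bonds$order))
  chg <- which(x$atoms$formal_charge != 0L)
  out <- character()
  for (i in seq_along(x$conformers)) {
    co <- x$conformers[[i]]
    out <- c(out,
      x$id, "  phoreseed", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              nrow(x$atoms), nrow(bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              co[, 1], co[, 2], co[, 3], x$atoms$element),
      if (nrow(bonds)) sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, ord),
      if (length(chg)) paste0("M  CHG", sprintf("%3d", length(chg)),
                              paste0(sprintf("%4d%4d", chg,
                                             x$atoms$formal_charge[chg]),
                                     collapse = "")),
      "M  END",
      ">  <rel_energy>", format(x$rel_energy[i], nsmall = 4), "",
      if (x$activity != "unknown") c(">  <activity>", x$activity, ""),
      "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialise / deserialise a pharmacophore model as JSON
#'
#' Round-trips are identical to within 1e-9 angstrom.
#'
#' @param model A [pharmacophore()].
#' @param path File path.
#' @return `read_pharmacophore` returns a [pharmacophore()];
#'   `write_pharmacophore` returns `path` invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore"))
  obj <- list(
    version = 1L,
    features = purrr::transpose(as.list(model$features)) |>
      map(function(f) list(label = f$label, kind = f$kind,
                           center = c(f$x, f$y, f$z),
                           tolerance = f$tolerance, essential = f$essential)),
    volumes = purrr::transpose(as.list(model$volumes)) |>
      map(function(v) {
        o <- list(center = c(v$x, v$y, v$z), radius = v$radius, mode = v$mode,
                  class = v$class, provenance = v$provenance)
        if (v$mode == "element") o$elements <- as.list(v$elements)
        o
      }),
    radius_map = as.list(model$radius_map),
    ring_radius = model$ring_radius,
    metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$version)) abort("pharmacophore parse error: missing field 'version'")
  fts <- map(obj$features, function(f) {
    if (is.null(f$kind) || !(f$kind %in% POINT_KINDS))
      abort(paste0("pharmacophore parse error: unknown feature kind '",
                   f$kind %||% "<missing>", "'"))
    tibble(label = f$label, kind = f$kind,
           x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
           tolerance = f$tolerance, essential = f$essential)
  })
  vols <- map(obj$volumes, function(v) {
    if (is.null(v$radius)) abort("pharmacophore parse error: missing field 'radius'")
    tibble(x = v$center[[1]], y = v$center[[2]], z = v$center[[3]],
           radius = v$radius, mode = v$mode %||% "all",
           elements = list(as.character(unlist(v$elements))),
           class = v$class %||% NA_character_,
           provenance = v$provenance %||% NA_character_)
  })
  pharmacophore(
    features = if (length(fts)) bind_rows(fts) else empty_features(),
    volumes = if (length(vols)) bind_rows(vols) else empty_volumes(),
    radius_map = radius_map(obj$radius_map$aliphatic, obj$radius_map$aromatic,
                            obj$radius_map$polar),
    ring_radius = obj$ring_radius,
    metadata = obj$metadata %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a Table-1-style screen report as TSV
#'
#' Columns: `ligand_id`, `activity`, `n_conformers`, `n_hits`, `best_dE`,
#' `best_rmsd`; ligands with no hit carry blank `best_dE`/`best_rmsd` cells.
#'
#' @param rows Tibble of screen rows (see [screen_ensemble()]).
#' @param path Output file.
#' @return `path` invisibly; `read_screen_report` returns the tibble.
#' @export
write_screen_report <- function(rows, path) {
  cols <- c("ligand_id", "activity", "n_conformers", "n_hits",
            "best_dE", "best_rmsd")
  if (nrow(rows) == 0L)
    rows <- tibble(ligand_id = character(), activity = character(),
                   n_conformers = integer(), n_hits = integer(),
                   best_dE = numeric(), best_rmsd = numeric())
  readr::write_tsv(rows[, cols], path, na = "")
  invisible(path)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    ligand_id = readr::col_character(), activity = readr::col_character(),
    n_conformers = readr::col_integer(), n_hits = readr::col_integer(),
    best_dE = readr::col_double(), best_rmsd = readr::col_double()))
}

#' Read a pairwise column map from a FASTA or Clustal alignment
#'
#' For the chosen pair of sequences, returns aligned residue positions as
#' 1-based ungapped indices; columns where either member is a gap contribute
#' no pair.
#'
#' @param path Alignment file (FASTA or Clustal; format auto-detected).
#' @param pair Indices or names of the two sequences to map (default first
#'   two).
#' @return Tibble with columns `index_a`, `index_b`; the aligned sequences
#'   are attached as attribute `"sequences"`.
#' @export
read_alignment <- function(path, pair = c(1L, 2L)) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(methods::as(aln, "AAStringSet"))
  } else {
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) >= 2L && length(unique(Biostrings::width(ss))) != 1L)
      abort("ragged alignment")
    seqs <- as.character(ss)
  }
  if (length(seqs) < 2L) abort("alignment needs at least two sequences")
  alignment_column_map(seqs, pair)
}

#' @rdname read_alignment
#' @param seqs Named character vector of equal-length aligned sequences.
#' @export
alignment_column_map <- function(seqs, pair = c(1L, 2L)) {
  if (length(unique(nchar(seqs))) != 1L) abort("ragged alignment")
  a <- strsplit(seqs[[pair[1]]], "")[[1]]
  b <- strsplit(seqs[[pair[2]]], "")[[1]]
  gap <- c("-", ".")
  ia <- cumsum(!(a %in% gap))
  ib <- cumsum(!(b %in% gap))
  keep <- !(a %in% gap) & !(b %in% gap)
  out <- tibble(index_a = ia[keep], index_b = ib[keep])
  attr(out, "sequences") <- seqs[pair]
  out
}
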