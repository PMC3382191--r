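# The pharmacophore data model and its receptor-based construction:
# interaction features seeded at reference-ligand annotation points, and
# excluded volumes centred on binding-site hydrogens and aromatic ring
# centroids, with class-dependent radii tunable against a labelled library.

# side-chain ring atom names used for receptor ring volumes
RESIDUE_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

#' Excluded-volume radius map by hydrogen class
#'
#' Radii (angstrom) applied to excluded volumes centred on receptor
#' hydrogens, by class.  The Bondi van der Waals values are 1.2 (aliphatic)
#' and 1.0 (aromatic/polar); the tuned final values used by default
#' throughout the package are 1.5 and 1.3.
#'
#' @param aliphatic,aromatic,polar Radii in angstrom, all > 0.
#' @return Named numeric vector of class `radius_map`.
#' @export
radius_map <- function(aliphatic = 1.5, aromatic = 1.3, polar = 1.3) {
  v <- c(aliphatic = as.numeric(aliphatic), aromatic = as.numeric(aromatic),
         polar = as.numeric(polar))
  if (any(!is.finite(v)) || any(v <= 0)) abort("radii must be positive")
  structure(v, class = "radius_map")
}

#' @rdname radius_map
#' @export
radius_map_bondi <- function() radius_map(1.2, 1.0, 1.0)

#' @rdname radius_map
#' @export
radius_map_final <- function() radius_map(1.5, 1.3, 1.3)

#' @rdname radius_map
#' @export
radius_map_d2 <- function() radius_map(2.1, 1.9, 1.9)

empty_features <- function() {
  tibble(label = character(), kind = character(), x = numeric(),
         y = numeric(), z = numeric(), tolerance = numeric(),
         essential = logical())
}

empty_volumes <- function() {
  tibble(x = numeric(), y = numeric(), z = numeric(), radius = numeric(),
         mode = character(), elements = list(), class = character(),
         provenance = character())
}

#' Construct a pharmacophore model
#'
#' A pharmacophore is a set of typed interaction features (center,
#' tolerance sphere, essential flag) plus excluded volumes (forbidden
#' spheres; mode `"all"` rejects any heavy atom, mode `"element"` rejects
#' only atoms whose element is in the volume's element set, e.g. an
#' oxygen-excluding ExclO volume).
#'
#' @param features Feature tibble (`label`, `kind`, `x`, `y`, `z`,
#'   `tolerance`, `essential`).
#' @param volumes Volume tibble (`x`, `y`, `z`, `radius`, `mode`,
#'   `elements` list column, `class`, `provenance`).
#' @param radius_map [radius_map()] used to build the volumes.
#' @param ring_radius Radius (angstrom) of ring-centroid volumes.
#' @param metadata Free-text provenance string.
#' @return Object of class `pharmacophore`.
#' @export
pharmacophore <- function(features = empty_features(),
                          volumes = empty_volumes(),
                          radius_map = radius_map_final(),
                          ring_radius = 2.5, metadata = "") {
  features <- as_tibble(features)
  volumes <- as_tibble(volumes)
  if (nrow(features) > 0L) {
    if (!all(features$kind %in% POINT_KINDS)) abort("unknown feature kind")
    if (any(features$tolerance <= 0)) abort("feature tolerance must be > 0")
  }
  if (nrow(volumes) > 0L) {
    if (any(volumes$radius <= 0)) abort("volume radius must be > 0")
    bad <- volumes$mode == "element" &
      map_int(volumes$elements, length) == 0L
    if (any(bad)) abort("element-specific volume needs a non-empty element set")
  }
  structure(list(features = features, volumes = volumes,
                 radius_map = radius_map, ring_radius = ring_radius,
                 metadata = metadata),
            class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf(
    "<pharmacophore: %d features (%d essential), %d excluded volumes; radii %s; ring %.2f>\n",
    nrow(x$features), sum(x$features$essential), nrow(x$volumes),
    paste(sprintf("%s=%.2f", names(x$radius_map), x$radius_map),
          collapse = " "), x$ring_radius))
  invisible(x)
}

#' Residues in contact with the ligand
#'
#' Returns receptor residues having at least one atom within `cutoff`
#' (center-to-center, inclusive) of at least one ligand heavy atom.  All
#' receptor atoms count, hydrogens included.
#'
#' @param complex A [structure_complex()].
#' @param cutoff Distance cutoff in angstrom (3.0 for excluded-volume
#'   construction, 3.5 for the binding-pocket definition).
#' @return Tibble (`chain`, `residue_seq`, `residue_name`, `min_dist`)
#'   sorted by chain then residue number.
#' @export
contact_residues <- function(complex, cutoff = 3.5) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  lig <- filter(complex$ligand, !.data$is_hydrogen)
  if (nrow(lig) == 0L || nrow(complex$receptor) == 0L)
    return(tibble(chain = character(), residue_seq = integer(),
                  residue_name = character(), min_dist = numeric()))
  d <- cross_dist(as_xyz_matrix(complex$receptor), as_xyz_matrix(lig))
  complex$receptor |>
    mutate(.min_d = apply(d, 1, min)) |>
    group_by(.data$chain, .data$residue_seq, .data$residue_name) |>
    summarise(min_dist = min(.data$.min_d), .groups = "drop") |>
    filter(.data$min_dist <= cutoff) |>
    arrange(.data$chain, .data$residue_seq)
}

# classify a receptor hydrogen without a bond table: the nearest heavy atom
# in the same residue is its covalent partner
classify_receptor_hydrogen <- function(h_row, res_atoms) {
  heavy <- filter(res_atoms, !.data$is_hydrogen)
  if (nrow(heavy) == 0L) return("aliphatic")
  d <- cross_dist(matrix(c(h_row$x, h_row$y, h_row$z), 1),
                  as_xyz_matrix(heavy))
  nb <- heavy[which.min(d), ]
  if (toupper(nb$element) %in% c("N", "O", "S")) return("polar")
  rings <- RESIDUE_RINGS[[toupper(h_row$residue_name)]]
  if (!is.null(rings) && toupper(nb$element) == "C" &&
      nb$name %in% unlist(rings)) return("aromatic")
  "aliphatic"
}

#' Build excluded volumes from receptor-ligand complexes
#'
#' One volume is placed over every hydrogen of every residue within
#' `contact_cutoff` of the ligand (hydrogen-bonded hydrogens included),
#' with radius taken from `radius_map` by hydrogen class; one volume of
#' radius `ring_radius` is placed at the centroid of each aromatic
#' side-chain ring (His/Phe/Tyr/Trp) of a contact residue, guarding
#' against face-to-edge ring clashes.  Volumes from multiple pre-superposed
#' complexes are unioned; centers within `dedup_dist` are merged keeping
#' the larger radius.
#'
#' @param complexes A [structure_complex()] or list of them, sharing one
#'   frame of reference.
#' @param radius_map A [radius_map()].
#' @param contact_cutoff Ligand-to-residue distance defining contact
#'   residues (angstrom).
#' @param ring_radius Ring-centroid volume radius (angstrom).
#' @param dedup_dist Merge distance for the multi-complex union (angstrom).
#' @return Volume tibble (see [pharmacophore()]).
#' @export
build_excluded_volumes <- function(complexes, radius_map = radius_map_final(),
                                   contact_cutoff = 3.0, ring_radius = 2.5,
                                   dedup_dist = 0.25) {
  if (inherits(complexes, "structure_complex")) complexes <- list(complexes)
  vols <- list()
  for (cx in complexes) {
    if (!any(cx$receptor$is_hydrogen)) abort("structure not protonated")
    contacts <- contact_residues(cx, contact_cutoff)
    for (i in seq_len(nrow(contacts))) {
      res <- contacts[i, ]
      res_atoms <- filter(cx$receptor, .data$chain == res$chain,
                          .data$residue_seq == res$residue_seq)
      hs <- filter(res_atoms, .data$is_hydrogen)
      for (j in seq_len(nrow(hs))) {
        h <- hs[j, ]
        cls <- classify_receptor_hydrogen(h, res_atoms)
        vols[[length(vols) + 1L]] <- tibble(
          x = h$x, y = h$y, z = h$z, radius = unname(radius_map[[cls]]),
          mode = "all", elements = list(character()), class = cls,
          provenance = sprintf("%s:%s%d:%s", cx$id, res$residue_name,
                               res$residue_seq, h$name))
      }
      rings <- RESIDUE_RINGS[[toupper(res$residue_name)]]
      for (ring in rings) {
        ra <- filter(res_atoms, .data$name %in% ring)
        if (nrow(ra) < 3L) next
        cn <- ring_centroid_normal(as_xyz_matrix(ra))
        vols[[length(vols) + 1L]] <- tibble(
          x = cn$centroid[1], y = cn$centroid[2], z = cn$centroid[3],
          radius = ring_radius, mode = "all", elements = list(character()),
          class = "ring",
          provenance = sprintf("%s:%s%d:ring", cx$id, res$residue_name,
                               res$residue_seq))
      }
    }
  }
  if (length(vols) == 0L) return(empty_volumes())
  dedup_volumes(bind_rows(vols), dedup_dist)
}

lex_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

dedup_volumes <- function(vols, dedup_dist) {
  kept <- vols[0, ]
  for (i in seq_len(nrow(vols))) {
    v <- vols[i, ]
    if (nrow(kept) > 0L) {
      d <- sqrt((kept$x - v$x)^2 + (kept$y - v$y)^2 + (kept$z - v$z)^2)
      hit <- which(d <= dedup_dist)
      if (length(hit) > 0L) {
        k <- hit[1]
        # keep the larger radius; on a radius tie keep the
        # lexicographically smaller center so the union is commutative
        # in complex order
        if (v$radius > kept$radius[k] ||
            (v$radius == kept$radius[k] &&
             lex_lt(c(v$x, v$y, v$z),
                    c(kept$x[k], kept$y[k], kept$z[k]))))
          kept[k, ] <- v
        next
      }
    }
    kept <- bind_rows(kept, v)
  }
  kept
}

#' Seed features at reference-ligand annotation points
#'
#' Each requested feature is placed at the position of the first unused
#' annotation point of its kind (points are consumed in their deterministic
#' perception order).
#'
#' @param reference_points Annotation-point tibble from
#'   [perceive_annotation_points()].
#' @param feature_spec Tibble (`label`, `kind`, `tolerance`, `essential`).
#' @return Feature tibble.
#' @export
place_features <- function(reference_points, feature_spec) {
  feature_spec <- as_tibble(feature_spec)
  if (nrow(feature_spec) == 0L) return(empty_features())
  used <- logical(nrow(reference_points))
  out <- list()
  for (i in seq_len(nrow(feature_spec))) {
    fs <- feature_spec[i, ]
    cand <- which(reference_points$kind == fs$kind & !used)
    if (length(cand) == 0L)
      abort(paste0("unseeded feature: no ", fs$kind, " annotation point for '",
                   fs$label, "'"))
    k <- cand[1]
    used[k] <- TRUE
    out[[i]] <- tibble(label = fs$label, kind = fs$kind,
                       x = reference_points$x[k], y = reference_points$y[k],
                       z = reference_points$z[k],
                       tolerance = fs$tolerance, essential = fs$essential)
  }
  bind_rows(out)
}

#' Rigidly translate the feature block of a model
#'
#' Shifts all feature centers by `offset`, leaving excluded volumes fixed
#' in the receptor frame — the knob used to align the feature triad with a
#' receptor-derived volume set.
#'
#' @param model A [pharmacophore()].
#' @param offset Length-3 numeric, angstrom.
#' @return The shifted [pharmacophore()].
#' @export
shift_features <- function(model, offset) {
  offset <- as.numeric(offset)
  model$features$x <- model$features$x + offset[1]
  model$features$y <- model$features$y + offset[2]
  model$features$z <- model$features$z + offset[3]
  model
}

#' Toggle a feature between essential and optional
#'
#' @param model A [pharmacophore()].
#' @param label Feature label.
#' @param essential New flag (default `FALSE`, i.e. demotion to optional).
#' @return The updated [pharmacophore()].
#' @export
demote_feature <- function(model, label, essential = FALSE) {
  k <- which(model$features$label == label)
  if (length(k) == 0L) abort(paste0("unknown feature label: ", label))
  model$features$essential[k] <- essential
  model
}

#' Re-derive volume radii from a radius map
#'
#' Hydrogen-derived volumes (class aliphatic/aromatic/polar) take the
#' map's class radius; ring volumes keep `ring_radius`.
#'
#' @param model A [pharmacophore()].
#' @param map A [radius_map()].
#' @return The updated [pharmacophore()].
#' @export
set_radius_map <- function(model, map) {
  cls <- model$volumes$class
  idx <- cls %in% names(map)
  model$volumes$radius[idx] <- unname(map[cls[idx]])
  model$radius_map <- map
  model
}

#' Grid search for the most discriminating radius map
#'
#' Rebuilds the model's excluded-volume radii at every map in `grid`,
#' screens the labelled library, and returns the map maximising the
#' discrimination score (active hit fraction minus inactive hit fraction).
#' Ties break toward larger radii (stricter shape), then lexicographically
#' by (aliphatic, aromatic, polar) descending.
#'
#' @param model A screening-ready [pharmacophore()].
#' @param ligands List of labelled [ligand_ensemble()] objects (at least
#'   one active and one inactive).
#' @param grid List of [radius_map()] candidates.
#' @param dE_cutoff Conformer energy cutoff, kcal/mol.
#' @param active_set Activity labels counted as active.
#' @return List with `radius_map` (winner), `score`, and `table` (one row
#'   per grid point with fractions and score).
#' @export
tune_radii <- function(model, ligands, grid, dE_cutoff = 4.0,
                       active_set = "full") {
  if (length(grid) == 0L) abort("empty radius-map grid")
  rows <- map(seq_along(grid), function(i) {
    m <- set_radius_map(model, grid[[i]])
    sc <- discrimination_score(screen_library(m, ligands, dE_cutoff),
                               active_set = active_set)
    tibble(grid_index = i, aliphatic = grid[[i]][["aliphatic"]],
           aromatic = grid[[i]][["aromatic"]], polar = grid[[i]][["polar"]],
           active_hit_fraction = sc$active_hit_fraction,
           inactive_hit_fraction = sc$inactive_hit_fraction,
           score = sc$score)
  }) |> bind_rows()
  ord <- order(-rows$score, -rows$aliphatic, -rows$aromatic, -rows$polar)
  best <- rows[ord[1], ]
  list(radius_map = grid[[best$grid_index]], score = best$score, table = rows)
}
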