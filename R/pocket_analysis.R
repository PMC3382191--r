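# Binding-pocket characterisation and two-receptor comparison: grid
# flood-fill pocket volume, conservation mapping through a pairwise
# alignment, Ballesteros-Weinstein numbering, and interface interaction
# geometry (hydrogen bonds, salt bridges, close contacts, ring stacking
# candidates).

#' Grid flood-fill estimate of the binding-pocket volume
#'
#' The pocket is the set of grid points within `shell` of any ligand heavy
#' atom, outside every receptor atom's Bondi van-der-Waals sphere, and
#' 6-connected-reachable from the grid point nearest the ligand centroid;
#' the volume is the reachable count times the grid cell volume.
#'
#' @param complex A [structure_complex()].
#' @param grid_spacing Grid spacing in angstrom (> 0).
#' @param shell Ligand shell radius in angstrom.
#' @return Volume in cubic angstrom.
#' @export
pocket_volume <- function(complex, grid_spacing = 0.5, shell = 4.0) {
  if (grid_spacing <= 0) abort("grid spacing must be > 0")
  lig <- filter(complex$ligand, !.data$is_hydrogen)
  if (nrow(lig) == 0L) return(0)
  L <- as_xyz_matrix(lig)
  lo <- apply(L, 2, min) - shell - grid_spacing
  hi <- apply(L, 2, max) + shell + grid_spacing
  ax <- map(1:3, function(k) seq(lo[k], hi[k], by = grid_spacing))
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  G <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  in_shell <- rep(FALSE, nrow(G))
  for (i in seq_len(nrow(L))) {
    d2 <- (G[, 1] - L[i, 1])^2 + (G[, 2] - L[i, 2])^2 + (G[, 3] - L[i, 3])^2
    in_shell <- in_shell | d2 <= shell^2
  }
  blocked <- rep(FALSE, nrow(G))
  rec <- complex$receptor
  if (nrow(rec) > 0L) {
    Rm <- as_xyz_matrix(rec)
    rv <- unname(BONDI_VDW[toupper(rec$element)])
    rv[is.na(rv)] <- 1.5
    for (i in seq_len(nrow(Rm))) {
      d2 <- (G[, 1] - Rm[i, 1])^2 + (G[, 2] - Rm[i, 2])^2 +
        (G[, 3] - Rm[i, 3])^2
      blocked <- blocked | d2 < rv[i]^2
    }
  }
  open <- array(in_shell & !blocked, dim = c(nx, ny, nz))
  centroid <- colMeans(L)
  seed <- map_int(1:3, function(k) which.min(abs(ax[[k]] - centroid[k])))
  if (!open[seed[1], seed[2], seed[3]]) return(0)
  # BFS flood fill, 6-connectivity
  reached <- array(FALSE, dim = dim(open))
  queue <- matrix(seed, ncol = 3)
  reached[seed[1], seed[2], seed[3]] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0L) {
    nxt <- list()
    for (o in seq_len(6)) {
      cand <- sweep(queue, 2, offs[o, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= nx & cand[, 2] >= 1 &
        cand[, 2] <= ny & cand[, 3] >= 1 & cand[, 3] <= nz
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) next
      li <- cand[, 1] + nx * (cand[, 2] - 1L) + nx * ny * (cand[, 3] - 1L)
      keep <- open[li] & !reached[li]
      if (any(keep)) {
        li <- li[keep]
        reached[li] <- TRUE
        nxt[[length(nxt) + 1L]] <- cand[keep, , drop = FALSE]
      }
    }
    queue <- if (length(nxt)) unique(do.call(rbind, nxt)) else
      matrix(numeric(), ncol = 3)
  }
  sum(reached) * grid_spacing^3
}

#' Map conservation of pocket residues through a pairwise alignment
#'
#' A residue of sequence A is conserved when the alignment pairs it with a
#' residue of B carrying the identical one-letter code; residues aligned to
#' a gap are not conserved.  Strict identity only — physicochemical
#' similarity classes are out of scope.
#'
#' @param pocket Tibble with columns `index_a` (1-based ungapped position
#'   in sequence A) and `aa` (one-letter code in A).
#' @param column_map Pairwise column map from [read_alignment()] /
#'   [alignment_column_map()].
#' @param seq_b Ungapped sequence of B as a single string.
#' @return `pocket` with an added logical `conserved` column.
#' @export
conservation_map <- function(pocket, column_map, seq_b) {
  pocket <- as_tibble(pocket)
  seqs <- attr(column_map, "sequences")
  if (!is.null(seqs)) {
    len_a <- nchar(gsub("[-.]", "", seqs[[1]]))
    if (any(pocket$index_a < 1L | pocket$index_a > len_a))
      abort("residue outside alignment span")
  }
  bpos <- column_map$index_b[match(pocket$index_a, column_map$index_a)]
  bb <- strsplit(seq_b, "")[[1]]
  pocket$conserved <- !is.na(bpos) & bpos <= length(bb) &
    bb[ifelse(is.na(bpos), 1L, bpos)] == pocket$aa
  pocket
}

#' Ballesteros-Weinstein numbering
#'
#' Renders `"h.nn"` with `nn = 50 + (residue_seq - ref_seq)` for residues
#' inside a declared helix span; residues outside every span return NA.
#' Helix spans and x.50 anchors are explicit configuration, never inferred.
#'
#' @param residue_seq Integer vector of author residue numbers.
#' @param helix_refs Tibble with columns `helix`, `start`, `end`,
#'   `ref_seq` (author number of the x.50 anchor).
#' @return Character vector of BW indices (NA outside all spans).
#' @export
bw_number <- function(residue_seq, helix_refs) {
  helix_refs <- as_tibble(helix_refs)
  map_chr(as.integer(residue_seq), function(rs) {
    k <- which(helix_refs$start <= rs & rs <= helix_refs$end)
    if (length(k) == 0L) return(NA_character_)
    k <- k[1]
    sprintf("%s.%d", helix_refs$helix[k],
            50L + rs - as.integer(helix_refs$ref_seq[k]))
  })
}

#' Assemble a pocket report for one complex
#'
#' Pocket residues (within `cutoff` of the ligand), grid pocket volume,
#' optional BW indices and optional conservation flags against a second
#' receptor sequence.
#'
#' @param complex A [structure_complex()].
#' @param cutoff Pocket definition cutoff, angstrom.
#' @param helix_refs Optional BW configuration (see [bw_number()]).
#' @param column_map,seq_b Optional conservation inputs (see
#'   [conservation_map()]); `index_a` is taken to be the author residue
#'   number unless `index_map` translates it.
#' @param index_map Optional function mapping author residue numbers to
#'   ungapped sequence positions (defaults to identity).
#' @param grid_spacing,shell Passed to [pocket_volume()].
#' @return List of class `pocket_report`: `residues` tibble, `volume`,
#'   `n_residues`, `n_nonconserved`.
#' @export
pocket_report <- function(complex, cutoff = 3.5, helix_refs = NULL,
                          column_map = NULL, seq_b = NULL, index_map = identity,
                          grid_spacing = 0.5, shell = 4.0) {
  res <- contact_residues(complex, cutoff)
  res$aa <- three_to_one(res$residue_name)
  res$bw <- if (!is.null(helix_refs)) bw_number(res$residue_seq, helix_refs)
            else NA_character_
  if (!is.null(column_map) && !is.null(seq_b)) {
    cm <- conservation_map(
      tibble(index_a = as.integer(index_map(res$residue_seq)), aa = res$aa),
      column_map, seq_b)
    res$conserved <- cm$conserved
  } else {
    res$conserved <- NA
  }
  structure(list(
    residues = res,
    volume = pocket_volume(complex, grid_spacing, shell),
    n_residues = nrow(res),
    n_nonconserved = if (all(is.na(res$conserved))) NA_integer_
                     else sum(!res$conserved)),
    class = "pocket_report")
}

#' @export
print.pocket_report <- function(x, ...) {
  cat(sprintf("<pocket_report: %d residues, volume %.1f A^3, %s non-conserved>\n",
              x$n_residues, x$volume,
              if (is.na(x$n_nonconserved)) "?" else x$n_nonconserved))
  invisible(x)
}

three_to_one <- function(res3) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- unname(tab[toupper(res3)])
  out[is.na(out)] <- "X"
  out
}

angle_deg <- function(a, b, c) {
  # angle at b, degrees
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Geometric interaction report for a receptor-ligand interface
#'
#' Reports, across the ligand-receptor interface only:
#' * hydrogen bonds: donor-heavy to acceptor-heavy distance <= `hbond_dmax`
#'   and D-H...A angle (at the hydrogen) >= `hbond_amin`;
#' * salt bridges: cationic nitrogen to carboxylate oxygen distance <=
#'   `salt_dmax`;
#' * close contacts: non-bonded interface atom pairs closer than
#'   `contact_d` (strict);
#' * ring-stack candidates: ligand aromatic ring centroid to receptor
#'   side-chain ring centroid <= `stack_dmax` (geometry only).
#'
#' @param complex A [structure_complex()] with hydrogens.
#' @param hbond_dmax,hbond_amin Hydrogen-bond distance (angstrom) and
#'   minimum angle (degrees).
#' @param salt_dmax Salt-bridge N-O distance cutoff, angstrom.
#' @param contact_d Close-contact threshold, angstrom (strict `<`).
#' @param stack_dmax Ring-centroid distance cutoff, angstrom.
#' @return Tibble: `kind`, `partner_a` (ligand side), `partner_b`
#'   (receptor side), `distance`, `angle` (NA where not applicable).
#' @export
report_key_interactions <- function(complex, hbond_dmax = 3.5,
                                    hbond_amin = 120, salt_dmax = 4.0,
                                    contact_d = 2.6, stack_dmax = 6.0) {
  lig <- complex$ligand
  rec <- complex$receptor
  Lxyz <- as_xyz_matrix(lig)
  Rxyz <- as_xyz_matrix(rec)
  adj <- bond_adjacency(nrow(lig), complex$ligand_bonds)
  lig_label <- sprintf("LIG:%s", lig$name)
  rec_label <- sprintf("%s%d:%s", rec$residue_name, rec$residue_seq, rec$name)
  recs <- list()
  add <- function(kind, a, b, d, ang = NA_real_) {
    recs[[length(recs) + 1L]] <<- tibble(kind = kind, partner_a = a,
                                         partner_b = b, distance = d,
                                         angle = ang)
  }
  # donor/H pairs
  lig_donors <- list()
  for (i in seq_len(nrow(lig))) {
    if (lig$is_hydrogen[i] || !(toupper(lig$element[i]) %in% c("N", "O")))
      next
    hs <- adj[[i]][lig$is_hydrogen[adj[[i]]]]
    for (h in hs) lig_donors[[length(lig_donors) + 1L]] <- c(i, h)
  }
  rec_donors <- list()
  for (i in seq_len(nrow(rec))) {
    if (rec$is_hydrogen[i] || !(toupper(rec$element[i]) %in% c("N", "O")))
      next
    same_res <- which(rec$chain == rec$chain[i] &
                        rec$residue_seq == rec$residue_seq[i] &
                        rec$is_hydrogen)
    if (length(same_res) == 0L) next
    d <- sqrt(rowSums(sweep(Rxyz[same_res, , drop = FALSE], 2,
                            Rxyz[i, ])^2))
    for (h in same_res[d < 1.3])
      rec_donors[[length(rec_donors) + 1L]] <- c(i, h)
  }
  lig_acc <- which(!lig$is_hydrogen & toupper(lig$element) %in% c("N", "O"))
  rec_acc <- which(!rec$is_hydrogen & toupper(rec$element) %in% c("N", "O"))
  hbond <- function(dh, Dxyz, Hxyz, acc_idx, Axyz, lab_d, lab_a, swap) {
    D <- Dxyz[dh[1], ]; H <- Hxyz[dh[2], ]
    for (a in acc_idx) {
      A <- Axyz[a, ]
      d <- vnorm(A - D)
      if (d > hbond_dmax || d < 1e-6) next
      ang <- angle_deg(D, H, A)
      if (ang < hbond_amin) next
      if (swap) add("hbond", lab_a[a], lab_d[dh[1]], d, ang)
      else add("hbond", lab_d[dh[1]], lab_a[a], d, ang)
    }
  }
  for (dh in lig_donors) hbond(dh, Lxyz, Lxyz, rec_acc, Rxyz,
                               lig_label, rec_label, swap = FALSE)
  for (dh in rec_donors) hbond(dh, Rxyz, Rxyz, lig_acc, Lxyz,
                               rec_label, lig_label, swap = TRUE)
  # salt bridges: ligand cationic N vs receptor carboxylate O (and the
  # mirror case for anionic ligand oxygens vs receptor basic nitrogens)
  lig_cat <- which(!lig$is_hydrogen & toupper(lig$element) == "N" &
                     (lig$formal_charge > 0L |
                        map_int(seq_len(nrow(lig)), function(i)
                          sum(lig$is_hydrogen[adj[[i]]])) >= 2L))
  rec_coo <- which(toupper(rec$residue_name) %in% c("ASP", "GLU") &
                     rec$name %in% c("OD1", "OD2", "OE1", "OE2"))
  for (i in lig_cat) {
    for (j in rec_coo) {
      d <- vnorm(Rxyz[j, ] - Lxyz[i, ])
      if (d <= salt_dmax) add("salt-bridge", lig_label[i], rec_label[j], d)
    }
  }
  # close contacts (interface pairs are non-bonded by construction)
  if (nrow(lig) > 0L && nrow(rec) > 0L) {
    D <- cross_dist(Lxyz, Rxyz)
    idx <- which(D < contact_d, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      add("close-contact", lig_label[idx[r, 1]], rec_label[idx[r, 2]],
          D[idx[r, 1], idx[r, 2]])
  }
  # ring-stack candidates
  lrings <- aromatic_rings(lig, complex$ligand_bonds)
  if (length(lrings) > 0L) {
    contacts <- contact_residues(complex, cutoff = stack_dmax + 4)
    for (i in seq_len(nrow(contacts))) {
      res <- contacts[i, ]
      rings <- RESIDUE_RINGS[[toupper(res$residue_name)]]
      if (is.null(rings)) next
      res_atoms <- filter(rec, .data$chain == res$chain,
                          .data$residue_seq == res$residue_seq)
      for (ring in rings) {
        ra <- filter(res_atoms, .data$name %in% ring)
        if (nrow(ra) < 3L) next
        rc <- ring_centroid_normal(as_xyz_matrix(ra))$centroid
        for (lr in lrings) {
          lc <- ring_centroid_normal(Lxyz[lr, , drop = FALSE])$centroid
          d <- vnorm(rc - lc)
          if (d <= stack_dmax)
            add("ring-stack-candidate", "LIG:ring",
                sprintf("%s%d:ring", res$residue_name, res$residue_seq), d)
        }
      }
    }
  }
  if (length(recs) == 0L)
    return(tibble(kind = character(), partner_a = character(),
                  partner_b = character(), distance = numeric(),
                  angle = numeric()))
  bind_rows(recs)
}
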