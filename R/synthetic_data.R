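# Synthetic study fixtures: a toy protonated receptor-ligand complex with a
# defined pocket, and ligand ensembles with planted hit/miss ground truth.
#
# Synthetic ligands are minimal chemically-plausible point sets (ring,
# amine nitrogen, hydroxyl, linker/probe carbons) rather than force-field
# geometries: the matcher consumes annotation points plus heavy atoms, so
# this suffices and keeps screens sub-second.  Coordinates are rounded to
# the precision of the target file format (PDB 1e-3, SDF 1e-4) at
# generation time so that file round-trips are exact.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

runif_ball <- function(r) {
  repeat {
    v <- runif(3, -r, r)
    if (vnorm(v) <= r) return(v)
  }
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

hexagon <- function(center, radius = 1.40, azimuth = 0) {
  ang <- azimuth + (0:5) * pi / 3
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3])
}

#' Generate a toy protonated receptor-ligand complex
#'
#' A dopamine-like rigid ligand (catechol ring, ethylamine chain with a
#' protonated nitrogen) sits at the origin, surrounded by pseudo-residues:
#' a serine (polar hydroxyl hydrogen) hydrogen-bonded to one catechol
#' oxygen, an aspartate carboxylate paired with the ligand nitrogen, a
#' phenylalanine ring stacked face-to-edge over the ligand ring, and a
#' shell of glycines 4.5-6 angstrom out.  At least three residues lie
#' within 3.0 angstrom contact of the ligand; receptor hydrogens point
#' away from the ligand so excluded volumes built from the complex leave
#' the reference pose clear.
#'
#' @param seed Integer seed; output is deterministic per seed.
#' @param n_shell_atoms Approximate receptor atom count (>= 10).
#' @return A [structure_complex()].
#' @export
make_toy_complex <- function(seed = 1L, n_shell_atoms = 60L) {
  if (n_shell_atoms < 10L) abort("n_shell_atoms must be >= 10")
  with_local_seed(seed, {
    jit <- function() runif_ball(0.05)
    ## --- ligand -----------------------------------------------------
    ring <- hexagon(c(0, 0, 0))
    o1 <- 2.76 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
    o2 <- 2.76 * c(cos(pi), sin(pi), 0)
    u1 <- unit(o1)
    h_o1 <- o1 + 0.97 * u1            # points at the serine OG
    h_o2 <- o2 + 0.97 * unit(o2)
    c7 <- c(2.90, 0, 0)
    c8 <- c(3.65, 0, 1.30)
    n1 <- c(4.40, 0, 2.60)
    v_asp <- unit(c(1, 0, 1))
    hn <- rbind(n1 + 1.02 * v_asp,    # toward the aspartate carboxylate
                n1 + 1.02 * unit(c(0.3, 0.9, 0.3)),
                n1 + 1.02 * unit(c(0.3, -0.9, 0.3)))
    ring_h_idx <- c(2, 5, 6)          # C2/C5/C6 carry ring hydrogens
    ring_h <- t(apply(ring[ring_h_idx, ], 1, function(p) p * (2.48 / 1.40)))
    lig_pos <- rbind(ring, o1, o2, h_o1, h_o2, c7, c8, n1, hn, ring_h)
    lig <- new_atom_table(
      serial = seq_len(nrow(lig_pos)) + 1000L,
      name = c(paste0("C", 1:6), "O1", "O2", "HO1", "HO2", "C7", "C8", "N1",
               paste0("HN", 1:3), paste0("HC", ring_h_idx)),
      element = c(rep("C", 6), "O", "O", "H", "H", "C", "C", "N",
                  rep("H", 3), rep("H", 3)),
      residue_name = "DOP", residue_seq = 900L, chain = "A",
      x = lig_pos[, 1], y = lig_pos[, 2], z = lig_pos[, 3],
      formal_charge = c(rep(0L, 12), 1L, rep(0L, 6)))
    lig_bonds <- tibble(
      a1 = c(1L, 2L, 3L, 4L, 5L, 6L, 3L, 4L, 7L, 8L, 1L, 11L, 12L,
             13L, 13L, 13L, 2L, 5L, 6L),
      a2 = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 11L, 12L, 13L,
             14L, 15L, 16L, 17L, 18L, 19L),
      order = c("2", "1", "2", "1", "2", "1", "1", "1", "1", "1", "1",
                "1", "1", "1", "1", "1", "1", "1", "1"))
    ## --- anchor residues --------------------------------------------
    rec <- list()
    push <- function(res_name, res_seq, names, elements, pos) {
      rec[[length(rec) + 1L]] <<- new_atom_table(
        serial = 0L, name = names, element = elements,
        residue_name = res_name, residue_seq = res_seq, chain = "A",
        x = pos[, 1], y = pos[, 2], z = pos[, 3])
    }
    # SER 1: OG accepts the catechol O1-H; HG points away from the ligand
    og <- o1 + 2.80 * u1 + jit()
    cb_s <- og + 1.43 * unit(u1 + c(0, 0, -0.9))
    ca_s <- cb_s + 1.52 * unit(u1 + c(0, 0, -0.4))
    n_s <- ca_s + 1.46 * unit(u1 + c(0, 0, 0.3))
    hg <- og + 0.97 * unit(0.25 * u1 + c(0, 0, 1))   # points up, off-ligand
    hb_s <- cb_s + 1.09 * unit(u1 + c(0, 0, -0.3))
    push("SER", 1L, c("N", "CA", "CB", "OG", "HG", "HB2"),
         c("N", "C", "C", "O", "H", "H"),
         rbind(n_s, ca_s, cb_s, og, hg, hb_s))
    # ASP 2: carboxylate paired with the ligand ammonium
    cg_d <- n1 + 4.00 * v_asp + jit()
    od1 <- cg_d - 1.25 * unit(cg_d - n1)
    perp <- unit(c(-v_asp[3], 0, v_asp[1]))
    od2 <- cg_d + 1.25 * unit(perp + 0.4 * v_asp)
    cb_d <- cg_d + 1.52 * v_asp
    hb1 <- cb_d + 1.09 * unit(v_asp + 0.5 * perp)
    hb2 <- cb_d + 1.09 * unit(v_asp - 0.5 * perp)
    push("ASP", 2L, c("CB", "CG", "OD1", "OD2", "HB2", "HB3"),
         c("C", "C", "O", "O", "H", "H"),
         rbind(cb_d, cg_d, od1, od2, hb1, hb2))
    # PHE 3: ring face-on 2.9 angstrom above the catechol ring
    p0 <- c(0, 0, 2.90) + jit() * 0.5
    # azimuth offset keeps the ring hydrogens clear of the ligand chain
    phe_ring <- hexagon(p0, azimuth = pi / 2)
    phe_h <- t(apply(phe_ring, 1, function(p)
      p0 + (p - p0) * (2.48 / 1.40)))
    # CB sits on the ring carbon facing away from the ligand chain (the
    # CG attachment point carries no ring hydrogen)
    phe_h <- phe_h[c(1:3, 5:6), , drop = FALSE]
    cb_f <- phe_ring[4, ] + unit(phe_ring[4, ] - p0) * 1.5 + c(0, 0, 0.8)
    push("PHE", 3L,
         c("CB", "CZ", "CE1", "CD1", "CG", "CD2", "CE2",
           "HZ", "HE1", "HD1", "HD2", "HE2"),
         c("C", rep("C", 6), rep("H", 5)),
         rbind(cb_f, phe_ring, phe_h))
    ## --- glycine shell ----------------------------------------------
    n_core <- sum(map_int(rec, nrow))
    n_gly <- max(1L, ceiling((n_shell_atoms - n_core) / 7))
    lig_heavy <- rbind(ring, o1, o2, c7, c8, n1)
    placed <- 0L
    attempts <- 0L
    while (placed < n_gly && attempts < 5000L) {
      attempts <- attempts + 1L
      w <- unit(rnorm(3))
      d0 <- runif(1, 4.5, 6.0)
      ca <- w * d0
      nn <- ca + 1.46 * unit(rnorm(3))
      cc <- ca + 1.52 * unit(rnorm(3))
      oo <- cc + 1.23 * unit(rnorm(3))
      hn_g <- nn + 1.01 * w
      ha1 <- ca + 1.09 * unit(w + rnorm(3) * 0.2)
      ha2 <- ca + 1.09 * unit(w + rnorm(3) * 0.2)
      pos <- rbind(nn, ca, cc, oo, hn_g, ha1, ha2)
      if (min(cross_dist(pos, lig_heavy)) < 3.2) next
      placed <- placed + 1L
      push("GLY", 3L + placed, c("N", "CA", "C", "O", "H", "HA2", "HA3"),
           c("N", "C", "C", "O", "H", "H", "H"), pos)
    }
    receptor <- bind_rows(rec)
    receptor$serial <- seq_len(nrow(receptor))
    receptor <- mutate(receptor, across(c("x", "y", "z"), ~ round(.x, 3)))
    lig2 <- mutate(lig, across(c("x", "y", "z"), ~ round(.x, 3)))
    lig2$serial <- max(receptor$serial) + seq_len(nrow(lig2))
    structure_complex(receptor, lig2, lig_bonds,
                      id = sprintf("toy-%d", seed))
  })
}

#' Default D1-style feature layout
#'
#' The three-point full-agonist arrangement: a cation feature for the
#' TM3-aspartate salt bridge, an aromatic feature for the TM6
#' phenylalanine stack, and a donor feature for the TM5-serine hydrogen
#' bond.  All essential; 1.0 angstrom tolerance.
#'
#' @param tolerance Feature tolerance radius, angstrom.
#' @return Feature-spec tibble for [place_features()].
#' @export
default_feature_spec <- function(tolerance = 1.0) {
  tibble(label = c("AspTM3", "Aro", "Ser-TM5"),
         kind = c("cation", "aromatic", "donor"),
         tolerance = tolerance, essential = TRUE)
}

#' Build a pharmacophore model from complexes
#'
#' Seeds features at the annotation points of the first complex's ligand
#' and unions excluded volumes over all complexes.
#'
#' @param complexes A [structure_complex()] or list of them.
#' @param feature_spec Feature-spec tibble (default
#'   [default_feature_spec()]).
#' @param radius_map A [radius_map()].
#' @param contact_cutoff,ring_radius See [build_excluded_volumes()].
#' @return A [pharmacophore()].
#' @export
build_model <- function(complexes, feature_spec = default_feature_spec(),
                        radius_map = radius_map_final(),
                        contact_cutoff = 3.0, ring_radius = 2.5) {
  if (inherits(complexes, "structure_complex")) complexes <- list(complexes)
  ref <- complexes[[1]]
  pts <- perceive_annotation_points(ref$ligand, ref$ligand_bonds)
  pharmacophore(
    features = place_features(pts, feature_spec),
    volumes = build_excluded_volumes(complexes, radius_map, contact_cutoff,
                                     ring_radius),
    radius_map = radius_map, ring_radius = ring_radius,
    metadata = paste("built from", paste(map_chr(complexes, "id"),
                                         collapse = "+")))
}

#' Planted-ensemble specification
#'
#' @param n_active Number of planted-hit conformers.
#' @param n_tolerance,n_clash,n_energy Decoy counts per violation mode.
#' @param jitter Uniform positional jitter of active annotation points,
#'   angstrom; must stay below the smallest feature tolerance.
#' @param seed Integer seed.
#' @return List of class `planted_spec`.
#' @export
planted_spec <- function(n_active = 4L, n_tolerance = 2L, n_clash = 2L,
                         n_energy = 2L, jitter = 0.3, seed = 11L) {
  stopifnot(n_active >= 0, n_tolerance >= 0, n_clash >= 0, n_energy >= 0,
            jitter >= 0)
  structure(list(n_active = n_active, n_tolerance = n_tolerance,
                 n_clash = n_clash, n_energy = n_energy, jitter = jitter,
                 seed = seed), class = "planted_spec")
}

# topology of the planted probe ligand: aromatic ring, protonated N
# (cation), hydroxyl (donor + acceptor), two linker carbons, three probe
# carbons.  Atom indices are fixed; coordinates vary per conformer.
planted_topology <- function() {
  atoms <- new_atom_table(
    serial = 1:14,
    name = c(paste0("C", 1:6), "N1", "O1", "HO1", "C7", "C8",
             "C9", "C10", "C11"),
    element = c(rep("C", 6), "N", "O", "H", "C", "C", "C", "C", "C"),
    residue_name = "LIG", residue_seq = 1L, chain = "A",
    x = 0, y = 0, z = 0,
    formal_charge = c(rep(0L, 6), 1L, rep(0L, 7)))
  bonds <- tibble(
    a1 = c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 10L, 4L, 11L, 10L, 12L, 13L),
    a2 = c(2L, 3L, 4L, 5L, 6L, 1L, 10L, 7L, 11L, 8L, 12L, 13L, 14L),
    order = c("2", "1", "2", "1", "2", "1", rep("1", 7)))
  bonds <- bind_rows(bonds, tibble(a1 = 8L, a2 = 9L, order = "1"))
  list(atoms = atoms, bonds = bonds)
}

# coordinates of the planted ligand for given feature anchor positions
# (cation/aromatic/donor centers) and probe positions; rounded to SDF
# precision
planted_coords <- function(f_aro, f_cat, f_don, probes, azimuth = 0) {
  ring <- hexagon(f_aro, azimuth = azimuth)
  horiz <- function(v) {
    h <- c(v[1], v[2], 0)
    if (vnorm(h) < 1e-6) h <- c(1, 0, 0)
    unit(h)
  }
  edge_n <- f_aro + 1.4 * horiz(f_cat - f_aro)
  c7 <- (edge_n + f_cat) / 2
  edge_o <- f_aro + 1.4 * horiz(f_don - f_aro)
  c8 <- (edge_o + f_don) / 2
  ho1 <- f_don + 0.97 * unit(f_don - f_aro)
  co <- rbind(ring, f_cat, f_don, ho1, c7, c8,
              probes$aliphatic, probes$aromatic, probes$polar)
  colnames(co) <- c("x", "y", "z")
  round(co, 4)
}

# probe positions relative to one volume of each hydrogen class: the probe
# sits at (radius + delta) from the target volume's center (delta < 0
# plants a clash) along a direction validated to clear every other volume
probe_positions <- function(model, delta = c(aliphatic = 0.15,
                                             aromatic = 0.15,
                                             polar = 0.15)) {
  vols <- model$volumes
  fts <- model$features
  anchors <- map(seq_len(nrow(fts)),
                 function(i) as.numeric(fts[i, c("x", "y", "z")]))
  pos <- list()
  for (cls in c("aliphatic", "aromatic", "polar")) {
    k <- which(vols$class == cls)
    if (length(k) == 0L)
      abort(paste0("model has no ", cls, "-class volume to probe"))
    v <- vols[k[1], ]
    ctr <- c(v$x, v$y, v$z)
    dist <- v$radius + delta[[cls]]
    margin <- max(delta[[cls]], 0) + 0.15
    dirs <- c(map(anchors, function(a) unit(a - ctr)),
              map(1:50, function(i) unit(rnorm(3))))
    placed <- NULL
    for (u in dirs) {
      cand <- ctr + dist * u
      others <- vols[-k[1], , drop = FALSE]
      clear <- nrow(others) == 0L ||
        all(sqrt((others$x - cand[1])^2 + (others$y - cand[2])^2 +
                   (others$z - cand[3])^2) >= others$radius + margin)
      if (clear) { placed <- cand; break }
    }
    if (is.null(placed))
      abort(paste0("infeasible placement: no clear probe direction for ",
                   cls, " volume"))
    pos[[cls]] <- placed
  }
  pos
}

# tolerance decoy: displace the cation point until the best rigid fit can
# no longer bring every matched point inside its tolerance sphere.  The
# nominal displacement is tolerance + 0.5; because a rigid superposition
# of a three-point constellation absorbs a large part of a single-point
# displacement (a displacement delta leaves a worst-case best-fit residual
# of only ~2*delta/3), the magnitude escalates geometrically until the
# matcher verifiably rejects the conformer with reason "tolerance".
make_tolerance_decoy <- function(model, fc, topo, probes0, dE_cutoff) {
  tol <- model$features$tolerance[model$features$kind == "cation"][1]
  ctr <- (fc$cation + fc$aromatic + fc$donor) / 3
  base <- unit(fc$cation - ctr)
  for (mag in (tol + 0.5) * 1.2^(0:8)) {
    for (attempt in 1:24) {
      ang <- runif(1, 0, 2 * pi)
      dir <- as.numeric(unit(rot_z(ang) %*% base))
      co <- planted_coords(fc$aromatic, fc$cation + mag * dir,
                           fc$donor, probes0)
      fate <- planted_fate(model, topo, co, dE_cutoff)
      if (!fate$hit && fate$reason == "tolerance") return(co)
    }
  }
  abort("infeasible placement: tolerance decoy keeps fitting after 1000 attempts")
}

# verify a conformer's fate against the model, for planting guarantees
planted_fate <- function(model, topo, coords, dE_cutoff = 4.0) {
  pts <- perceive_annotation_points(topo$atoms, topo$bonds, coords)
  heavy <- which(!topo$atoms$is_hydrogen)
  res <- match_conformer(model, pts, coords[heavy, , drop = FALSE],
                         topo$atoms$element[heavy])
  list(hit = res$hit, reason = res$reject_reason, rmsd = res$rmsd)
}

feature_centers <- function(model) {
  f <- model$features
  list(cation = as.numeric(f[f$kind == "cation", c("x", "y", "z")][1, ]),
       aromatic = as.numeric(f[f$kind == "aromatic", c("x", "y", "z")][1, ]),
       donor = as.numeric(f[f$kind == "donor", c("x", "y", "z")][1, ]))
}

#' Plant a ligand ensemble with known per-conformer ground truth
#'
#' Active conformers present annotation points at the model's feature
#' centers plus uniform jitter, with all heavy atoms clear of the excluded
#' volumes and energies below the cutoff.  Each decoy violates exactly one
#' constraint: `tolerance` decoys displace the cation point by its
#' feature's tolerance + 0.5 angstrom (direction chosen, and the failure
#' verified, at generation time), `clash` decoys move a probe carbon to an
#' excluded-volume center, `energy` decoys keep an active geometry but an
#' energy of cutoff + 1.
#'
#' @param model A screening-ready [pharmacophore()] with cation, aromatic
#'   and donor features (e.g. from [build_model()] on [make_toy_complex()]).
#' @param spec A [planted_spec()].
#' @param dE_cutoff Energy cutoff the ensemble is planted against,
#'   kcal/mol.
#' @param id Ensemble id.
#' @return List with `ensemble` (a [ligand_ensemble()]) and `truth`
#'   (tibble `conformer`, `planted` in
#'   active/tolerance/clash/energy).
#' @export
make_planted_ensemble <- function(model, spec, dE_cutoff = 4.0,
                                  id = "planted") {
  stopifnot(inherits(spec, "planted_spec"))
  min_tol <- min(model$features$tolerance)
  if (spec$jitter >= min_tol)
    abort("jitter must stay below the smallest feature tolerance")
  topo <- planted_topology()
  fc <- feature_centers(model)
  with_local_seed(spec$seed, {
    # probe clearance scales with jitter: the rigid fit can displace heavy
    # atoms by roughly twice the point jitter
    d0 <- max(0.15, 2 * spec$jitter + 0.1)
    probes0 <- probe_positions(model, delta = c(aliphatic = d0,
                                                aromatic = d0, polar = d0))
    make_active <- function(jit) {
      for (attempt in 1:1000) {
        co <- planted_coords(fc$aromatic + runif_ball(jit),
                             fc$cation + runif_ball(jit),
                             fc$donor + runif_ball(jit), probes0,
                             azimuth = runif(1, 0, 2 * pi))
        fate <- planted_fate(model, topo, co, dE_cutoff)
        if (fate$hit) return(co)
      }
      abort("infeasible placement: no clash-free active conformer in 1000 attempts")
    }
    make_tolerance <- function() {
      make_tolerance_decoy(model, fc, topo, probes0, dE_cutoff)
    }
    make_clash <- function(cls = "aliphatic") {
      vols <- model$volumes
      k <- which(vols$class == cls)[1]
      if (is.na(k)) k <- 1L
      probes <- probes0
      probes[[if (cls %in% names(probes)) cls else "aliphatic"]] <-
        c(vols$x[k], vols$y[k], vols$z[k])
      co <- planted_coords(fc$aromatic, fc$cation, fc$donor, probes)
      fate <- planted_fate(model, topo, co, dE_cutoff)
      if (fate$hit || fate$reason != "clash")
        abort("infeasible placement: clash decoy not rejected as clash")
      co
    }
    confs <- list(); truth <- character(); energy <- numeric()
    for (i in seq_len(spec$n_active)) {
      confs <- c(confs, list(make_active(spec$jitter)))
      truth <- c(truth, "active")
      energy <- c(energy, if (i == 1L) 0 else runif(1, 0, dE_cutoff * 0.6))
    }
    for (i in seq_len(spec$n_tolerance)) {
      confs <- c(confs, list(make_tolerance()))
      truth <- c(truth, "tolerance")
      energy <- c(energy, if (length(energy) == 0L) 0
                  else runif(1, 0, dE_cutoff * 0.8))
    }
    for (i in seq_len(spec$n_clash)) {
      confs <- c(confs, list(make_clash(
        c("aliphatic", "aromatic", "polar")[1L + (i - 1L) %% 3L])))
      truth <- c(truth, "clash")
      energy <- c(energy, if (length(energy) == 0L) 0
                  else runif(1, 0, dE_cutoff * 0.8))
    }
    for (i in seq_len(spec$n_energy)) {
      confs <- c(confs, list(planted_coords(fc$aromatic, fc$cation,
                                            fc$donor, probes0)))
      truth <- c(truth, "energy")
      energy <- c(energy, dE_cutoff + 1 + runif(1))
    }
    activity <- if (spec$n_active > 0L) "full" else "inactive"
    ens <- ligand_ensemble(id, topo$atoms, topo$bonds, confs,
                           rel_energy = rep(0, length(confs)),
                           activity = activity)
    ens$rel_energy <- round(energy, 4)   # planted energies are already relative
    list(ensemble = ens,
         truth = tibble(conformer = seq_along(truth), planted = truth))
  })
}

#' Plant a labelled active/inactive screening library
#'
#' Actives contain planted-hit conformers (plus one energy decoy);
#' inactives contain only decoys, cycling the clash probe through the
#' three hydrogen classes so radius tuning is informative: each clash
#' probe sits just inside its class radius under the model's map and just
#' outside it under the Bondi map, making the library separable exactly at
#' the map the model was built with.
#'
#' @param model A screening-ready [pharmacophore()].
#' @param n_actives,n_inactives Ligand counts (>= 1 each).
#' @param seed Integer seed.
#' @param dE_cutoff Energy cutoff, kcal/mol.
#' @return List of [ligand_ensemble()] objects with activity labels and a
#'   `truth` attribute per ensemble.
#' @export
make_labeled_library <- function(model, n_actives = 15L, n_inactives = 10L,
                                 seed = 1L, dE_cutoff = 4.0) {
  stopifnot(n_actives >= 1L, n_inactives >= 1L)
  specs <- c(
    map(seq_len(n_actives), function(i)
      list(id = sprintf("active-%02d", i),
           spec = planted_spec(n_active = 3L, n_tolerance = 0L,
                               n_clash = 0L, n_energy = 1L, jitter = 0,
                               seed = seed * 10000L + i))),
    map(seq_len(n_inactives), function(i)
      list(id = sprintf("inactive-%02d", i),
           spec = planted_spec(n_active = 0L, n_tolerance = 1L,
                               n_clash = 1L, n_energy = 1L, jitter = 0,
                               seed = seed * 10000L + 5000L + i),
           clash_class = c("aliphatic", "aromatic", "polar")[1L + (i - 1L) %% 3L])))
  map(specs, function(s) {
    pl <- make_planted_library_member(model, s, dE_cutoff)
    ens <- pl$ensemble
    ens$id <- s$id
    attr(ens, "truth") <- pl$truth
    ens
  })
}

# library members re-use the planted-ensemble machinery; inactive members
# plant their single clash decoy just inside the requested class radius
make_planted_library_member <- function(model, s, dE_cutoff) {
  if (is.null(s$clash_class))
    return(make_planted_ensemble(model, s$spec, dE_cutoff, id = s$id))
  topo <- planted_topology()
  fc <- feature_centers(model)
  with_local_seed(s$spec$seed, {
    probes0 <- probe_positions(model)
    # clash decoy: one class probe at radius - 0.15 (inside under the
    # model's map, outside under smaller maps)
    delta <- c(aliphatic = 0.15, aromatic = 0.15, polar = 0.15)
    delta[[s$clash_class]] <- -0.15
    probes_in <- probe_positions(model, delta = delta)
    co_clash <- planted_coords(fc$aromatic, fc$cation, fc$donor, probes_in)
    fate <- planted_fate(model, topo, co_clash, dE_cutoff)
    if (fate$hit || fate$reason != "clash")
      abort("infeasible placement: library clash decoy not rejected as clash")
    co_tol <- make_tolerance_decoy(model, fc, topo, probes0, dE_cutoff)
    co_energy <- planted_coords(fc$aromatic, fc$cation, fc$donor, probes0)
    ens <- ligand_ensemble(
      s$id, topo$atoms, topo$bonds,
      list(co_clash, co_tol, co_energy), rel_energy = rep(0, 3),
      activity = "inactive")
    ens$rel_energy <- round(c(0, runif(1, 0, dE_cutoff * 0.8),
                              dE_cutoff + 1 + runif(1)), 4)
    list(ensemble = ens,
         truth = tibble(conformer = 1:3,
                        planted = c("clash", "tolerance", "energy")))
  })
}
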