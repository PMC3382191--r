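# In-code fixtures shared across test files.  All structures are built
# programmatically; nothing binary is stored.

atom_tbl <- phoreseed:::new_atom_table

empty_bonds <- function() {
  tibble::tibble(a1 = integer(), a2 = integer(), order = character())
}

# minimal PDB text fixture: one glycine (5 atoms incl. one hydrogen) plus
# one HET atom
fixture_pdb_lines <- function(het = TRUE, hydrogens = TRUE) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       3.200   1.600   0.000  1.00  0.00           O")
  lines <- c(lines, if (hydrogens)
    "ATOM      5  H   GLY A   1      -0.500  -0.800   0.000  1.00  0.00           H"
    else
    "ATOM      5  CB  GLY A   1      -0.500  -0.800   0.000  1.00  0.00           C")
  if (het) lines <- c(lines,
    "HETATM    6  C1  LIG A 900       0.500   3.000   0.000  1.00  0.00           C")
  c(lines, "END")
}

write_fixture_pdb <- function(path, ...) {
  writeLines(fixture_pdb_lines(...), path)
  path
}

# multi-record SDF text with a given energy per record (same 4-atom
# topology: N+ - C - O - H)
fixture_sdf_lines <- function(energies, tag = "rel_energy", shift = 0,
                              drop_tag_on = integer()) {
  unlist(lapply(seq_along(energies), function(i) {
    dx <- shift * (i - 1)
    c("fixmol", "  test", "",
      "  4  3  0  0  0  0  0  0  0  0999 V2000",
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              c(0 + dx, 1.45 + dx, 2.10 + dx, 2.50 + dx),
              c(0, 0, 1.2, 1.9), rep(0, 4), c("N", "C", "O", "H")),
      "  1  2  1  0", "  2  3  1  0", "  3  4  1  0",
      "M  CHG  1   1   1",
      "M  END",
      if (!(i %in% drop_tag_on))
        c(paste0(">  <", tag, ">"), format(energies[i]), ""),
      "$$$$")
  }))
}

write_fixture_sdf <- function(path, ...) {
  writeLines(fixture_sdf_lines(...), path)
  path
}

# dopamine topology (catechol ring, ethylamine, protonated N) with an
# idealised planar-ring geometry; used for perception tests
dopamine_fixture <- function() {
  cx <- make_toy_complex(1)
  list(atoms = cx$ligand, bonds = cx$ligand_bonds)
}

# benzene: 6 aromatic C (Kekule) + 6 H
benzene_fixture <- function() {
  ang <- (0:5) * pi / 3
  pos_c <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  pos_h <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  atoms <- atom_tbl(1:12, c(paste0("C", 1:6), paste0("H", 1:6)),
                    c(rep("C", 6), rep("H", 6)), "BNZ", 1L, "A",
                    c(pos_c[, 1], pos_h[, 1]), c(pos_c[, 2], pos_h[, 2]),
                    c(pos_c[, 3], pos_h[, 3]))
  bonds <- tibble::tibble(
    a1 = c(1:6, 1:6), a2 = c(2:6, 1L, 7:12),
    order = c(rep(c("2", "1"), 3), rep("1", 6)))
  list(atoms = atoms, bonds = bonds)
}

methane_fixture <- function() {
  atoms <- atom_tbl(1:5, c("C1", paste0("H", 1:4)), c("C", rep("H", 4)),
                    "MET", 1L, "A",
                    c(0, 0.63, -0.63, 0.63, -0.63),
                    c(0, 0.63, -0.63, -0.63, 0.63),
                    c(0, 0.63, 0.63, -0.63, -0.63))
  bonds <- tibble::tibble(a1 = rep(1L, 4), a2 = 2:5, order = rep("1", 4))
  list(atoms = atoms, bonds = bonds)
}

# small random rigid transform utilities
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(X, R, t) sweep(as.matrix(X) %*% t(R), 2, t, "+")

# unpruned exhaustive matcher oracle: enumerate every injective
# kind-compatible assignment covering all essentials, superpose, test
# tolerances and clashes directly
oracle_match <- function(model, points, heavy, elements) {
  feats <- model$features
  nf <- nrow(feats)
  assigns <- list()
  recurse <- function(i, sigma, used) {
    if (i > nf) {
      assigns[[length(assigns) + 1L]] <<- sigma
      return(invisible())
    }
    for (p in which(points$kind == feats$kind[i] & !used)) {
      used[p] <- TRUE; sigma[i] <- p
      recurse(i + 1L, sigma, used)
      used[p] <- FALSE; sigma[i] <- NA_integer_
    }
    if (!feats$essential[i]) recurse(i + 1L, sigma, used)
  }
  recurse(1L, rep(NA_integer_, nf), logical(nrow(points)))
  fpos <- cbind(feats$x, feats$y, feats$z)
  ppos <- cbind(points$x, points$y, points$z)
  best <- NULL
  for (sigma in assigns) {
    m <- which(!is.na(sigma))
    if (length(m) == 0L) next
    fit <- kabsch(ppos[sigma[m], , drop = FALSE], fpos[m, , drop = FALSE])
    resid <- sqrt(rowSums((fit$transform(ppos[sigma[m], , drop = FALSE]) -
                             fpos[m, , drop = FALSE])^2))
    if (any(resid > feats$tolerance[m])) next
    if (phoreseed:::volume_clash(model$volumes, fit$transform(heavy),
                                 elements)) next
    cand <- list(n = length(m), rmsd = fit$rmsd)
    if (is.null(best) || cand$n > best$n ||
        (cand$n == best$n && cand$rmsd < best$rmsd)) best <- cand
  }
  if (is.null(best)) list(hit = FALSE, rmsd = NA_real_)
  else list(hit = TRUE, rmsd = best$rmsd)
}

# random small matching instance for oracle-equivalence checks
random_match_instance <- function() {
  nf <- sample(1:4, 1)
  kinds_f <- sample(c("acceptor", "aromatic", "cation", "donor"), nf,
                    replace = TRUE)
  feats <- tibble::tibble(
    label = paste0("f", seq_len(nf)), kind = kinds_f,
    x = runif(nf, -4, 4), y = runif(nf, -4, 4), z = runif(nf, -4, 4),
    tolerance = runif(nf, 0.4, 1.2),
    essential = c(TRUE, runif(nf - 1) < 0.6))
  np <- sample(2:8, 1)
  pts <- tibble::tibble(
    kind = sample(c("acceptor", "aromatic", "cation", "donor"), np,
                  replace = TRUE),
    x = runif(np, -4, 4), y = runif(np, -4, 4), z = runif(np, -4, 4),
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    source_atoms = as.list(seq_len(np)))
  nv <- sample(0:3, 1)
  vols <- if (nv > 0) tibble::tibble(
    x = runif(nv, -4, 4), y = runif(nv, -4, 4), z = runif(nv, -4, 4),
    radius = runif(nv, 0.3, 1.2),
    mode = sample(c("all", "element"), nv, replace = TRUE, prob = c(.8, .2)),
    elements = lapply(seq_len(nv), function(i) "O"),
    class = rep("aliphatic", nv), provenance = rep("test", nv))
  else phoreseed:::empty_volumes()
  nh <- sample(1:6, 1)
  heavy <- matrix(runif(nh * 3, -4, 4), ncol = 3)
  elements <- sample(c("C", "N", "O"), nh, replace = TRUE)
  model <- pharmacophore(features = feats, volumes = vols)
  list(model = model, points = pts, heavy = heavy, elements = elements)
}
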