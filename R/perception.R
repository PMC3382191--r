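# Ligand annotation-point perception and hydrogen classification.
#
# Aromaticity is taken from input bond flags ("ar"/order 4) or from
# alternating Kekule patterns in 6-rings; no Huckel perception is attempted,
# since conformer generators deliver pre-typed topologies.

bond_adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bond_order_chr <- function(bonds) as.character(bonds$order)

#' Classify a hydrogen atom for excluded-volume radii
#'
#' Radii of receptor-derived excluded volumes depend on the hydrogen class:
#' a hydrogen on N/O/S is `polar`, on an aromatic carbon `aromatic`,
#' otherwise `aliphatic`.
#'
#' @param atom_index Index of the hydrogen in `atoms`.
#' @param atoms Atom tibble (needs `element`, `is_hydrogen`).
#' @param bonds Bond tibble (`a1`, `a2`, `order`).
#' @return One of `"polar"`, `"aromatic"`, `"aliphatic"`.
#' @export
classify_hydrogen <- function(atom_index, atoms, bonds) {
  if (!atoms$is_hydrogen[atom_index]) abort("not a hydrogen")
  adj <- bond_adjacency(nrow(atoms), bonds)
  nb <- adj[[atom_index]]
  nb <- nb[!atoms$is_hydrogen[nb]]
  if (length(nb) == 0L) abort("unbonded hydrogen")
  heavy <- nb[1]
  el <- toupper(atoms$element[heavy])
  if (el %in% c("N", "O", "S")) return("polar")
  if (el == "C" && heavy %in% unlist(aromatic_rings(atoms, bonds)))
    return("aromatic")
  "aliphatic"
}

# All 5-/6-membered aromatic rings: cycles whose bonds are all flagged
# aromatic, or 6-cycles with an alternating Kekule single/double pattern.
aromatic_rings <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (nrow(bonds) == 0L) return(list())
  ord <- bond_order_chr(bonds)
  bkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  omap <- setNames(ord, bkey(bonds$a1, bonds$a2))
  adj <- bond_adjacency(n, bonds)
  # drop hydrogens from the ring search
  rings <- list()
  seen <- character()
  find_cycles <- function(start) {
    # DFS for simple cycles of length 5 or 6 through `start`
    path <- integer()
    walk <- function(v) {
      path[[length(path) + 1L]] <<- v
      if (length(path) <= 6L) {
        for (w in adj[[v]]) {
          if (atoms$is_hydrogen[w]) next
          if (w == start && length(path) >= 5L) {
            cyc <- sort(path)
            key <- paste(cyc, collapse = ",")
            if (!(key %in% seen)) {
              seen <<- c(seen, key)
              rings[[length(rings) + 1L]] <<- path
            }
          } else if (!(w %in% path) && w > start) {
            walk(w)
          }
        }
      }
      path <<- path[-length(path)]
    }
    walk(start)
  }
  for (v in seq_len(n)) if (!atoms$is_hydrogen[v]) find_cycles(v)
  keep(rings, function(cyc) {
    k <- length(cyc)
    ords <- map_chr(seq_len(k), function(i) {
      a <- cyc[i]; b <- cyc[if (i == k) 1L else i + 1L]
      o <- omap[[bkey(a, b)]]
      if (is.null(o)) "0" else o
    })
    if (any(ords == "0")) return(FALSE)
    if (all(ords %in% c("ar", "4"))) return(TRUE)
    # alternating Kekule in 6-rings
    k == 6L && all(ords %in% c("1", "2")) &&
      (identical(ords, rep(c("1", "2"), 3)) ||
       identical(ords, rep(c("2", "1"), 3)))
  })
}

#' Centroid and unit normal of a ring
#'
#' The centroid is the unweighted mean of the ring positions; the normal is
#' the least-variance direction of the centred positions, sign-fixed to a
#' positive z component (positive x on a z tie).
#'
#' @param positions n x 3 matrix of ring atom positions (n >= 3,
#'   non-collinear).
#' @return List with `centroid` (length-3) and `normal` (unit length-3).
#' @export
ring_centroid_normal <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3L) abort("degenerate ring")
  centroid <- colMeans(positions)
  centred <- sweep(positions, 2, centroid)
  ev <- eigen(crossprod(centred), symmetric = TRUE)
  if (ev$values[2] < 1e-9 * max(ev$values[1], 1)) abort("degenerate ring")
  normal <- ev$vectors[, 3]
  if (normal[3] < 0 || (abs(normal[3]) < 1e-12 && normal[1] < 0))
    normal <- -normal
  if (abs(normal[3]) < 1e-12 && abs(normal[1]) < 1e-12 && normal[2] < 0)
    normal <- -normal
  list(centroid = as.numeric(centroid), normal = as.numeric(normal / vnorm(normal)))
}

#' Perceive typed annotation points on a conformer
#'
#' Applies the package's declared feature-typing conventions:
#' * `cation` at each nitrogen with formal charge +1 and at each neutral
#'   sp3 amine nitrogen (all single bonds, not an amide alpha-N, not an
#'   N-oxide);
#' * `donor` at each O-H or neutral N-H heavy atom, direction along the
#'   (lowest-index) hydrogen — a +1 nitrogen contributes a cation point
#'   only, its salt-bridge role being captured there;
#' * `acceptor` at each oxygen and each non-quaternary neutral nitrogen
#'   with an available lone pair;
#' * `aromatic` at the unweighted centroid of each 5-/6-membered aromatic
#'   ring, with unit ring normal.
#'
#' Output ordering is deterministic: by kind (alphabetical), then lowest
#' source atom index.
#'
#' @param atoms Atom tibble (topology; `element`, `is_hydrogen`,
#'   `formal_charge`).
#' @param bonds Bond tibble (`a1`, `a2`, `order`).
#' @param coords n x 3 matrix of conformer coordinates (defaults to the
#'   positions stored in `atoms`).
#' @return Tibble with columns `kind`, `x`, `y`, `z`, `dx`, `dy`, `dz`
#'   (unit direction or NA) and `source_atoms` (list column of atom
#'   indices).
#' @export
perceive_annotation_points <- function(atoms, bonds, coords = NULL) {
  n <- nrow(atoms)
  if (is.null(coords)) coords <- as_xyz_matrix(atoms)
  coords <- as.matrix(coords)
  pts <- list()
  add <- function(kind, pos, dir, src) {
    pos <- unname(pos)
    dir <- unname(dir)
    pts[[length(pts) + 1L]] <<- tibble(
      kind = kind, x = pos[1], y = pos[2], z = pos[3],
      dx = dir[1], dy = dir[2], dz = dir[3], source_atoms = list(sort(src)))
  }
  if (n == 0L) return(empty_points())
  adj <- bond_adjacency(n, bonds)
  ord <- bond_order_chr(bonds)
  rings <- aromatic_rings(atoms, bonds)
  ring_atoms <- unique(unlist(rings))
  el <- toupper(atoms$element)
  bond_orders_at <- function(i) {
    sel <- bonds$a1 == i | bonds$a2 == i
    ord[sel]
  }
  is_carbonyl_c <- function(i) {
    el[i] == "C" && any(map_lgl(seq_len(nrow(bonds)), function(k) {
      o <- ord[k]
      other <- if (bonds$a1[k] == i) bonds$a2[k]
               else if (bonds$a2[k] == i) bonds$a1[k] else return(FALSE)
      o == "2" && el[other] %in% c("O", "S")
    }))
  }
  for (i in seq_len(n)) {
    if (atoms$is_hydrogen[i]) next
    nb <- adj[[i]] %||% integer()
    hy <- nb[atoms$is_hydrogen[nb]]
    heavies <- nb[!atoms$is_hydrogen[nb]]
    orders <- bond_orders_at(i)
    pos <- coords[i, ]
    if (el[i] == "N") {
      charged <- atoms$formal_charge[i] > 0L
      in_ring <- i %in% ring_atoms
      all_single <- length(orders) == 0L || all(orders == "1")
      amide <- any(map_lgl(heavies, is_carbonyl_c))
      n_oxide <- any(el[heavies] == "O")
      if (charged) {
        add("cation", pos, c(NA_real_, NA_real_, NA_real_), i)
      } else {
        if (all_single && !in_ring && !amide && !n_oxide)
          add("cation", pos, c(NA_real_, NA_real_, NA_real_), i)
        if (length(hy) > 0L) {
          h <- min(hy)
          add("donor", pos, unit(coords[h, ] - pos), c(i, h))
        }
        quaternary <- length(nb) >= 4L
        if (!quaternary && all_single)
          add("acceptor", pos, c(NA_real_, NA_real_, NA_real_), i)
        if (in_ring && length(hy) == 0L)   # pyridine-type lone pair
          add("acceptor", pos, c(NA_real_, NA_real_, NA_real_), i)
      }
    } else if (el[i] == "O") {
      if (length(hy) > 0L) {
        h <- min(hy)
        add("donor", pos, unit(coords[h, ] - pos), c(i, h))
      }
      add("acceptor", pos, c(NA_real_, NA_real_, NA_real_), i)
    }
  }
  for (r in rings) {
    cn <- ring_centroid_normal(coords[r, , drop = FALSE])
    add("aromatic", cn$centroid, cn$normal, r)
  }
  if (length(pts) == 0L) return(empty_points())
  out <- bind_rows(pts)
  out$.first <- map_int(out$source_atoms, function(s) as.integer(min(s)))
  out <- arrange(out, factor(.data$kind, levels = POINT_KINDS), .data$.first)
  out$.first <- NULL
  out
}

empty_points <- function() {
  tibble(kind = character(), x = numeric(), y = numeric(), z = numeric(),
         dx = numeric(), dy = numeric(), dz = numeric(),
         source_atoms = list())
}
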