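# Conformer-vs-pharmacophore matching: correspondence enumeration, Kabsch
# rigid superposition, per-feature tolerance test, excluded-volume clash
# test, and ensemble-level screening summaries.
#
# Superposition moves the ligand (points + heavy atoms) into the
# pharmacophore frame; the receptor-derived excluded volumes never move.

#' Kabsch least-squares rigid superposition
#'
#' Returns the proper rigid transform (rotation, translation) minimising
#' the RMSD of `P` mapped onto `Q`; reflections are disallowed.  One point
#' gives a pure translation; two points the optimal axis rotation.
#'
#' @param P,Q n x 3 matrices of paired points (rows correspond).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`,
#'   and `transform(X)` applying the map to an m x 3 matrix.
#' @export
kabsch <- function(P, Q) {
  P <- matrix(as.numeric(P), ncol = 3)
  Q <- matrix(as.numeric(Q), ncol = 3)
  if (nrow(P) == 0L || nrow(P) != nrow(Q)) abort("point sets must be non-empty and paired")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (nrow(P) == 1L) {
    R <- diag(3)
  } else {
    H <- crossprod(Pc, Qc)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  tr <- as.numeric(cq - R %*% cp)
  mapped <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((mapped - Qc)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd,
       transform = function(X) sweep(as.matrix(X) %*% t(R), 2, tr, "+"))
}

#' Enumerate kind-compatible feature-to-point correspondences
#'
#' Yields every injective assignment of annotation points to features that
#' covers all essential features and any subset of optional ones, pruned by
#' pairwise distance compatibility: an assignment (i -> p, j -> q) survives
#' only if |d(feature_i, feature_j) - d(point_p, point_q)| <= tol_i + tol_j.
#' Enumeration order is deterministic.
#'
#' @param features Feature tibble.
#' @param points Annotation-point tibble.
#' @param prune Apply the pairwise distance filter (disable only for
#'   oracle-style exhaustive checks).
#' @return List of integer vectors, one entry per feature (point index or
#'   NA for an unmatched optional feature).
#' @export
enumerate_correspondences <- function(features, points, prune = TRUE) {
  nf <- nrow(features)
  if (nf == 0L) return(list())
  fpos <- as_xyz_matrix(features)
  ppos <- as_xyz_matrix(points)
  dff <- if (nf > 0L) cross_dist(fpos, fpos) else matrix(0, 0, 0)
  dpp <- if (nrow(points) > 0L) cross_dist(ppos, ppos) else matrix(0, 0, 0)
  # essentials first so dead ends are pruned early; restore order on output
  ord <- order(!features$essential, seq_len(nf))
  out <- list()
  assign_next <- function(k, sigma, used) {
    if (k > nf) {
      out[[length(out) + 1L]] <<- sigma[order(ord)]
      return(invisible())
    }
    i <- ord[k]
    cand <- which(points$kind == features$kind[i] & !used)
    for (p in cand) {
      ok <- TRUE
      if (prune) {
        for (k2 in seq_len(k - 1L)) {
          j <- ord[k2]
          if (is.na(sigma[k2])) next
          if (abs(dff[i, j] - dpp[p, sigma[k2]]) >
              features$tolerance[i] + features$tolerance[j]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        used[p] <- TRUE
        sigma[k] <- p
        assign_next(k + 1L, sigma, used)
        used[p] <- FALSE
        sigma[k] <- NA_integer_
      }
    }
    if (!features$essential[i]) assign_next(k + 1L, sigma, used)
    invisible()
  }
  assign_next(1L, rep(NA_integer_, nf), logical(nrow(points)))
  out
}

#' Match one conformer against a pharmacophore
#'
#' For every surviving correspondence the matched annotation points are
#' rigidly superposed onto the matched feature centers ([kabsch()]); the
#' match survives if every matched point lies within its feature's
#' tolerance sphere and, after applying the same transform to the ligand
#' heavy atoms, no atom center lies strictly inside an excluded volume
#' (mode `"all"`), or inside an element-specific volume whose element set
#' contains the atom's element.  Among survivors the one matching the most
#' optional features, then the lowest RMSD, wins.  RMSD is the root mean
#' square distance between feature centers and their matched annotation
#' points, over matched features only.
#'
#' @param model A [pharmacophore()] with at least one essential feature.
#' @param points Annotation-point tibble for this conformer.
#' @param heavy_atoms m x 3 matrix of ligand heavy-atom coordinates (ligand
#'   hydrogens are by convention not clash-tested).
#' @param elements Character vector of heavy-atom element symbols.
#' @return A `match_result`: list with `hit`, `correspondence` (tibble
#'   `feature`, `point`), `rotation`, `translation`, `rmsd`,
#'   `reject_reason` (`"none"`, `"no-correspondence"`, `"tolerance"`,
#'   `"clash"`).
#' @export
match_conformer <- function(model, points, heavy_atoms, elements) {
  features <- model$features
  if (nrow(features) == 0L || !any(features$essential))
    abort("model is not screening-ready: needs at least one essential feature")
  heavy_atoms <- matrix(as.numeric(heavy_atoms), ncol = 3)
  miss <- function(reason) {
    structure(list(hit = FALSE, correspondence = NULL, rotation = NULL,
                   translation = NULL, rmsd = NA_real_,
                   reject_reason = reason), class = "match_result")
  }
  if (nrow(points) == 0L) return(miss("no-correspondence"))
  corrs <- enumerate_correspondences(features, points)
  if (length(corrs) == 0L) return(miss("no-correspondence"))
  ppos <- as_xyz_matrix(points)
  fpos <- as_xyz_matrix(features)
  passed_tolerance <- FALSE
  best <- NULL
  for (sigma in corrs) {
    m <- which(!is.na(sigma))
    fit <- kabsch(ppos[sigma[m], , drop = FALSE], fpos[m, , drop = FALSE])
    resid <- sqrt(rowSums((fit$transform(ppos[sigma[m], , drop = FALSE]) -
                             fpos[m, , drop = FALSE])^2))
    if (any(resid > features$tolerance[m])) next
    passed_tolerance <- TRUE
    if (volume_clash(model$volumes, fit$transform(heavy_atoms), elements)) next
    cand <- list(sigma = sigma, n_matched = length(m), rmsd = fit$rmsd,
                 fit = fit)
    if (is.null(best) || cand$n_matched > best$n_matched ||
        (cand$n_matched == best$n_matched && cand$rmsd < best$rmsd))
      best <- cand
  }
  if (is.null(best))
    return(miss(if (passed_tolerance) "clash" else "tolerance"))
  m <- which(!is.na(best$sigma))
  structure(list(
    hit = TRUE,
    correspondence = tibble(feature = m, point = best$sigma[m]),
    rotation = best$fit$rotation, translation = best$fit$translation,
    rmsd = best$rmsd, reject_reason = "none"), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$hit)
    cat(sprintf("<match_result: HIT, %d features matched, rmsd %.3f>\n",
                nrow(x$correspondence), x$rmsd))
  else
    cat(sprintf("<match_result: miss (%s)>\n", x$reject_reason))
  invisible(x)
}

# TRUE if any atom center lies strictly inside an applicable volume
volume_clash <- function(volumes, atoms, elements) {
  if (nrow(volumes) == 0L || nrow(atoms) == 0L) return(FALSE)
  elements <- toupper(elements)
  for (i in seq_len(nrow(volumes))) {
    v <- volumes[i, ]
    sel <- if (v$mode == "element")
      elements %in% toupper(v$elements[[1]]) else rep(TRUE, nrow(atoms))
    if (!any(sel)) next
    d2 <- (atoms[sel, 1] - v$x)^2 + (atoms[sel, 2] - v$y)^2 +
      (atoms[sel, 3] - v$z)^2
    if (any(d2 < v$radius^2 - 1e-12)) return(TRUE)
  }
  FALSE
}

#' Screen every conformer of an ensemble
#'
#' Conformers with relative energy above `dE_cutoff` (inclusive comparison:
#' boundary conformers count) are excluded from screening and labelled
#' `reject_reason = "energy"`.
#'
#' @param model A [pharmacophore()].
#' @param ensemble A [ligand_ensemble()].
#' @param dE_cutoff Energy cutoff, kcal/mol (default 4.0, the MOE-ensemble
#'   convention; the MacroModel 16.7 kJ/mol cutoff converts to the same
#'   value up to rounding).
#' @return Tibble with one row per conformer: `conformer`, `rel_energy`,
#'   `screened`, `hit`, `rmsd`, `reject_reason`, `n_matched`.
#' @export
screen_conformers <- function(model, ensemble, dE_cutoff = 4.0) {
  if (length(ensemble$conformers) == 0L)
    return(tibble(conformer = integer(), rel_energy = numeric(),
                  screened = logical(), hit = logical(), rmsd = numeric(),
                  reject_reason = character(), n_matched = integer()))
  heavy_idx <- which(!ensemble$atoms$is_hydrogen)
  rows <- map(seq_along(ensemble$conformers), function(i) {
    e <- ensemble$rel_energy[i]
    if (e > dE_cutoff)
      return(tibble(conformer = i, rel_energy = e, screened = FALSE,
                    hit = FALSE, rmsd = NA_real_, reject_reason = "energy",
                    n_matched = NA_integer_))
    co <- ensemble$conformers[[i]]
    pts <- perceive_annotation_points(ensemble$atoms, ensemble$bonds, co)
    res <- match_conformer(model, pts, co[heavy_idx, , drop = FALSE],
                           ensemble$atoms$element[heavy_idx])
    tibble(conformer = i, rel_energy = e, screened = TRUE, hit = res$hit,
           rmsd = res$rmsd, reject_reason = res$reject_reason,
           n_matched = if (res$hit) nrow(res$correspondence) else NA_integer_)
  })
  bind_rows(rows)
}

#' Screen an ensemble into a Table-style summary row
#'
#' `n_conformers` counts conformers within the energy cutoff; `n_hits`
#' those that match the model.  The best hit is the hit of lowest relative
#' energy (ties broken by lower RMSD) and supplies `best_dE`/`best_rmsd`;
#' both are NA when nothing hits.
#'
#' @inheritParams screen_conformers
#' @return One-row tibble: `ligand_id`, `activity`, `n_conformers`,
#'   `n_hits`, `best_dE`, `best_rmsd`.
#' @export
screen_ensemble <- function(model, ensemble, dE_cutoff = 4.0) {
  det <- screen_conformers(model, ensemble, dE_cutoff)
  hits <- filter(det, .data$hit)
  best_dE <- NA_real_
  best_rmsd <- NA_real_
  if (nrow(hits) > 0L) {
    hits <- arrange(hits, .data$rel_energy, .data$rmsd)
    best_dE <- hits$rel_energy[1]
    best_rmsd <- hits$rmsd[1]
  }
  tibble(ligand_id = ensemble$id, activity = ensemble$activity,
         n_conformers = sum(det$screened), n_hits = nrow(hits),
         best_dE = best_dE, best_rmsd = best_rmsd)
}

#' Screen a library of ensembles
#'
#' @param model A [pharmacophore()].
#' @param ensembles List of [ligand_ensemble()] objects.
#' @param dE_cutoff Energy cutoff, kcal/mol.
#' @return Tibble of [screen_ensemble()] rows, one per ligand, with class
#'   `screen_result`.
#' @export
screen_library <- function(model, ensembles, dE_cutoff = 4.0) {
  out <- bind_rows(map(ensembles, screen_ensemble, model = model,
                       dE_cutoff = dE_cutoff))
  class(out) <- c("screen_result", class(out))
  out
}

#' Active/inactive discrimination of a screen
#'
#' A ligand counts as a hit when `n_hits >= hit_min`.  Returns the active
#' hit fraction, the inactive hit fraction, and their difference as the
#' discrimination score (1 = perfect separation, 0 = no discrimination).
#'
#' @param rows Screen-row tibble with an `activity` column.
#' @param active_set Activity labels counted as active (default `"full"`).
#' @param inactive_set Labels counted as inactive.
#' @param hit_min Minimum `n_hits` for a ligand-level hit.
#' @return List with `active_hit_fraction`, `inactive_hit_fraction`,
#'   `score`.
#' @export
discrimination_score <- function(rows, active_set = "full",
                                 inactive_set = "inactive", hit_min = 1L) {
  act <- filter(rows, .data$activity %in% active_set)
  ina <- filter(rows, .data$activity %in% inactive_set)
  if (nrow(act) == 0L || nrow(ina) == 0L)
    abort("degenerate label sets: need at least one active and one inactive")
  af <- mean(act$n_hits >= hit_min)
  inf_ <- mean(ina$n_hits >= hit_min)
  list(active_hit_fraction = af, inactive_hit_fraction = inf_,
       score = af - inf_)
}
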