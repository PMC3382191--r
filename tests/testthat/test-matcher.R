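test_that("kabsch recovers exact rigid transforms and handles small n", {
  set.seed(1)
  P <- matrix(runif(12, -3, 3), ncol = 3)
  # identity
  fit <- kabsch(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # constructed rotation + translation recovered exactly
  theta <- pi / 2
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  Q <- apply_rigid(P, R, c(1, 2, 3))
  fit2 <- kabsch(P, Q)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit2$rotation, R, tolerance = 1e-9)
  expect_equal(fit2$transform(P), Q, tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  # one point: pure translation
  fit1 <- kabsch(matrix(c(1, 1, 1), 1), matrix(c(4, 5, 6), 1))
  expect_equal(fit1$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit1$translation, c(3, 4, 5))
  # two points: optimal axis alignment, no reflection
  P2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  Q2 <- rbind(c(0, 0, 0), c(0, 2, 0))
  fit2p <- kabsch(P2, Q2)
  expect_equal(fit2p$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit2p$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(P[0, ], P[0, ]), "non-empty")
})

test_that("kabsch beats a large random-rotation search", {
  set.seed(7)
  for (case in 1:3) {
    P <- matrix(runif(15, -3, 3), ncol = 3)
    Q <- matrix(runif(15, -3, 3), ncol = 3)
    best <- kabsch(P, Q)$rmsd
    Pc <- sweep(P, 2, colMeans(P))
    Qc <- sweep(Q, 2, colMeans(Q))
    # stochastic lower-bound: no random rotation does better than the
    # analytic optimum (within numerical slack)
    found <- Inf
    for (i in 1:20000) {
      R <- random_rotation()
      r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
      if (r < found) found <- r
    }
    expect_true(best <= found + 1e-9)
    expect_true(found - best < 0.05 * max(found, 1))
  }
})

test_that("correspondence enumeration counts forced and multiple matches", {
  mk_feats <- function(kinds, ess = TRUE) tibble::tibble(
    label = paste0("f", seq_along(kinds)), kind = kinds,
    x = seq_along(kinds) * 2, y = 0, z = 0,
    tolerance = 1, essential = ess)
  mk_pts <- function(kinds, xs) tibble::tibble(
    kind = kinds, x = xs, y = 0, z = 0, dx = NA_real_, dy = NA_real_,
    dz = NA_real_, source_atoms = as.list(seq_along(kinds)))
  # 3 essential features of distinct kinds, 3 matching points -> 1
  f3 <- mk_feats(c("cation", "aromatic", "donor"))
  p3 <- mk_pts(c("cation", "aromatic", "donor"), c(2, 4, 6))
  expect_equal(length(enumerate_correspondences(f3, p3)), 1)
  # 1 essential aromatic feature, 2 aromatic points -> 2
  f1 <- mk_feats("aromatic")
  p2 <- mk_pts(c("aromatic", "aromatic"), c(2, 2.5))
  expect_equal(length(enumerate_correspondences(f1, p2)), 2)
})

test_that("pruned enumeration equals brute force filtered by the same predicate", {
  set.seed(11)
  for (case in 1:20) {
    inst <- random_match_instance()
    feats <- inst$model$features
    pts <- inst$points
    got <- enumerate_correspondences(feats, pts)
    all_sigma <- enumerate_correspondences(feats, pts, prune = FALSE)
    dff <- as.matrix(dist(cbind(feats$x, feats$y, feats$z)))
    dpp <- as.matrix(dist(cbind(pts$x, pts$y, pts$z)))
    ok <- Filter(function(sigma) {
      m <- which(!is.na(sigma))
      if (length(m) < 2) return(TRUE)
      for (i in m) for (j in m) {
        if (i >= j) next
        if (abs(dff[i, j] - dpp[sigma[i], sigma[j]]) >
            feats$tolerance[i] + feats$tolerance[j]) return(FALSE)
      }
      TRUE
    }, all_sigma)
    key <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_equal(key(got), key(ok))
  }
})

test_that("match decisions follow tolerance, clash and ExclO semantics", {
  feats <- tibble::tibble(
    label = c("A", "B", "C"), kind = c("cation", "aromatic", "donor"),
    x = c(0, 3, 0), y = c(0, 0, 4), z = 0, tolerance = 1,
    essential = TRUE)
  pts <- tibble::tibble(
    kind = c("cation", "aromatic", "donor"),
    x = c(0, 3, 0), y = c(0, 0, 4), z = 0,
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    source_atoms = list(1L, 2L, 3L))
  heavy <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1.5, 1.5, 0))
  elems <- c("N", "C", "O", "C")
  m0 <- pharmacophore(features = feats)
  r0 <- match_conformer(m0, pts, heavy, elems)
  expect_true(r0$hit)
  expect_equal(r0$rmsd, 0, tolerance = 1e-9)
  # all-mode volume on a heavy atom -> clash
  vol_all <- tibble::tibble(x = 1.5, y = 1.5, z = 0, radius = 0.5,
                            mode = "all", elements = list(character()),
                            class = "aliphatic", provenance = "t")
  m1 <- pharmacophore(features = feats, volumes = vol_all)
  r1 <- match_conformer(m1, pts, heavy, elems)
  expect_false(r1$hit)
  expect_equal(r1$reject_reason, "clash")
  # oxygen-specific volume must not block a carbon
  vol_o <- dplyr::mutate(vol_all, mode = "element", elements = list("O"))
  m2 <- pharmacophore(features = feats, volumes = vol_o)
  r2 <- match_conformer(m2, pts, heavy, elems)
  expect_true(r2$hit)
  # but it blocks an oxygen at the same position
  elems_o <- c("N", "C", "O", "O")
  r3 <- match_conformer(m2, pts, heavy, elems_o)
  expect_false(r3$hit)
  expect_equal(r3$reject_reason, "clash")
  # no kind-compatible points
  pts_wrong <- dplyr::mutate(pts, kind = "acceptor")
  r4 <- match_conformer(m0, pts_wrong, heavy, elems)
  expect_false(r4$hit)
  expect_equal(r4$reject_reason, "no-correspondence")
})

test_that("footnote-style RMSD is the closed-form root mean square residual", {
  # two matched features at residuals 0.6 and 0.8 -> rmsd sqrt(0.5) = 0.7071
  feats <- tibble::tibble(
    label = c("A", "B"), kind = c("cation", "donor"),
    x = c(0, 10), y = 0, z = 0, tolerance = 1, essential = TRUE)
  # points displaced perpendicular to the A-B axis keep the optimal fit at
  # the construction: residuals 0.6 / 0.8 up to the fit's centering
  p <- rbind(c(0, 0.6, 0), c(10, -0.8, 0))
  fit <- kabsch(p, cbind(feats$x, feats$y, feats$z))
  expect_true(fit$rmsd <= sqrt((0.36 + 0.64) / 2) + 1e-9)
  expect_equal(sqrt((0.36 + 0.64) / 2), 0.7071068, tolerance = 1e-6)
  # direct formula check on fixed residuals
  expect_equal(sqrt(mean(c(0.6, 0.8)^2)), 0.70710678, tolerance = 1e-8)
})

test_that("match_conformer equals the exhaustive oracle on random instances", {
  set.seed(101)
  n_agree <- 0
  for (case in 1:60) {
    inst <- random_match_instance()
    got <- match_conformer(inst$model, inst$points, inst$heavy,
                           inst$elements)
    want <- oracle_match(inst$model, inst$points, inst$heavy, inst$elements)
    expect_equal(got$hit, want$hit)
    if (got$hit) expect_equal(got$rmsd, want$rmsd, tolerance = 1e-6)
    n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 60)
})

test_that("hit status and rmsd are invariant under rigid motion of the conformer", {
  cx <- make_toy_complex(1)
  model <- build_model(cx)
  pl <- make_planted_ensemble(model, planted_spec(2, 1, 1, 0, jitter = 0.25,
                                                  seed = 13))
  ens <- pl$ensemble
  heavy_idx <- which(!ens$atoms$is_hydrogen)
  set.seed(77)
  for (i in seq_along(ens$conformers)) {
    co <- ens$conformers[[i]]
    pts <- perceive_annotation_points(ens$atoms, ens$bonds, co)
    base <- match_conformer(model, pts, co[heavy_idx, ],
                            ens$atoms$element[heavy_idx])
    R <- random_rotation()
    t <- runif(3, -10, 10)
    co2 <- apply_rigid(co, R, t)
    pts2 <- perceive_annotation_points(ens$atoms, ens$bonds, co2)
    moved <- match_conformer(model, pts2, co2[heavy_idx, ],
                             ens$atoms$element[heavy_idx])
    expect_equal(moved$hit, base$hit)
    if (base$hit) expect_equal(moved$rmsd, base$rmsd, tolerance = 1e-6)
  }
})

test_that("screening an ensemble applies the inclusive energy cutoff", {
  cx <- make_toy_complex(1)
  model <- build_model(cx)
  pl <- make_planted_ensemble(model, planted_spec(3, 0, 0, 0, jitter = 0.1,
                                                  seed = 21))
  ens <- pl$ensemble
  ens$rel_energy <- c(0, 2, 5)
  row <- screen_ensemble(model, ens, dE_cutoff = 4.0)
  expect_equal(row$n_conformers, 2)
  expect_equal(row$n_hits, 2)
  expect_equal(row$best_dE, 0)
  # boundary conformer counts (inclusive)
  ens$rel_energy <- c(0, 4, 5)
  expect_equal(screen_ensemble(model, ens, 4.0)$n_conformers, 2)
  # empty ensemble
  ens0 <- ligand_ensemble("none", ens$atoms, ens$bonds, list(), numeric())
  row0 <- screen_ensemble(model, ens0)
  expect_equal(row0$n_conformers, 0)
  expect_equal(row0$n_hits, 0)
  expect_true(is.na(row0$best_dE) && is.na(row0$best_rmsd))
})

test_that("discrimination score reproduces the published hit-rate arithmetic", {
  # 14 of 15 actives hit, 2 of 10 inactives hit
  rows <- tibble::tibble(
    ligand_id = paste0("l", 1:25),
    activity = c(rep("full", 15), rep("inactive", 10)),
    n_conformers = 10L,
    n_hits = c(rep(1L, 14), 0L, rep(1L, 2), rep(0L, 8)),
    best_dE = NA_real_, best_rmsd = NA_real_)
  sc <- discrimination_score(rows)
  expect_equal(sc$active_hit_fraction, 14 / 15, tolerance = 1e-9)
  expect_equal(sc$inactive_hit_fraction, 0.2, tolerance = 1e-9)
  expect_equal(sc$score, 14 / 15 - 0.2, tolerance = 1e-9)
  expect_equal(round(sc$active_hit_fraction, 4), 0.9333)
  # perfect and null separation
  rows2 <- dplyr::mutate(rows, n_hits = ifelse(activity == "full", 1L, 0L))
  expect_equal(discrimination_score(rows2)$score, 1.0)
  rows3 <- dplyr::mutate(rows, n_hits = 1L)
  expect_equal(discrimination_score(rows3)$score, 0.0)
  expect_error(discrimination_score(rows[1:15, ]), "degenerate label sets")
})

test_that("monotonicity: volumes, essentiality and cutoff move hits one way", {
  cx <- make_toy_complex(1)
  model <- build_model(cx)
  set.seed(3)
  for (s in 1:6) {
    pl <- make_planted_ensemble(model, planted_spec(2, 1, 1, 1,
                                                    jitter = 0.2,
                                                    seed = 30 + s))
    ens <- pl$ensemble
    base <- screen_ensemble(model, ens)$n_hits
    # enlarging every volume radius can only lose hits
    bigger <- model
    bigger$volumes$radius <- bigger$volumes$radius + runif(1, 0.2, 1.0)
    expect_lte(screen_ensemble(bigger, ens)$n_hits, base)
    # adding a volume can only lose hits
    extra <- model
    extra$volumes <- dplyr::bind_rows(
      extra$volumes,
      tibble::tibble(x = runif(1, -3, 5), y = runif(1, -3, 3),
                     z = runif(1, -1, 3), radius = runif(1, 0.5, 2),
                     mode = "all", elements = list(character()),
                     class = "aliphatic", provenance = "extra"))
    expect_lte(screen_ensemble(extra, ens)$n_hits, base)
    # demoting essential -> optional can only gain hits
    demoted <- demote_feature(model, "Ser-TM5")
    expect_gte(screen_ensemble(demoted, ens)$n_hits, base)
    # raising the energy cutoff can only gain hits
    expect_gte(screen_ensemble(model, ens, dE_cutoff = 6)$n_hits, base)
    expect_lte(screen_ensemble(model, ens, dE_cutoff = 1)$n_hits, base)
  }
})
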