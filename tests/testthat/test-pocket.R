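test_that("pocket volume matches the analytic sphere and converges with spacing", {
  lig <- atom_tbl(1L, "C1", "C", "LIG", 1L, "A", 0, 0, 0)
  rec <- atom_tbl(1:2, c("CA", "HA"), c("C", "H"), "GLY", 1L, "A",
                  c(50, 51), 0, 0)   # receptor far away: no blocking
  cx <- structure_complex(rec, lig, empty_bonds())
  v_true <- 4 / 3 * pi * 4^3
  v025 <- pocket_volume(cx, grid_spacing = 0.25, shell = 4.0)
  expect_lt(abs(v025 - v_true) / v_true, 0.05)
  # grid convergence on a non-trivial pocket
  cx2 <- make_toy_complex(2)
  v_a <- pocket_volume(cx2, grid_spacing = 0.5)
  v_b <- pocket_volume(cx2, grid_spacing = 0.25)
  expect_lt(abs(v_a - v_b) / v_b, 0.05)
  expect_error(pocket_volume(cx2, grid_spacing = 0), "spacing")
})

test_that("pocket volume shrinks to zero inside a closing cage", {
  lig <- atom_tbl(1L, "C1", "C", "LIG", 1L, "A", 0, 0, 0)
  # octahedral cage of fat pseudo-atoms closing in on the ligand
  cage <- function(d) {
    pos <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0), c(0, -d, 0),
                 c(0, 0, d), c(0, 0, -d))
    pos <- rbind(pos, pos * 0.99 + 0.01)  # fill gaps a little
    atom_tbl(seq_len(nrow(pos) + 1),
             c(paste0("S", seq_len(nrow(pos))), "H1"),
             c(rep("S", nrow(pos)), "H"),
             "CAG", 1L, "A", c(pos[, 1], 9), c(pos[, 2], 9),
             c(pos[, 3], 9))
  }
  v_open <- pocket_volume(structure_complex(cage(4.5), lig, empty_bonds()),
                          grid_spacing = 0.5)
  v_tight <- pocket_volume(structure_complex(cage(2.0), lig, empty_bonds()),
                           grid_spacing = 0.5)
  expect_lt(v_tight, v_open)
  v_closed <- pocket_volume(structure_complex(cage(1.2), lig, empty_bonds()),
                            grid_spacing = 0.5)
  expect_lt(v_closed, 10)
})

test_that("pocket volume is rigid-motion invariant up to discretisation", {
  cx <- make_toy_complex(1)
  v0 <- pocket_volume(cx, grid_spacing = 0.5)
  set.seed(5)
  R <- random_rotation()
  t <- c(3.1, -2.2, 1.7)
  move <- function(df) {
    m <- apply_rigid(cbind(df$x, df$y, df$z), R, t)
    df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
    df
  }
  cx2 <- cx
  cx2$receptor <- move(cx$receptor)
  cx2$ligand <- move(cx$ligand)
  v1 <- pocket_volume(cx2, grid_spacing = 0.5)
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("conservation is strict identity through the column map", {
  cm <- alignment_column_map(c(a = "SDF", b = "CDF"))
  pocket <- tibble::tibble(index_a = 1:3, aa = c("S", "D", "F"))
  got <- conservation_map(pocket, cm, "CDF")
  expect_equal(got$conserved, c(FALSE, TRUE, TRUE))
  # residue aligned to a gap is not conserved
  cm2 <- alignment_column_map(c(a = "AC", b = "A-"))
  got2 <- conservation_map(tibble::tibble(index_a = 1:2, aa = c("A", "C")),
                           cm2, "A")
  expect_equal(got2$conserved, c(TRUE, FALSE))
  # flags always partition the pocket
  expect_equal(sum(got$conserved) + sum(!got$conserved), nrow(got))
  # out-of-span residue errors
  expect_error(conservation_map(tibble::tibble(index_a = 9L, aa = "A"),
                                cm2, "A"), "outside alignment span")
})

test_that("a planted 22-residue pocket reports exactly its 10 substitutions", {
  set.seed(8)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "A", "S")
  stopifnot(length(aa) == 22)
  bb <- aa
  swap <- sample(22, 10)
  repl <- c(A = "G", R = "K", N = "H", D = "E", C = "S", Q = "N", E = "D",
            G = "A", H = "N", I = "V", L = "N", K = "R", M = "L", F = "Y",
            P = "A", S = "I", T = "S", W = "F", Y = "F", V = "I")
  bb[swap] <- repl[aa[swap]]
  cm <- alignment_column_map(c(a = paste(aa, collapse = ""),
                               b = paste(bb, collapse = "")))
  got <- conservation_map(tibble::tibble(index_a = 1:22, aa = aa), cm,
                          paste(bb, collapse = ""))
  expect_equal(sum(!got$conserved), 10)
  expect_equal(sum(got$conserved), 12)
})

test_that("Ballesteros-Weinstein numbering is anchored at x.50", {
  hr <- tibble::tibble(helix = 3L, start = 95L, end = 130L, ref_seq = 121L)
  expect_equal(bw_number(103L, hr), "3.32")
  expect_equal(bw_number(121L, hr), "3.50")
  expect_equal(bw_number(107L, hr), "3.36")
  expect_true(is.na(bw_number(200L, hr)))
  # round trip: residue = ref + (nn - 50)
  nn <- as.integer(sub("^3\\.", "", bw_number(111L, hr)))
  expect_equal(121L + (nn - 50L), 111L)
})

test_that("interaction records honour their distance and angle thresholds", {
  # constructed O-H...O with heavy-heavy 2.7 and angle 178 degrees
  lig <- atom_tbl(1:2, c("O1", "HO1"), c("O", "H"), "LIG", 900L, "A",
                  x = c(0, 0.97), y = c(0, 0.02), z = 0)
  rec <- atom_tbl(1:2, c("OG", "HG"), c("O", "H"), "SER", 1L, "A",
                  x = c(2.7, 3.2), y = c(0, 0.8), z = 0)
  cx <- structure_complex(rec, lig,
                          tibble::tibble(a1 = 1L, a2 = 2L, order = "1"))
  ki <- report_key_interactions(cx)
  hb <- ki[ki$kind == "hbond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.7, tolerance = 1e-6)
  expect_gt(hb$angle, 175)
  # heavy-heavy 4.6 is outside the hydrogen-bond distance
  rec2 <- dplyr::mutate(rec, x = x + 1.9)
  cx2 <- structure_complex(rec2, lig,
                           tibble::tibble(a1 = 1L, a2 = 2L, order = "1"))
  expect_equal(nrow(dplyr::filter(report_key_interactions(cx2),
                                  kind == "hbond")), 0)
  # two non-bonded atoms at 2.5 make one close contact (2.6 is exclusive)
  lig3 <- atom_tbl(1L, "C1", "C", "LIG", 900L, "A", 0, 0, 0)
  rec3 <- atom_tbl(1:2, c("CA", "H"), c("C", "H"), "ALA", 1L, "A",
                   x = c(2.5, 6), y = 0, z = 0)
  cx3 <- structure_complex(rec3, lig3, empty_bonds())
  cc <- dplyr::filter(report_key_interactions(cx3), kind == "close-contact")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$distance, 2.5, tolerance = 1e-9)
  rec4 <- dplyr::mutate(rec3, x = c(2.6, 6))
  cx4 <- structure_complex(rec4, lig3, empty_bonds())
  expect_equal(nrow(dplyr::filter(report_key_interactions(cx4),
                                  kind == "close-contact")), 0)
})

test_that("the toy complex reports its designed salt bridge and ring stack", {
  cx <- make_toy_complex(1)
  ki <- report_key_interactions(cx)
  expect_true(any(ki$kind == "salt-bridge"))
  sb <- ki[ki$kind == "salt-bridge", ][1, ]
  expect_lt(sb$distance, 4.0)
  expect_true(any(ki$kind == "ring-stack-candidate"))
  hb <- ki[ki$kind == "hbond", ]
  expect_true(all(hb$angle >= 120 & hb$angle <= 180))
  expect_true(all(hb$distance <= 3.5))
})

test_that("pocket report assembles residues, volume and conservation", {
  cx <- make_toy_complex(1)
  hr <- tibble::tibble(helix = 5L, start = 1L, end = 3L, ref_seq = 1L)
  rep <- pocket_report(cx, cutoff = 3.5, helix_refs = hr)
  expect_s3_class(rep, "pocket_report")
  expect_equal(rep$n_residues, nrow(rep$residues))
  expect_gt(rep$volume, 0)
  expect_equal(rep$residues$bw[rep$residues$residue_seq == 1], "5.50")
  g <- glance(rep)
  expect_equal(g$n_residues, rep$n_residues)
})
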