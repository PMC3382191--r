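test_that("read_complex splits receptor and ligand and demands protons", {
  p <- write_fixture_pdb(withr::local_tempfile(fileext = ".pdb"))
  cx <- read_complex(p)
  expect_s3_class(cx, "structure_complex")
  expect_equal(nrow(cx$receptor), 5)
  expect_equal(nrow(cx$ligand), 1)
  expect_equal(sum(cx$receptor$is_hydrogen), 1)
  # coordinates preserved exactly as printed
  expect_identical(cx$ligand$x, 0.5)
  expect_identical(cx$receptor$x[2], 1.46)

  p2 <- write_fixture_pdb(withr::local_tempfile(fileext = ".pdb"),
                          het = FALSE)
  expect_error(read_complex(p2), "no ligand residue")

  p3 <- write_fixture_pdb(withr::local_tempfile(fileext = ".pdb"),
                          hydrogens = FALSE)
  expect_error(read_complex(p3), "not protonated")
})

test_that("complex PDB round trip preserves atoms, names and topology", {
  cx <- make_toy_complex(3)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_complex(cx, p)
  cx2 <- read_complex(p)
  expect_equal(nrow(cx2$receptor), nrow(cx$receptor))
  expect_equal(cx2$receptor$name, cx$receptor$name)
  expect_equal(cx2$ligand$name, cx$ligand$name)
  for (col in c("x", "y", "z")) {
    expect_equal(cx2$receptor[[col]], cx$receptor[[col]], tolerance = 1e-9)
    expect_equal(cx2$ligand[[col]], cx$ligand[[col]], tolerance = 1e-9)
  }
  # bond sets identical up to row order
  canon <- function(b) dplyr::arrange(
    dplyr::transmute(b, lo = pmin(a1, a2), hi = pmax(a1, a2),
                     order = as.character(order)), lo, hi)
  expect_equal(canon(cx2$ligand_bonds), canon(cx$ligand_bonds))
})

test_that("ensemble energies are converted to kcal/mol and re-based", {
  p <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"),
                         energies = c(10, 12, 14))
  ens <- read_ligand_ensemble(p)
  expect_equal(ens$rel_energy, c(0, 2, 4))
  expect_equal(length(ens$conformers), 3)
  expect_equal(ens$atoms$formal_charge, c(1L, 0L, 0L, 0L))

  p2 <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"),
                          energies = c(0, 16.7))
  ens2 <- read_ligand_ensemble(p2, energy_unit = "kJ/mol")
  expect_equal(ens2$rel_energy, c(0, 16.7 / 4.184), tolerance = 1e-9)

  p3 <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"),
                          energies = c(1, 2), drop_tag_on = 2L)
  expect_error(read_ligand_ensemble(p3), "missing energy property")
})

test_that("energy re-basing is idempotent and unit paths agree", {
  p_kcal <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"),
                              energies = c(3, 5, 9) / 4.184)
  p_kj <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"),
                            energies = c(3, 5, 9))
  e_kcal <- read_ligand_ensemble(p_kcal)$rel_energy
  e_kj <- read_ligand_ensemble(p_kj, energy_unit = "kJ/mol")$rel_energy
  expect_equal(e_kcal, e_kj, tolerance = 1e-6)
  # re-basing twice equals once
  rebased <- e_kcal - min(e_kcal)
  expect_identical(rebased, e_kcal)
})

test_that("heterogeneous SDF topology is rejected", {
  lines1 <- fixture_sdf_lines(1)
  lines2 <- fixture_sdf_lines(2)
  lines2 <- sub("^  2  3  1  0$", "  2  4  1  0", lines2)
  p <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(lines1, lines2), p)
  expect_error(read_ligand_ensemble(p), "topology mismatch")
})

test_that("ligand ensemble SDF round trip is exact at format precision", {
  cx <- make_toy_complex(1)
  model <- build_model(cx)
  pl <- make_planted_ensemble(model, planted_spec(2, 1, 1, 1, jitter = 0.2,
                                                  seed = 7))
  p <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_ensemble(pl$ensemble, p)
  back <- read_ligand_ensemble(p, activity = pl$ensemble$activity)
  expect_equal(length(back$conformers), length(pl$ensemble$conformers))
  expect_equal(back$atoms$element, pl$ensemble$atoms$element)
  expect_equal(back$atoms$formal_charge, pl$ensemble$atoms$formal_charge)
  for (i in seq_along(back$conformers))
    expect_equal(unname(back$conformers[[i]]),
                 unname(pl$ensemble$conformers[[i]]), tolerance = 1e-9)
})

test_that("pharmacophore JSON round trip is identity to 1e-9", {
  cx <- make_toy_complex(2)
  m <- build_model(cx)
  p <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(m, p)
  m2 <- read_pharmacophore(p)
  expect_equal(m2$features, m$features, tolerance = 1e-9)
  expect_equal(m2$volumes$radius, m$volumes$radius, tolerance = 1e-9)
  expect_equal(m2$volumes$x, m$volumes$x, tolerance = 1e-9)
  expect_equal(unclass(m2$radius_map), unclass(m$radius_map))
  expect_equal(m2$ring_radius, m$ring_radius)

  # empty model round trips too
  m0 <- pharmacophore()
  write_pharmacophore(m0, p)
  m0b <- read_pharmacophore(p)
  expect_equal(nrow(m0b$features), 0)
  expect_equal(nrow(m0b$volumes), 0)

  # element-specific (ExclO) volumes survive the round trip
  mx <- pharmacophore(
    features = m$features,
    volumes = tibble::tibble(x = 1, y = 2, z = 3, radius = 1.5,
                             mode = "element", elements = list("O"),
                             class = "aliphatic", provenance = "ExclO"))
  write_pharmacophore(mx, p)
  mxb <- read_pharmacophore(p)
  expect_equal(mxb$volumes$mode, "element")
  expect_equal(mxb$volumes$elements[[1]], "O")
})

test_that("malformed pharmacophore JSON names the offending field", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(version = 1, features = list(
    list(label = "A", kind = "wiggly", center = c(0, 0, 0),
         tolerance = 1, essential = TRUE)), volumes = list(),
    radius_map = list(aliphatic = 1.5, aromatic = 1.3, polar = 1.3),
    ring_radius = 2.5), p, auto_unbox = TRUE)
  expect_error(read_pharmacophore(p), "unknown feature kind")
})

test_that("screen report TSV mirrors the hit-table layout with blank no-hit cells", {
  rows <- tibble::tibble(
    ligand_id = c("dopamine", "quinpirole"),
    activity = c("full", "inactive"),
    n_conformers = c(6L, 4L), n_hits = c(1L, 0L),
    best_dE = c(0.0, NA), best_rmsd = c(0.66, NA))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_screen_report(rows, p)
  txt <- readLines(p)
  expect_equal(txt[2], "dopamine\tfull\t6\t1\t0\t0.66")
  expect_equal(txt[3], "quinpirole\tinactive\t4\t0\t\t")
  back <- read_screen_report(p)
  expect_equal(as.data.frame(back), as.data.frame(rows))

  write_screen_report(rows[0, ], p)
  expect_equal(length(readLines(p)), 1L)  # header only
})

test_that("alignment column maps skip gaps and reject ragged input", {
  cm <- alignment_column_map(c(a = "AC-D", b = "ACED"))
  expect_equal(cm$index_a, c(1, 2, 3))
  expect_equal(cm$index_b, c(1, 2, 4))

  # all-gap column contributes no pair
  cm2 <- alignment_column_map(c(a = "A-C", b = "A-C"))
  expect_equal(nrow(cm2), 2)

  expect_error(alignment_column_map(c(a = "AC", b = "ACD")),
               "ragged alignment")

  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-D", ">b", "ACED"), p)
  expect_equal(read_alignment(p)$index_b, c(1, 2, 4))

  writeLines(c(">a", "ACD"), p)
  expect_error(read_alignment(p), "two sequences")

  # clustal format (canonical block layout)
  p2 <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL format alignment", "", "",
               "drd1            AC-DE", "drd2            ACEDE",
               "                **.**", ""), p2)
  cm3 <- read_alignment(p2)
  expect_equal(cm3$index_a, c(1, 2, 3, 4))
  expect_equal(cm3$index_b, c(1, 2, 4, 5))
})
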