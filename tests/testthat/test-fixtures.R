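test_that("planted bonds reproduce the requested geometry exactly", {
  sp <- plant_spec(noise_sigma = 0, bond_length = 1.33,
                   dihedrals = c(phi = -60, psi = 140, omega = 180),
                   burial = "exposed", seed = 50)
  p <- make_positive(sp)
  site <- isopeptider:::truth_site(p$truth)
  expect_equal(bond_length(p$structure, site), 1.33, tolerance = 1e-9)
  got <- pseudo_dihedrals(p$structure, site)
  expect_equal(unname(got), c(-60, 140, 180), tolerance = 1e-6)
  expect_error(make_positive(plant_spec(bond_length = -1)), "bond_length")
})

test_that("generators are deterministic to the byte", {
  sp <- plant_spec(noise_sigma = 0.3, seed = 60, n_decoy = 20)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(make_positive(sp)$structure, f1)
  write_structure_pdb(make_positive(sp)$structure, f2)
  expect_identical(readLines(f1), readLines(f2))

  n1 <- make_negative(30, seed = 61, library = lib6)
  n2 <- make_negative(30, seed = 61, library = lib6)
  expect_identical(n1$x, n2$x)
})

test_that("every planted site is recovered by the exhaustive matcher at sigma zero", {
  for (tt in c("Lys-Asn-Asp", "Lys-Asp-Glu", "Lys-Asn-Glu")) {
    p <- make_positive(plant_spec(triad_type = tt, noise_sigma = 0,
                                  burial = "exposed", n_decoy = 16,
                                  seed = 70))
    lib1 <- isopeptider:::template_from_structure(p$structure, p$truth, "self")
    lib1 <- structure(lib1, class = c("iso_template_library", class(lib1)))
    h <- find_matches_brute(p$structure, lib1)
    expect_equal(h$lys_resno, p$truth$lys_resno)
    expect_lt(h$rmsd, 1e-6)
  }
})

test_that("decoys carry matchable residue types yet produce no hits", {
  st <- make_negative(80, seed = 1, library = lib6)
  res <- dplyr::distinct(st, resno, resid)
  expect_gte(sum(res$resid %in% c("LYS", "ASN", "ASP", "GLU")), 4)
  expect_equal(nrow(find_matches(st, lib6)), 0)
})

test_that("burial control orders relative accessibility", {
  b <- make_positive(plant_spec(seed = 81, burial = "buried", n_decoy = 16))
  e <- make_positive(plant_spec(seed = 81, burial = "exposed", n_decoy = 16))
  site <- isopeptider:::truth_site(b$truth)
  expect_lt(compute_rasa(b$structure, site),
            compute_rasa(e$structure, site))
})

test_that("a small corpus is complete, self-consistent and reproducible", {
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- make_corpus(d1, n_pos = 3, n_neg = 2, seed = 9, n_ref = 40)
  expect_length(c1$structure_paths, 5)
  expect_equal(nrow(c1$truth), 3)
  expect_true(file.exists(file.path(d1, "truth.tsv")))
  lib <- load_template_library(c1$template_dir)
  expect_equal(nrow(lib), 12)
  ref <- read_geometry_reference(c1$geometry_reference)
  expect_setequal(names(ref), c("topology", "phi", "psi", "omega",
                                "bond_length"))

  c2 <- make_corpus(d2, n_pos = 3, n_neg = 2, seed = 9, n_ref = 40)
  for (rel in c(file.path("structures", basename(c1$structure_paths)),
                "truth.tsv", "geometry_reference.tsv")) {
    expect_identical(readLines(file.path(d1, rel)),
                     readLines(file.path(d2, rel)), label = rel)
  }
})
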