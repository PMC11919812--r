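test_that("PDB parsing keeps one altloc, drops waters, flags heteroatoms", {
  f <- write_mini_pdb(tempfile(fileext = ".pdb"))
  st <- read_structure(f)

  res <- dplyr::distinct(st, chain, resno, resid, nonstandard)
  expect_equal(nrow(res), 4)            # 3 protein residues + ligand, no water
  expect_false(any(st$resid == "HOH"))
  expect_true(res$nonstandard[res$resid == "LIG"])
  expect_false(any(res$nonstandard[res$resid != "LIG"]))

  # altloc: the occupancy-0.6 A copy of NZ wins; one NZ remains
  nz <- st[st$elety == "NZ", ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$x, 13.0)
  expect_equal(nz$o, 0.6)
})

test_that("identical content in PDB and mmCIF parses identically", {
  p <- make_positive(plant_spec(seed = 3, burial = "exposed", n_decoy = 20))
  fp <- tempfile(fileext = ".pdb"); fc <- tempfile(fileext = ".cif")
  write_structure_pdb(p$structure, fp)
  write_structure_cif(p$structure, fc)
  sp <- read_structure(fp, id = "x")
  sc <- read_structure(fc, id = "x")
  cols <- c("chain", "resno", "resid", "elety")
  expect_equal(as.data.frame(sp[, cols]), as.data.frame(sc[, cols]),
               ignore_attr = TRUE)
  # coordinates bitwise equal after parse
  expect_identical(sp$x, sc$x)
  expect_identical(sp$y, sc$y)
  expect_identical(sp$z, sc$z)
  expect_identical(attr(sp, "source_format"), "pdb")
  expect_identical(attr(sc, "source_format"), "cif")
})

test_that("unparseable and empty inputs produce informative errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure", bad)
  expect_error(read_structure(bad))
  onlywater <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), onlywater)
  expect_error(read_structure(onlywater), "empty structure")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("sequence extraction maps residues invertibly with X for ligands", {
  f <- write_mini_pdb(tempfile(fileext = ".pdb"))
  st <- read_structure(f)
  map <- extract_sequence(st, "A")
  expect_equal(paste(map$letter, collapse = ""), "KNDX")
  expect_equal(map$resno, c(10L, 11L, 12L, 13L))
  # invertibility: every mapped residue's name encodes its letter
  std <- map[map$letter != "X", ]
  expect_equal(unname(isopeptider:::AA_CODE[std$resid]), std$letter)
  expect_error(extract_sequence(st, "Z"), "unknown chain")
})

test_that("prediction TSV has the documented columns, order and sorting", {
  hdr_only <- tempfile(fileext = ".tsv")
  write_predictions_tsv(isopeptider:::empty_predictions(), hdr_only)
  lines <- readLines(hdr_only)
  expect_length(lines, 1)
  expect_identical(strsplit(lines, "\t")[[1]], isopeptider:::TSV_COLUMNS)

  pred <- isopeptider:::empty_predictions() |>
    tibble::add_row(structure_id = "s", chain = "A", r1_bond = 50L,
                    r_cat = 51L, r2_bond = 52L, r1_bond_name = "LYS",
                    r_cat_name = "ASP", r2_bond_name = "ASN",
                    probability = 0.9, is_bond = TRUE, rmsd = 0.4,
                    r_asa = 0.1, template = "t", type = "CnaA-like") |>
    tibble::add_row(structure_id = "s", chain = "A", r1_bond = 7L,
                    r_cat = 8L, r2_bond = 9L, r1_bond_name = "LYS",
                    r_cat_name = "GLU", r2_bond_name = "ASN",
                    probability = 0.8, is_bond = TRUE, rmsd = 0.5,
                    r_asa = 0.2, template = "t", type = "CnaB-like")
  f <- tempfile(fileext = ".tsv")
  write_predictions_tsv(pred, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(tab$r1_bond, c(7, 50))   # sorted by (structure, chain, lys)
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))
})
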