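single_atom <- function(x = 0, y = 0, z = 0, elety = "C", resno = 1L) {
  tibble::tibble(type = "ATOM", chain = "A", resno = resno, resid = "ALA",
                 elety = elety, x = x, y = y, z = z)
}

test_that("an isolated atom reproduces the analytic sphere area", {
  st <- as_structure(single_atom(), id = "one")
  got <- compute_sasa(st, n_points = 500)$sasa
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
})

test_that("distant atoms do not occlude; overlapping ones follow the cap formula", {
  far <- as_structure(dplyr::bind_rows(
    single_atom(), single_atom(x = 10, elety = "C2", resno = 2L)), id = "far")
  s <- compute_sasa(far)
  expect_equal(s$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 0.02)

  for (d in c(2.0, 3.5, 5.0)) {
    ov <- as_structure(dplyr::bind_rows(
      single_atom(), single_atom(x = d, elety = "C2", resno = 2L)),
      id = "ov")
    s <- compute_sasa(ov, n_points = 2000)
    expect_equal(s$sasa, rep(spherical_cap_exposed(3.1, d), 2),
                 tolerance = 0.02 * 4 * pi * 3.1^2)
  }
})

test_that("occluders never increase SASA and dense packing buries a residue", {
  p <- make_positive(plant_spec(seed = 21, burial = "exposed", n_decoy = 20))
  b <- make_positive(plant_spec(seed = 21, burial = "buried", n_decoy = 20))
  site <- isopeptider:::truth_site(p$truth)
  res <- tibble::tibble(chain = "A",
                        resno = c(site$lys_resno, site$cat_resno,
                                  site$acc_resno),
                        insert = "")
  exposed <- compute_sasa(p$structure, residues = res)$sasa
  buried <- compute_sasa(b$structure, residues = res)$sasa
  expect_true(all(buried <= exposed))
  expect_lt(compute_rasa(b$structure, site), 0.07)
  expect_gt(compute_rasa(p$structure, site), 0.4)
})

test_that("SASA is invariant under rigid transforms", {
  p <- make_positive(plant_spec(seed = 22, burial = "exposed", n_decoy = 15))
  site <- isopeptider:::truth_site(p$truth)
  r0 <- compute_rasa(p$structure, site, n_points = 2000)
  set.seed(5)
  for (i in 1:3) {
    st2 <- transform_structure(p$structure, random_rotation(),
                               stats::rnorm(3, 0, 30))
    expect_equal(compute_rasa(st2, site, n_points = 2000), r0,
                 tolerance = 0.005)
  }
})

test_that("the point-count discretization is converged at 500 points", {
  p <- make_positive(plant_spec(seed = 23, burial = "exposed", n_decoy = 15))
  site <- isopeptider:::truth_site(p$truth)
  expect_lt(abs(compute_rasa(p$structure, site, n_points = 500) -
                  compute_rasa(p$structure, site, n_points = 2000)), 0.02)
})

test_that("residue types without a tabulated maximum are rejected", {
  st <- as_structure(tibble::tibble(
    type = c("ATOM", "ATOM", "ATOM", "HETATM"), chain = "A",
    resno = c(1L, 2L, 3L, 4L),
    resid = c("LYS", "ASP", "ASN", "LIG"),
    elety = c("CA", "CA", "CA", "C1"),
    x = c(0, 4, 8, 12), y = 0, z = 0), id = "mix")
  site <- list(lys_chain = "A", lys_resno = 1L, cat_chain = "A",
               cat_resno = 2L, acc_chain = "A", acc_resno = 3L)
  expect_silent(compute_rasa(st, site))
  bad_site <- list(lys_chain = "A", lys_resno = 1L, cat_chain = "A",
                   cat_resno = 2L, acc_chain = "A", acc_resno = 3L,
                   acc_insert = "")
  st_bad <- st; st_bad$resid[3] <- "XYZ"; st_bad$nonstandard[3] <- TRUE
  expect_error(compute_rasa(st_bad, bad_site), "XYZ")
})
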