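test_that("dihedral angles: planar cases, oracle agreement, mirror antisymmetry", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)

  set.seed(8)
  for (i in 1:20) {
    p <- matrix(stats::rnorm(12, 0, 3), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    oracle <- bio3d::torsion.xyz(as.numeric(t(p)))
    expect_equal(mine, oracle, tolerance = 1e-9)
    mirrored <- dihedral_angle(-p[1, ], -p[2, ], -p[3, ], -p[4, ])
    if (abs(mine) < 180 - 1e-9) expect_equal(mirrored, -mine,
                                             tolerance = 1e-9)
  }
})

test_that("planted geometry is reproduced and mirrors negate all pseudo-dihedrals", {
  dih <- c(phi = -60, psi = 140, omega = 170)
  st <- triad_structure(dihedrals = dih, bond_length = 1.40)
  site <- triad_site()
  expect_equal(bond_length(st, site), 1.40, tolerance = 1e-9)
  got <- pseudo_dihedrals(st, site)
  expect_equal(unname(got[c("phi", "psi", "omega")]),
               unname(dih[c("phi", "psi", "omega")]), tolerance = 1e-6)

  st_m <- st
  st_m$x <- -st_m$x; st_m$y <- -st_m$y; st_m$z <- -st_m$z
  expect_equal(unname(pseudo_dihedrals(st_m, site)), unname(-got),
               tolerance = 1e-9)
})

test_that("missing atoms make lengths and angles unmeasurable, not wrong", {
  st <- triad_structure()
  site <- triad_site()
  st2 <- st[st$elety != "CG" | st$resno != 23L, ]   # drop acceptor acyl CG
  expect_true(is.na(bond_length(st2, site)))
  d <- pseudo_dihedrals(st2, site)
  expect_true(all(is.na(d)))
  st3 <- st[st$elety != "CD" | st$resno != 21L, ]   # drop lysine CD only
  d3 <- pseudo_dihedrals(st3, site)
  expect_true(is.na(d3[["phi"]]))
  expect_false(is.na(d3[["psi"]]))
})

test_that("Z-score outliers require strictly exceeding four", {
  ref <- list(bond_length_mean = 1.33, bond_length_sd = 0.02)
  expect_equal(bond_zscore(1.33, ref)$z, 0)
  expect_false(bond_zscore(1.33, ref)$outlier)
  # exactly representable: (3 - 1) / 0.5 is 4 with no rounding
  ref2 <- list(bond_length_mean = 1, bond_length_sd = 0.5)
  at4 <- bond_zscore(3, ref2)
  expect_identical(at4$z, 4)
  expect_false(at4$outlier)
  expect_true(bond_zscore(3.0005, ref2)$outlier)
  expect_true(bond_zscore(1.33 + 5 * 0.02, ref)$outlier)
  expect_true(bond_zscore(1.33 - 5 * 0.02, ref)$outlier)
})

test_that("KDE calibration flags about five percent of its own training set", {
  set.seed(14)
  s <- cbind(stats::rnorm(500, -120, 9), stats::rnorm(500, 130, 9))
  kde <- fit_kde(s)
  frac <- mean(kde_loglik(kde, s) < kde$cutoff)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)

  centroid <- colMeans(s)
  expect_gt(kde_loglik(kde, centroid), kde$cutoff)
  far <- centroid + c(6 * stats::sd(s[, 1]), 6 * stats::sd(s[, 2]))
  expect_lt(kde_loglik(kde, far), kde$cutoff)
  expect_equal(kde_loglik(kde, far), oracle_kde_loglik(kde, far),
               tolerance = 1e-9)
  expect_error(fit_kde(s[1:10, ]), "refusing")
})

test_that("the mirrored angular KDE integrates to one, including at the cut", {
  set.seed(15)
  # centered on the 180/-180 cut, where mirroring matters most
  s <- cbind(isopeptider:::wrap_angle(stats::rnorm(60, 180, 8)),
             stats::rnorm(60, -150, 8))
  kde <- fit_kde(s)
  grid <- seq(-179.5, 179.5, by = 1)
  dens <- 0
  for (a1 in grid) {
    dens <- dens + sum(exp(kde_loglik(kde, cbind(a1, grid))))
  }
  expect_equal(dens * 1 * 1, 1, tolerance = 0.02)
})

test_that("geometry assessment combines flags correctly (exhaustive truth table)", {
  for (z in c(TRUE, FALSE)) for (a in c(TRUE, FALSE))
    for (b in c(TRUE, FALSE)) for (c_ in c(TRUE, FALSE)) {
      got <- isopeptider:::combine_geometry_flags(z, c(a, b, c_))
      expect_identical(got,
                       if (z || a || b || c_) "outlier" else "ok")
    }
  # missing components are skipped, not treated as outliers
  expect_identical(isopeptider:::combine_geometry_flags(NA, c(NA, FALSE, NA)),
                   "ok")
})

test_that("in-distribution bonds pass QC; stretched or twisted ones flag", {
  ref <- fit_geometry_reference(sample_geometry_reference(200, seed = 88))
  g <- isopeptider:::TOPOLOGY_GEOMETRY[["CnaA-like"]]
  dih <- c(phi = g$phi, psi = g$psi, omega = g$omega)
  site <- triad_site()

  ok <- assess_geometry(triad_structure(dihedrals = dih), site, ref)
  expect_identical(ok$geometry_flag, "ok")

  stretched <- triad_structure(dihedrals = dih,
                               bond_length = 1.33 + 6 * 0.02)
  rep_s <- assess_geometry(stretched, site, ref)
  expect_true(rep_s$zscore_flag)
  expect_identical(rep_s$geometry_flag, "outlier")

  # S1-style: length in range but pseudo-omega rotated 90 degrees off
  twisted <- triad_structure(dihedrals = c(phi = g$phi, psi = g$psi,
                                           omega = g$omega - 90))
  rep_t <- assess_geometry(twisted, site, ref)
  expect_false(rep_t$zscore_flag)
  expect_true(rep_t$omega_psi_flag || rep_t$omega_phi_flag)
  expect_identical(rep_t$geometry_flag, "outlier")
})

test_that("Z-scores are rigid-transform invariant and linear in length", {
  ref <- fit_geometry_reference(sample_geometry_reference(100, seed = 5))
  st <- triad_structure()
  site <- triad_site()
  z0 <- bond_zscore(bond_length(st, site), ref)$z
  set.seed(77)
  st2 <- transform_structure(st, random_rotation(), c(5, -3, 11))
  expect_equal(bond_zscore(bond_length(st2, site), ref)$z, z0,
               tolerance = 1e-6)
  z1 <- bond_zscore(1.0, ref); z2 <- bond_zscore(2.0, ref)
  expect_equal((z2$z - z1$z) * ref$bond_length_sd, 1.0, tolerance = 1e-9)
})
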