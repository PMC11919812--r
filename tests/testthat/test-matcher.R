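test_that("a planted triad self-matches at zero RMSD, invariant to rigid motion", {
  g <- isopeptider:::TOPOLOGY_GEOMETRY[["CnaA-like"]]
  st <- triad_structure(dihedrals = c(phi = g$phi, psi = g$psi,
                                      omega = g$omega))
  hits <- find_matches(st, lib6)
  expect_gte(nrow(hits), 1)
  expect_lt(min(hits$rmsd), 1e-6)

  set.seed(9)
  for (i in 1:5) {
    st2 <- transform_structure(st, random_rotation(), stats::rnorm(3, 0, 20))
    h2 <- find_matches(st2, lib6)
    expect_equal(nrow(h2), nrow(hits))
    expect_lt(max(abs(sort(h2$rmsd) - sort(hits$rmsd))), 1e-6)
  }
})

test_that("superposition RMSD agrees with an independent fitting routine", {
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(stats::rnorm(42), 14, 3)
    b <- a + matrix(stats::rnorm(42, 0, 0.3), 14, 3)
    expect_lt(abs(kabsch_rmsd(a, b) -
                    bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)),
                                fit = TRUE)),
              5.01e-4)               # the reference rounds to 3 decimals
  }
})

test_that("pruned search equals the exhaustive enumerator on noisy plants", {
  for (sigma in c(0.1, 0.3)) {
    p <- make_positive(plant_spec(noise_sigma = sigma, burial = "exposed",
                                  n_decoy = 24, seed = 400 + sigma * 10))
    a <- find_matches(p$structure, lib6)
    b <- find_matches_brute(p$structure, lib6)
    expect_equal(a$site_key, b$site_key)
    expect_equal(a$template_id, b$template_id)
    expect_lt(max(abs(a$rmsd - b$rmsd)), 1e-9)
  }
})

test_that("carboxylate oxygen naming is matched both ways", {
  # swapping OD1/OD2 on the target aspartate must not change the best RMSD
  p <- make_positive(plant_spec(triad_type = "Lys-Asn-Asp",
                                noise_sigma = 0.1, burial = "exposed",
                                n_decoy = 20, seed = 77))
  st <- p$structure
  h1 <- reduce_to_best(find_matches(st, lib6))
  i1 <- which(st$resno == p$truth$cat_resno & st$elety == "OD1")
  i2 <- which(st$resno == p$truth$cat_resno & st$elety == "OD2")
  st2 <- st
  st2[c(i1, i2), c("x", "y", "z")] <- st[c(i2, i1), c("x", "y", "z")]
  h2 <- reduce_to_best(find_matches(st2, lib6))
  expect_equal(h1$rmsd, h2$rmsd, tolerance = 1e-9)
})

test_that("site reduction keeps the minimum-RMSD hit with deterministic ties", {
  base <- isopeptider:::empty_hits()
  row <- function(tid, rmsd, lys = 1L) tibble::tibble(
    structure_id = "s", template_id = tid, topology = "CnaA-like",
    triad_type = "Lys-Asn-Asp", rmsd = rmsd,
    lys_chain = "A", lys_resno = lys, lys_insert = "", lys_resid = "LYS",
    cat_chain = "A", cat_resno = lys + 1L, cat_insert = "",
    cat_resid = "ASP",
    acc_chain = "A", acc_resno = lys + 2L, acc_insert = "",
    acc_resid = "ASN",
    site_key = paste0("A:", lys, "|A:", lys + 1, "|A:", lys + 2)
  )
  hits <- dplyr::bind_rows(base, row("t1", 0.8), row("t2", 0.5), row("t3", 0.9))
  expect_equal(reduce_to_best(hits)$template_id, "t2")

  two_sites <- dplyr::bind_rows(row("t1", 0.8), row("t1", 0.6, lys = 10L))
  expect_equal(nrow(reduce_to_best(two_sites)), 2)

  tie <- dplyr::bind_rows(row("tB", 0.5), row("tA", 0.5))
  expect_equal(reduce_to_best(tie)$template_id, "tA")

  # retained hit never beaten by a discarded one on the same site
  set.seed(12)
  many <- dplyr::bind_rows(lapply(1:20, function(i)
    row(sprintf("t%02d", i), stats::runif(1), lys = (i %% 3) * 10L + 1L)))
  best <- reduce_to_best(many)
  for (k in unique(many$site_key)) {
    expect_equal(best$rmsd[best$site_key == k],
                 min(many$rmsd[many$site_key == k]))
  }
})

test_that("minimum RMSD does not decrease with coordinate noise", {
  sigmas <- c(0, 0.1, 0.3, 0.5)
  means <- vapply(seq_along(sigmas), function(si) {
    r <- vapply(1:25, function(i) {
      p <- make_positive(plant_spec(noise_sigma = sigmas[si],
                                    burial = "exposed", n_decoy = 20,
                                    seed = 9000 + si * 100 + i))
      h <- find_matches(p$structure, lib6)
      if (nrow(h)) min(h$rmsd) else NA_real_
    }, 1)
    mean(r, na.rm = TRUE)
  }, 1)
  expect_true(all(diff(means) > 0))
})
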