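#' Deterministic quasi-uniform sphere point set
#'
#' Fibonacci (golden-angle) lattice on the unit sphere. Deterministic, so
#' SASA values are bit-reproducible across runs.
#'
#' @param n Number of points.
#' @return An n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-residue solvent accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: every heavy atom carries `n_points` quasi-uniform test
#' points on a sphere of radius (van der Waals + probe); a point is
#' accessible when it lies outside every other heavy atom's expanded
#' sphere. Atom SASA is the accessible fraction times the sphere area;
#' residue SASA sums its atoms. All heavy atoms of the structure (including
#' heteroatom ligands, which genuinely bury residues) occlude; hydrogens
#' are ignored.
#'
#' @param structure An `iso_structure`.
#' @param n_points Test points per atom (default 500).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param residues Optional tibble with columns `chain`, `resno`, `insert`
#'   restricting which residues' areas are evaluated (all atoms still
#'   occlude). Default: all residues.
#' @return A tibble with `chain`, `resno`, `insert`, `resid`, `n_atoms`
#'   and `sasa` (Angstrom^2). Residues with no heavy atoms get `NA` SASA.
#' @export
compute_sasa <- function(structure, n_points = 500, probe = 1.4,
                         residues = NULL) {
  heavy <- structure[!(structure$elesy %in% c("H", "D")), , drop = FALSE]
  res <- structure_residues(structure)
  if (!is.null(residues)) {
    residues$insert <- residues$insert %||% ""
    want <- residue_key(residues$chain, residues$resno, residues$insert)
    res <- res[res$key %in% want, , drop = FALSE]
    if (nrow(res) < length(unique(want))) stop("requested residue(s) absent ",
                                               "from structure")
  }
  pts <- fibonacci_sphere(n_points)
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  rad <- vdw_radius_of(heavy$elesy) + probe
  hkey <- residue_key(heavy$chain, heavy$resno, heavy$insert)

  atom_sasa <- function(i) {
    ri <- rad[i]
    ci <- xyz[i, ]
    d2 <- (xyz[, 1] - ci[1])^2 + (xyz[, 2] - ci[2])^2 + (xyz[, 3] - ci[3])^2
    nb <- which(d2 < (ri + rad)^2 & d2 > 1e-12)
    frac <- if (!length(nb)) 1 else {
      sp <- sweep(pts * ri, 2, ci, "+")
      free <- rep(TRUE, nrow(sp))
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      mean(free)
    }
    frac * 4 * pi * ri^2
  }

  sasa <- vapply(res$key, function(k) {
    idx <- which(hkey == k)
    if (!length(idx)) return(NA_real_)
    sum(vapply(idx, atom_sasa, 1))
  }, 1)

  tibble::tibble(chain = res$chain, resno = res$resno, insert = res$insert,
                 resid = res$resid,
                 n_atoms = vapply(res$key, function(k) sum(hkey == k), 1L),
                 sasa = unname(sasa))
}

#' Relative solvent accessibility of a triad site
#'
#' Residue SASA (whole-structure context) divided by the Rost-Sander
#' maximum for the residue type, averaged over the three triad residues.
#' Low values indicate burial in the hydrophobic core — a requirement for
#' isopeptide-bond formation and the classifier's second feature.
#'
#' @param structure An `iso_structure`.
#' @param site A list or one-row data frame with `lys_chain`, `lys_resno`,
#'   `cat_chain`, `cat_resno`, `acc_chain`, `acc_resno` (and optional
#'   `*_insert`).
#' @inheritParams compute_sasa
#' @return The mean relative accessibility (dimensionless; may slightly
#'   exceed 1 for extended conformations).
#' @export
compute_rasa <- function(structure, site, n_points = 500, probe = 1.4) {
  res <- tibble::tibble(
    chain = c(site$lys_chain, site$cat_chain, site$acc_chain),
    resno = c(site$lys_resno, site$cat_resno, site$acc_resno),
    insert = c(site$lys_insert %||% "", site$cat_insert %||% "",
               site$acc_insert %||% "")
  )
  sasa <- compute_sasa(structure, n_points = n_points, probe = probe,
                       residues = res)
  mx <- max_asa_table()
  m <- mx$max_asa[match(sasa$resid, mx$resid)]
  if (anyNA(m)) stop("no maximum-ASA value tabulated for residue type(s): ",
                     paste(unique(sasa$resid[is.na(m)]), collapse = ", "))
  if (anyNA(sasa$sasa)) stop("SASA undefined (no heavy atoms) for a site ",
                             "residue")
  mean(sasa$sasa / m)
}
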