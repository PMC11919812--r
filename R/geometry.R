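#' Signed dihedral angle of four points
#'
#' Standard signed torsion over the chain p1-p2-p3-p4, in degrees on
#' `(-180, 180]`. The sign convention is chirality-sensitive: mirroring all
#' coordinates negates the angle.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# standard deviation of angular data (degrees): recentre on the circular
# mean, wrap residuals, then take the linear sd
circular_sd <- function(a) {
  rad <- a * pi / 180
  mu <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  resid <- (a - mu + 180) %% 360 - 180
  stats::sd(resid)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

acyl_atom <- function(acc_resid) if (acc_resid == "GLU") "CD" else "CG"

site_atom <- function(structure, site, role, atom) {
  pre <- c(bond_lys = "lys", catalytic = "cat", bond_acceptor = "acc")[[role]]
  m <- residue_atom_coords(structure, site[[paste0(pre, "_chain")]],
                           site[[paste0(pre, "_resno")]],
                           site[[paste0(pre, "_insert")]] %||% "", atom)
  if (is.null(m)) NULL else m[1, ]
}

#' Isopeptide bond length of a site
#'
#' Euclidean distance from the lysine NZ to the acceptor's acyl carbon
#' (Asn/Asp CG; Glu CD in the defensive case of a Glu acceptor).
#'
#' @param structure An `iso_structure`.
#' @param site A site row/list (`lys_*`, `cat_*`, `acc_*` fields, with
#'   `acc_resid` naming the acceptor residue type).
#' @return Bond length in Angstrom, or `NA` (unmeasurable) when either atom
#'   is missing.
#' @export
bond_length <- function(structure, site) {
  nz <- site_atom(structure, site, "bond_lys", "NZ")
  cg <- site_atom(structure, site, "bond_acceptor", acyl_atom(site$acc_resid))
  if (is.null(nz) || is.null(cg)) return(NA_real_)
  sqrt(sum((nz - cg)^2))
}

#' Pseudo-dihedral angles across the isopeptide link
#'
#' The cross-link chain CD-CE-NZ-C(acyl)-CB-CA is treated as a peptide-bond
#' analogue: `pseudo_phi` = CD-CE-NZ-C(acyl), `pseudo_omega` =
#' CE-NZ-C(acyl)-CB (torsion about the acyl C-N bond), `pseudo_psi` =
#' NZ-C(acyl)-CB-CA.
#'
#' @inheritParams bond_length
#' @return Named numeric vector `c(phi, psi, omega)` in degrees on
#'   `(-180, 180]`; `NA` for angles whose atoms are missing.
#' @export
pseudo_dihedrals <- function(structure, site) {
  acyl <- acyl_atom(site$acc_resid)
  a <- list(
    cd = site_atom(structure, site, "bond_lys", "CD"),
    ce = site_atom(structure, site, "bond_lys", "CE"),
    nz = site_atom(structure, site, "bond_lys", "NZ"),
    cac = site_atom(structure, site, "bond_acceptor", acyl),
    cb = site_atom(structure, site, "bond_acceptor", "CB"),
    ca = site_atom(structure, site, "bond_acceptor", "CA")
  )
  dih <- function(p) {
    if (any(vapply(p, is.null, TRUE))) NA_real_
    else dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  c(phi = dih(a[c("cd", "ce", "nz", "cac")]),
    psi = dih(a[c("nz", "cac", "cb", "ca")]),
    omega = dih(a[c("ce", "nz", "cac", "cb")]))
}

#' Bond-length Z-score
#'
#' @param length Measured bond length (Angstrom).
#' @param ref An `iso_geometry_ref` (see [fit_geometry_reference()]).
#' @return A list `z` (signed score) and `outlier` (`TRUE` iff `|z| > 4`,
#'   strictly — a score of exactly 4 is not an outlier).
#' @export
bond_zscore <- function(length, ref) {
  if (is.na(length)) return(list(z = NA_real_, outlier = NA))
  z <- (length - ref$bond_length_mean) / ref$bond_length_sd
  list(z = z, outlier = abs(z) > 4)
}

#' Fit a 2-D angular kernel density model
#'
#' Gaussian product-kernel density over one pseudo-dihedral pair, with
#' Scott's-rule bandwidths. Angles live on the cut interval `(-180, 180]`;
#' samples within `mirror_margin` degrees of the cut are mirrored across it
#' (shifted by +/-360) to reduce wrap-around bias — a documented
#' approximation to a fully toroidal density. The outlier cutoff is the 5th
#' percentile of the training samples' own log-likelihoods, so about 5% of
#' training points sit outside their own 95th percentile by construction.
#'
#' @param samples A two-column numeric matrix/data frame of angles
#'   (degrees).
#' @param mirror_margin Mirroring margin in degrees (default 20).
#' @param min_samples Minimum sample count (default 20); fewer refuses to
#'   fit.
#' @return An object of class `iso_kde`: augmented sample set, bandwidths,
#'   original sample size, and `cutoff` (log-likelihood).
#' @export
fit_kde <- function(samples, mirror_margin = 20, min_samples = 20) {
  s <- as.matrix(samples)
  stopifnot(ncol(s) == 2)
  s <- s[stats::complete.cases(s), , drop = FALSE]
  if (nrow(s) < min_samples)
    stop("refusing to fit KDE on ", nrow(s), " samples (need >= ",
         min_samples, ")")
  n <- nrow(s)
  # Scott's rule, per dimension (d = 2), on the circular spread: the plain
  # standard deviation of wrapped angles is meaningless for samples
  # straddling the 180/-180 cut
  h <- apply(s, 2, circular_sd) * n^(-1 / 6)
  h[h < 1e-6] <- 1e-6
  aug <- s
  for (j in 1:2) {
    hi <- s[s[, j] > 180 - mirror_margin, , drop = FALSE]
    lo <- s[s[, j] <= -180 + mirror_margin, , drop = FALSE]
    if (nrow(hi)) { hi[, j] <- hi[, j] - 360; aug <- rbind(aug, hi) }
    if (nrow(lo)) { lo[, j] <- lo[, j] + 360; aug <- rbind(aug, lo) }
  }
  kde <- structure(list(samples = aug, n = n, bandwidth = h), class = "iso_kde")
  kde$cutoff <- unname(stats::quantile(kde_loglik(kde, s), 0.05))
  kde
}

#' Log-likelihood of angle pairs under a fitted KDE
#'
#' @param kde An `iso_kde`.
#' @param x A two-column matrix/data frame of query angles (degrees), or a
#'   length-2 vector.
#' @return Numeric vector of log-densities.
#' @export
kde_loglik <- function(kde, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  x <- as.matrix(x)
  s <- kde$samples; h <- kde$bandwidth
  vapply(seq_len(nrow(x)), function(i) {
    z1 <- (x[i, 1] - s[, 1]) / h[1]
    z2 <- (x[i, 2] - s[, 2]) / h[2]
    k <- exp(-0.5 * (z1^2 + z2^2)) / (2 * pi * h[1] * h[2])
    log(sum(k) / kde$n)
  }, 1)
}

ANGLE_PAIRS <- list(
  phi_psi = c("phi", "psi"),
  omega_psi = c("omega", "psi"),
  omega_phi = c("omega", "phi")
)

#' Fit the geometry reference from curated bond records
#'
#' Builds the full quality-control reference from a table of observed bond
#' geometries: pooled bond-length mean and standard deviation, plus six KDE
#' models — one per pseudo-dihedral pair (phi/psi, omega/psi, omega/phi)
#' for each topology (CnaA-like, CnaB-like) — each with its 5th-percentile
#' likelihood cutoff.
#'
#' @param reference A data frame with columns `topology`, `phi`, `psi`,
#'   `omega` (degrees) and `bond_length` (Angstrom), one row per curated
#'   bond.
#' @return An object of class `iso_geometry_ref`.
#' @export
fit_geometry_reference <- function(reference) {
  needed <- c("topology", "phi", "psi", "omega", "bond_length")
  stopifnot(all(needed %in% names(reference)))
  sd <- stats::sd(reference$bond_length)
  if (!is.finite(sd) || sd <= 0) stop("degenerate bond-length reference ",
                                      "(sd must be positive)")
  kdes <- list()
  for (topo in TOPOLOGIES) {
    rows <- reference[reference$topology == topo, , drop = FALSE]
    for (pair in names(ANGLE_PAIRS)) {
      kdes[[topo]][[pair]] <- fit_kde(rows[, ANGLE_PAIRS[[pair]]])
    }
  }
  structure(list(bond_length_mean = mean(reference$bond_length),
                 bond_length_sd = sd, kdes = kdes),
            class = "iso_geometry_ref")
}

#' Read / write a geometry reference sample table
#'
#' Tab-separated with columns `topology`, `phi`, `psi`, `omega`,
#' `bond_length`; the schema a user would produce from their own curated
#' bonds, so a real reference set can be dropped in for the bundled
#' synthetic one.
#'
#' @param path File path.
#' @return `read_geometry_reference()`: the sample tibble;
#'   `default_geometry_reference()`: the bundled synthetic reference,
#'   already fitted.
#' @export
read_geometry_reference <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_geometry_reference
#' @param reference Sample tibble to write.
#' @export
write_geometry_reference <- function(reference, path) {
  readr::write_tsv(reference, path)
  invisible(path)
}

#' @rdname read_geometry_reference
#' @export
default_geometry_reference <- function() {
  if (is.null(.iso_cache$geom_ref)) {
    .iso_cache$geom_ref <- fit_geometry_reference(
      read_geometry_reference(iso_extdata("geometry_reference_synthetic.tsv")))
  }
  .iso_cache$geom_ref
}

#' Geometric quality assessment of a predicted bond
#'
#' Combines the bond-length Z-score (outlier iff `|z| > 4`) with the three
#' pseudo-dihedral pair likelihoods under the topology's KDE models
#' (outlier iff below that model's 5th-percentile cutoff). The overall flag
#' is `"outlier"` if any available component flags; components whose atoms
#' are missing are reported `NA` and skipped.
#'
#' @param structure An `iso_structure`.
#' @param site A site row/list (see [bond_length()]), including `topology`.
#' @param ref An `iso_geometry_ref`.
#' @return A one-row tibble: `bond_length`, `zscore`, `zscore_flag`,
#'   `phi`, `psi`, `omega`, `phi_psi_likelihood`, `omega_psi_likelihood`,
#'   `omega_phi_likelihood`, `phi_psi_flag`, `omega_psi_flag`,
#'   `omega_phi_flag`, `geometry_flag`.
#' @export
assess_geometry <- function(structure, site, ref = default_geometry_reference()) {
  stopifnot(inherits(ref, "iso_geometry_ref"))
  topo <- site$topology
  if (!topo %in% names(ref$kdes)) stop("no KDE reference for topology ", topo)
  len <- bond_length(structure, site)
  zs <- bond_zscore(len, ref)
  dih <- pseudo_dihedrals(structure, site)
  lik <- flag <- stats::setNames(rep(NA_real_, 3), names(ANGLE_PAIRS))
  flag <- stats::setNames(rep(NA, 3), names(ANGLE_PAIRS))
  for (pair in names(ANGLE_PAIRS)) {
    v <- dih[ANGLE_PAIRS[[pair]]]
    if (anyNA(v)) next
    kde <- ref$kdes[[topo]][[pair]]
    lik[pair] <- kde_loglik(kde, v)
    flag[pair] <- lik[pair] < kde$cutoff
  }
  overall <- combine_geometry_flags(zs$outlier, flag)
  tibble::tibble(
    bond_length = len, zscore = zs$z, zscore_flag = zs$outlier,
    phi = unname(dih["phi"]), psi = unname(dih["psi"]),
    omega = unname(dih["omega"]),
    phi_psi_likelihood = unname(lik["phi_psi"]),
    omega_psi_likelihood = unname(lik["omega_psi"]),
    omega_phi_likelihood = unname(lik["omega_phi"]),
    phi_psi_flag = unname(flag["phi_psi"]),
    omega_psi_flag = unname(flag["omega_psi"]),
    omega_phi_flag = unname(flag["omega_phi"]),
    geometry_flag = overall
  )
}

# flag-combination rule kept separate so it can be tested exhaustively
combine_geometry_flags <- function(zscore_flag, pair_flags) {
  if (isTRUE(zscore_flag) || any(pair_flags %in% TRUE)) "outlier" else "ok"
}
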