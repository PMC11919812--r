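#' @importFrom withr with_seed
NULL

# --- internal-coordinate machinery -----------------------------------------

unit3 <- function(v) v / sqrt(sum(v^2))

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three reference positions `a`, `b`, `c`, returns the point `d`
#' with `|cd| = bond`, angle(b,c,d) = `angle` and torsion(a,b,c,d) =
#' `torsion` (degrees, standard sign convention).
#'
#' @param a,b,c Numeric 3-vectors.
#' @param bond Bond length (Angstrom).
#' @param angle Bond angle at `c` (degrees).
#' @param torsion Torsion about `b`-`c` (degrees).
#' @return Numeric 3-vector.
#' @export
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

# per-topology pseudo-dihedral distributions emulated by the generator:
# CnaA-like bonds are generated trans (omega ~ 180), CnaB-like cis
# (omega ~ 0), with distinct phi/psi centers, mirroring the cis/trans split
# between the two domain classes
TOPOLOGY_GEOMETRY <- list(
  "CnaA-like" = list(phi = -120, psi = 130, omega = 180, angle_sd = 8),
  "CnaB-like" = list(phi = 60, psi = -150, omega = 0, angle_sd = 8)
)
BOND_LENGTH_MEAN <- 1.33
BOND_LENGTH_SD <- 0.02

sample_site_geometry <- function(topology) {
  g <- TOPOLOGY_GEOMETRY[[topology]]
  c(phi = wrap_angle(stats::rnorm(1, g$phi, g$angle_sd)),
    psi = wrap_angle(stats::rnorm(1, g$psi, g$angle_sd)),
    omega = wrap_angle(stats::rnorm(1, g$omega, g$angle_sd)),
    bond_length = stats::rnorm(1, BOND_LENGTH_MEAN, BOND_LENGTH_SD))
}

# --- triad construction -----------------------------------------------------

atom_row <- function(role, resid, elety, p) {
  tibble::tibble(role = role, resid = resid, elety = elety,
                 x = p[1], y = p[2], z = p[3])
}

# Build an idealized bonded triad from internal coordinates. Returns a
# tibble (role, resid, elety, x, y, z) carrying backbone and side-chain
# atoms of the three residues; the planted bond length and the three
# pseudo-dihedrals are reproduced exactly by construction.
build_triad <- function(triad_type, topology,
                        bond_length = BOND_LENGTH_MEAN, dihedrals = NULL) {
  res <- triad_residues(triad_type)
  if (is.null(dihedrals)) {
    g <- TOPOLOGY_GEOMETRY[[topology]]
    dihedrals <- c(phi = g$phi, psi = g$psi, omega = g$omega)
  }
  phi <- dihedrals[["phi"]]; psi <- dihedrals[["psi"]]
  omega <- dihedrals[["omega"]]
  if (bond_length <= 0) stop("infeasible bond_length: ", bond_length)

  acc <- res[["bond_acceptor"]]   # ASN or ASP, acyl carbon CG
  xd2 <- if (acc == "ASN") "ND2" else "OD2"

  # acceptor residue in the laboratory frame
  n_a <- c(-0.57, 1.35, 0); ca_a <- c(0, 0, 0); cb_a <- c(1.53, 0, 0)
  cg_a <- nerf_place(n_a, ca_a, cb_a, 1.52, 113, -65)
  nz <- nerf_place(ca_a, cb_a, cg_a, bond_length, 115, psi)
  od1 <- nerf_place(ca_a, cb_a, cg_a, 1.23, 121, psi + 120)
  oxd <- nerf_place(ca_a, cb_a, cg_a, 1.33, 118, psi + 240)
  c_a <- nerf_place(cb_a, n_a, ca_a, 1.52, 111, -120)
  o_a <- nerf_place(n_a, ca_a, c_a, 1.23, 120, 0)

  # lysine chained backwards from NZ across the link
  ce <- nerf_place(cb_a, cg_a, nz, 1.47, 122, omega)
  cd <- nerf_place(cg_a, nz, ce, 1.52, 111, phi)
  cg_l <- nerf_place(nz, ce, cd, 1.52, 111, 180)
  cb_l <- nerf_place(ce, cd, cg_l, 1.52, 111, 180)
  ca_l <- nerf_place(cd, cg_l, cb_l, 1.52, 111, 180)
  n_l <- nerf_place(cg_l, cb_l, ca_l, 1.46, 110, -60)
  c_l <- nerf_place(cg_l, cb_l, ca_l, 1.52, 111, 60)
  o_l <- nerf_place(cb_l, ca_l, c_l, 1.23, 120, 150)

  # catalytic carboxylate hydrogen-bonded to NZ, rotated off the acyl side
  cat <- res[["catalytic"]]       # ASP or GLU
  o1 <- nerf_place(cd, ce, nz, 2.9, 100, phi + 150)
  ccat <- nerf_place(ce, nz, o1, 1.25, 115, 180)
  o2 <- nerf_place(nz, o1, ccat, 1.25, 126, 180)
  chain1 <- nerf_place(nz, o1, ccat, 1.52, 118, 0)
  if (cat == "ASP") {
    cb_c <- chain1
    ca_c <- nerf_place(o1, ccat, cb_c, 1.52, 112, 180)
    names_c <- c("CG", "OD1", "OD2", "CB", "CA")
  } else {
    cg_c <- chain1
    cb_c <- nerf_place(o1, ccat, cg_c, 1.52, 112, 180)
    ca_c <- nerf_place(ccat, cg_c, cb_c, 1.52, 112, 180)
    names_c <- c("CD", "OE1", "OE2", "CG", "CB", "CA")
  }
  n_c <- nerf_place(if (cat == "ASP") ccat else cg_c,
                    cb_c, ca_c, 1.46, 110, -60)
  c_c <- nerf_place(if (cat == "ASP") ccat else cg_c,
                    cb_c, ca_c, 1.52, 111, 60)
  o_c <- nerf_place(cb_c, ca_c, c_c, 1.23, 120, 150)

  cat_atoms <- if (cat == "ASP") list(ccat, o1, o2, cb_c, ca_c)
               else list(ccat, o1, o2, cg_c, cb_c, ca_c)
  triad <- dplyr::bind_rows(
    atom_row("bond_lys", "LYS", "N", n_l),
    atom_row("bond_lys", "LYS", "CA", ca_l),
    atom_row("bond_lys", "LYS", "C", c_l),
    atom_row("bond_lys", "LYS", "O", o_l),
    atom_row("bond_lys", "LYS", "CB", cb_l),
    atom_row("bond_lys", "LYS", "CG", cg_l),
    atom_row("bond_lys", "LYS", "CD", cd),
    atom_row("bond_lys", "LYS", "CE", ce),
    atom_row("bond_lys", "LYS", "NZ", nz),
    dplyr::bind_rows(Map(function(nm, p) atom_row("catalytic", cat, nm, p),
                         names_c, cat_atoms)),
    atom_row("catalytic", cat, "N", n_c),
    atom_row("catalytic", cat, "C", c_c),
    atom_row("catalytic", cat, "O", o_c),
    atom_row("bond_acceptor", acc, "N", n_a),
    atom_row("bond_acceptor", acc, "CA", ca_a),
    atom_row("bond_acceptor", acc, "C", c_a),
    atom_row("bond_acceptor", acc, "O", o_a),
    atom_row("bond_acceptor", acc, "CB", cb_a),
    atom_row("bond_acceptor", acc, "CG", cg_a),
    atom_row("bond_acceptor", acc, "OD1", od1),
    atom_row("bond_acceptor", acc, xd2, oxd)
  )
  check_self_clash(triad)
  triad
}

check_self_clash <- function(triad, min_dist = 1.0) {
  m <- as.matrix(triad[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  if (min(d) < min_dist)
    stop("infeasible triad geometry: atoms closer than ", min_dist, " A")
  invisible(TRUE)
}

# --- decoy chains -----------------------------------------------------------

# self-avoiding random-walk CA trace with approximate backbone and short
# side chains; full Lys/Asn/Asp/Glu/Gln side chains so decoys offer real
# (non-matching) triad candidates
decoy_atoms <- function(n_residues, min_ca_dist = 4.0, max_restarts = 200) {
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(NA_real_, n_residues, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- unit3(stats::rnorm(3))
    ok <- TRUE
    for (i in 2:n_residues) {
      placed <- FALSE
      for (try in 1:40) {
        nd <- unit3(dir + 0.9 * stats::rnorm(3))
        p <- ca[i - 1, ] + 3.8 * nd
        prev <- ca[seq_len(max(0, i - 2)), , drop = FALSE]
        if (!nrow(prev) ||
            min(sqrt(rowSums(sweep(prev, 2, p)^2))) >= min_ca_dist) {
          ca[i, ] <- p; dir <- nd; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    if (attempt == max_restarts) stop("decoy rejection budget exhausted ",
                                      "(self-avoiding walk)")
  }

  aa <- names(AA_CODE)
  types <- sample(aa, n_residues, replace = TRUE)
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    to_prev <- if (i > 1) unit3(ca[i - 1, ] - ca[i, ]) else c(-1, 0, 0)
    to_next <- if (i < n_residues) unit3(ca[i + 1, ] - ca[i, ]) else c(1, 0, 0)
    perp <- cross3(to_prev, to_next)
    if (sqrt(sum(perp^2)) < 1e-6) perp <- cross3(to_prev, c(0, 0, 1))
    perp <- unit3(perp)
    n_i <- ca[i, ] + 1.45 * unit3(to_prev + 0.5 * perp)
    c_i <- ca[i, ] + 1.52 * unit3(to_next - 0.5 * perp)
    o_i <- c_i + 1.23 * unit3(perp + 0.3 * to_next)
    at <- list(N = n_i, CA = ca[i, ], C = c_i, O = o_i)
    if (types[i] != "GLY") {
      at$CB <- nerf_place(n_i, c_i, ca[i, ], 1.53, 110, 122)
      tors <- sample(c(-60, 60, 180), 4, replace = TRUE)
      if (types[i] %in% c("LYS", "ARG", "MET", "GLU", "GLN", "ASN", "ASP",
                          "LEU", "ILE", "PHE", "TYR", "TRP", "HIS")) {
        at$CG <- nerf_place(n_i, ca[i, ], at$CB, 1.52, 113, tors[1])
      }
      if (types[i] == "LYS") {
        at$CD <- nerf_place(ca[i, ], at$CB, at$CG, 1.52, 111, tors[2])
        at$CE <- nerf_place(at$CB, at$CG, at$CD, 1.52, 111, tors[3])
        at$NZ <- nerf_place(at$CG, at$CD, at$CE, 1.47, 111, tors[4])
      } else if (types[i] %in% c("ASN", "ASP")) {
        at$OD1 <- nerf_place(ca[i, ], at$CB, at$CG, 1.23, 121, tors[2])
        nm <- if (types[i] == "ASN") "ND2" else "OD2"
        at[[nm]] <- nerf_place(ca[i, ], at$CB, at$CG, 1.33, 118,
                               tors[2] + 180)
      } else if (types[i] %in% c("GLU", "GLN")) {
        at$CD <- nerf_place(ca[i, ], at$CB, at$CG, 1.52, 113, tors[2])
        at$OE1 <- nerf_place(at$CB, at$CG, at$CD, 1.23, 121, tors[3])
        nm <- if (types[i] == "GLN") "NE2" else "OE2"
        at[[nm]] <- nerf_place(at$CB, at$CG, at$CD, 1.33, 118,
                               tors[3] + 180)
      }
    }
    rows[[i]] <- tibble::tibble(resno = i, resid = types[i],
                                elety = names(at),
                                x = vapply(at, `[[`, 1, 1),
                                y = vapply(at, `[[`, 1, 2),
                                z = vapply(at, `[[`, 1, 3))
  }
  dplyr::bind_rows(rows)
}

# close-packed occluding lattice around a coordinate set: carbon atoms on a
# cubic grid filling the neighbourhood of every input atom (contact
# distance ~ van der Waals, spacing too tight for a water probe), split
# into <=200-atom HETATM residues. Occlusion in the Shrake-Rupley sense is
# local, so burial requires packing, not an enclosing hollow shell.
burial_shell <- function(coords, contact = 2.9, margin = 6.0,
                         spacing = 2.6) {
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  grid <- as.matrix(expand.grid(
    x = seq(lo[1], hi[1], by = spacing),
    y = seq(lo[2], hi[2], by = spacing),
    z = seq(lo[3], hi[3], by = spacing)
  ))
  # keep lattice points clear of the embedded atoms but nothing else
  min_d2 <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(coords))) {
    d2 <- (grid[, 1] - coords[i, 1])^2 + (grid[, 2] - coords[i, 2])^2 +
      (grid[, 3] - coords[i, 3])^2
    min_d2 <- pmin(min_d2, d2)
  }
  pts <- grid[min_d2 >= contact^2, , drop = FALSE]
  grp <- (seq_len(nrow(pts)) - 1L) %/% 200L
  tibble::tibble(
    resno = 901L + grp,
    resid = "SHL",
    elety = paste0("C", sprintf("%03d", (seq_len(nrow(pts)) - 1L) %% 200L)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
}

# --- planted-structure generators ------------------------------------------

#' Specification of a planted isopeptide-bond fixture
#'
#' @param triad_type One of `"Lys-Asn-Asp"`, `"Lys-Asp-Glu"`,
#'   `"Lys-Asn-Glu"`.
#' @param topology `"CnaA-like"` (generated trans) or `"CnaB-like"` (cis).
#' @param noise_sigma Isotropic Gaussian coordinate noise (Angstrom),
#'   applied i.i.d. to every atom after construction.
#' @param bond_length Planted NZ-acyl-carbon distance (Angstrom).
#' @param dihedrals Named vector `c(phi, psi, omega)` in degrees, or `NULL`
#'   to draw from the topology's distribution.
#' @param burial `"buried"` (close-packed occluding shell around the triad,
#'   the physiological situation) or `"exposed"`.
#' @param n_decoy Number of decoy chain residues surrounding the triad in
#'   sequence.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(triad_type = "Lys-Asn-Asp", topology = "CnaA-like",
                       noise_sigma = 0, bond_length = BOND_LENGTH_MEAN,
                       dihedrals = NULL, burial = c("buried", "exposed"),
                       n_decoy = 40, seed = 1) {
  stopifnot(triad_type %in% TRIAD_TYPES, topology %in% TOPOLOGIES,
            noise_sigma >= 0, bond_length > 0)
  structure(list(triad_type = triad_type, topology = topology,
                 noise_sigma = noise_sigma, bond_length = bond_length,
                 dihedrals = dihedrals, burial = match.arg(burial),
                 n_decoy = n_decoy, seed = as.integer(seed)),
            class = "plant_spec")
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 7919) %% 2147483629)
}

#' Generate a structure with a planted isopeptide bond
#'
#' Constructs an idealized bonded triad from standard internal coordinates
#' (exactly reproducing the requested bond length and pseudo-dihedrals),
#' embeds it in a decoy chain (spatially offset, sequentially contiguous),
#' optionally wraps the triad in a close-packed occluding shell, and adds
#' isotropic Gaussian coordinate noise. Deterministic given the spec.
#'
#' @param spec A [plant_spec()].
#' @param id Structure identifier.
#' @return A list: `structure` (an `iso_structure`) and `truth` (one-row
#'   tibble with the ground-truth site, planted geometry and provenance).
#' @export
make_positive <- function(spec, id = sprintf("pos_seed%d", spec$seed)) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::with_seed(spec$seed, {
    dihedrals <- spec$dihedrals
    if (is.null(dihedrals)) {
      g <- sample_site_geometry(spec$topology)
      dihedrals <- g[c("phi", "psi", "omega")]
    }
    triad <- build_triad(spec$triad_type, spec$topology,
                         bond_length = spec$bond_length,
                         dihedrals = dihedrals)
    n_front <- spec$n_decoy %/% 2
    n_back <- spec$n_decoy - n_front
    decoy <- decoy_atoms(spec$n_decoy)
    decoy$x <- decoy$x + 40  # spatially remote, sequentially contiguous

    lys_no <- n_front + 1L; cat_no <- n_front + 2L; acc_no <- n_front + 3L
    triad_no <- c(bond_lys = lys_no, catalytic = cat_no,
                  bond_acceptor = acc_no)
    decoy$resno <- ifelse(decoy$resno <= n_front, decoy$resno,
                          decoy$resno + 3L)
    triad_at <- tibble::tibble(
      resno = unname(triad_no[triad$role]), resid = triad$resid,
      elety = triad$elety, x = triad$x, y = triad$y, z = triad$z
    )
    at <- dplyr::bind_rows(decoy, triad_at)
    at$type <- "ATOM"
    if (spec$burial == "buried") {
      shell <- burial_shell(as.matrix(triad_at[, c("x", "y", "z")]))
      shell$type <- "HETATM"
      at <- dplyr::bind_rows(at, shell)
    }
    at <- dplyr::arrange(at, .data$resno, factor(.data$elety,
                                                 levels = unique(.data$elety)))
    if (spec$noise_sigma > 0) {
      at$x <- at$x + stats::rnorm(nrow(at), 0, spec$noise_sigma)
      at$y <- at$y + stats::rnorm(nrow(at), 0, spec$noise_sigma)
      at$z <- at$z + stats::rnorm(nrow(at), 0, spec$noise_sigma)
    }
    at$chain <- "A"
    st <- as_structure(at, id = id)
    res <- triad_residues(spec$triad_type)
    truth <- tibble::tibble(
      structure_id = id, chain = "A",
      lys_resno = lys_no, cat_resno = cat_no, acc_resno = acc_no,
      lys_resid = res[["bond_lys"]], cat_resid = res[["catalytic"]],
      acc_resid = res[["bond_acceptor"]],
      triad_type = spec$triad_type, topology = spec$topology,
      bond_length = spec$bond_length,
      phi = unname(dihedrals[["phi"]]), psi = unname(dihedrals[["psi"]]),
      omega = unname(dihedrals[["omega"]]),
      burial = spec$burial, noise_sigma = spec$noise_sigma, seed = spec$seed
    )
    list(structure = st, truth = truth)
  })
}

#' Generate a decoy structure guaranteed free of template matches
#'
#' Builds a self-avoiding random-walk chain with standard side chains and
#' verifies by rejection (re-generating with a derived seed) that the
#' template matcher finds no hit at the given configuration.
#'
#' @param n_residues Chain length (at least 20).
#' @param seed Integer seed.
#' @param library Template library used for the rejection check.
#' @param config Search configuration for the rejection check.
#' @param max_tries Rejection budget.
#' @param id Structure identifier.
#' @return An `iso_structure`.
#' @export
make_negative <- function(n_residues, seed,
                          library = default_template_library(),
                          config = search_config(), max_tries = 20,
                          id = sprintf("neg_seed%d", seed)) {
  stopifnot(n_residues >= 20)
  for (t in seq_len(max_tries)) {
    at <- withr::with_seed(derive_seed(seed, t - 1L), decoy_atoms(n_residues))
    at$type <- "ATOM"
    at$chain <- "A"
    st <- as_structure(at, id = id)
    if (nrow(find_matches(st, library, config)) == 0L) return(st)
  }
  stop("decoy rejection budget exhausted: could not generate a match-free ",
       "structure in ", max_tries, " tries")
}

#' Default bundled template library
#'
#' The synthetic fixture library shipped with the package (the original
#' curated template set is not redistributable from this package); twelve
#' idealized-triad templates covering the three triad types and both
#' topologies. Point the pipeline at your own directory for production
#' scanning.
#'
#' @return An `iso_template_library`.
#' @export
default_template_library <- function() {
  load_template_library(iso_extdata("templates_synthetic"))
}

# template row cut from a planted structure: labeled side-chain atoms plus
# the site's real flank sequence, so identity exclusion is exercisable
template_from_structure <- function(structure, truth, id) {
  site <- truth_site(truth)
  atoms <- list()
  roles <- c(bond_lys = "lys", catalytic = "cat", bond_acceptor = "acc")
  for (role in TRIAD_ROLES) {
    pre <- roles[[role]]
    resid <- truth[[paste0(pre, "_resid")]]
    names <- TEMPLATE_ATOMS[[resid]]
    m <- residue_atom_coords(structure, truth$chain,
                             truth[[paste0(pre, "_resno")]], "", names)
    if (is.null(m)) stop("truth residue lacks template atoms")
    atoms[[role]] <- tibble::tibble(role = role, resid = resid,
                                    elety = names,
                                    x = m[, 1], y = m[, 2], z = m[, 3])
  }
  tibble::tibble(
    id = id, topology = truth$topology, triad_type = truth$triad_type,
    flank_sequence = site_flank(structure, site),
    atoms = list(dplyr::bind_rows(atoms))
  )
}

truth_site <- function(truth) {
  list(lys_chain = truth$chain, lys_resno = truth$lys_resno, lys_insert = "",
       cat_chain = truth$chain, cat_resno = truth$cat_resno, cat_insert = "",
       acc_chain = truth$chain, acc_resno = truth$acc_resno, acc_insert = "",
       lys_resid = truth$lys_resid, cat_resid = truth$cat_resid,
       acc_resid = truth$acc_resid, topology = truth$topology)
}

#' Generate an idealized synthetic template library
#'
#' One or more templates per (triad type x topology) combination, built
#' from the generator's idealized geometries: the first variant sits at the
#' topology's dihedral means, further variants at small deterministic
#' offsets. Flank sequences are random (seeded).
#'
#' @param n_per_combo Templates per combination (default 2).
#' @param seed Integer seed (flank sequences and offsets).
#' @return An `iso_template_library`.
#' @export
make_template_library <- function(n_per_combo = 2, seed = 202) {
  withr::with_seed(seed, {
    rows <- list()
    for (tt in TRIAD_TYPES) for (topo in TOPOLOGIES) {
      g <- TOPOLOGY_GEOMETRY[[topo]]
      for (k in seq_len(n_per_combo)) {
        off <- if (k == 1) c(0, 0, 0) else (-1)^k * 6 * c(1, -1, 1) * (k %/% 2)
        dih <- c(phi = wrap_angle(g$phi + off[1]),
                 psi = wrap_angle(g$psi + off[2]),
                 omega = wrap_angle(g$omega + off[3]))
        triad <- build_triad(tt, topo, dihedrals = dih)
        lab <- triad[triad$elety %in% unlist(TEMPLATE_ATOMS), , drop = FALSE]
        keep <- mapply(function(role, resid, elety)
          elety %in% TEMPLATE_ATOMS[[resid]],
          lab$role, lab$resid, lab$elety)
        lab <- lab[keep, c("role", "resid", "elety", "x", "y", "z")]
        lab <- lab[order(match(lab$role, TRIAD_ROLES)), ]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = sprintf("syn_%s_%s_%d",
                       gsub("-", "", tolower(substr(topo, 1, 4))),
                       tolower(gsub("Lys-|-", "", tt)), k),
          topology = topo, triad_type = tt,
          flank_sequence = paste(sample(unname(AA_CODE), 43, replace = TRUE),
                                 collapse = ""),
          atoms = list(lab)
        )
      }
    }
    lib <- dplyr::bind_rows(rows)
    structure(lib, class = c("iso_template_library", class(tibble::tibble())),
              version = "synthetic-1")
  })
}

#' Sample a synthetic geometry reference table
#'
#' Draws per-topology pseudo-dihedral triples and bond lengths from the
#' generator's distributions, in the same schema a user would produce from
#' curated real bonds ([read_geometry_reference()]).
#'
#' @param n_per_topology Rows per topology.
#' @param seed Integer seed.
#' @return A tibble with `topology`, `phi`, `psi`, `omega`, `bond_length`.
#' @export
sample_geometry_reference <- function(n_per_topology = 250, seed = 303) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(TOPOLOGIES, function(topo) {
      g <- TOPOLOGY_GEOMETRY[[topo]]
      tibble::tibble(
        topology = topo,
        phi = wrap_angle(stats::rnorm(n_per_topology, g$phi, g$angle_sd)),
        psi = wrap_angle(stats::rnorm(n_per_topology, g$psi, g$angle_sd)),
        omega = wrap_angle(stats::rnorm(n_per_topology, g$omega, g$angle_sd)),
        bond_length = stats::rnorm(n_per_topology, BOND_LENGTH_MEAN,
                                   BOND_LENGTH_SD)
      )
    }))
  })
}

#' Generate a complete self-consistent evaluation corpus
#'
#' Writes, under `dir`: planted-bond and decoy PDB files
#' (`structures/`), a ground-truth table (`truth.tsv`, mirroring the
#' prediction output schema so evaluation is a join), a template library
#' derived from held-out planted geometries (`templates/`, so
#' identity-based exclusion is exercisable against the corpus), and a
#' geometry reference (`geometry_reference.tsv`). Fully deterministic:
#' regenerating with the same arguments reproduces every file byte for
#' byte.
#'
#' @param dir Output directory.
#' @param n_pos,n_neg Numbers of planted-bond and decoy structures.
#' @param seed Master seed; everything else derives from it.
#' @param noise_sigma Coordinate noise for the planted positives
#'   (Angstrom).
#' @param n_neg_residues Decoy chain length.
#' @param n_templates_per_combo Held-out templates per (triad type x
#'   topology).
#' @param n_ref Geometry-reference rows per topology.
#' @return A list: `dir`, `structure_paths`, `truth` (tibble),
#'   `template_dir`, `geometry_reference` path.
#' @export
make_corpus <- function(dir, n_pos = 20, n_neg = 50, seed = 42,
                        noise_sigma = 0.2, n_neg_residues = 60,
                        n_templates_per_combo = 2, n_ref = 250) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)

  # held-out templates: planted geometries never reused for the positives
  tmpl_rows <- list()
  combos <- expand.grid(tt = TRIAD_TYPES, topo = TOPOLOGIES,
                        k = seq_len(n_templates_per_combo),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    sp <- plant_spec(triad_type = combos$tt[i], topology = combos$topo[i],
                     noise_sigma = 0, burial = "exposed",
                     seed = derive_seed(seed, 5000 + i))
    p <- make_positive(sp, id = sprintf("tmpl_%03d", i))
    tmpl_rows[[i]] <- template_from_structure(p$structure, p$truth,
                                              sprintf("held_%03d", i))
  }
  lib <- structure(dplyr::bind_rows(tmpl_rows),
                   class = c("iso_template_library",
                             class(tibble::tibble())),
                   version = sprintf("corpus-seed%d", seed))
  template_dir <- file.path(dir, "templates")
  save_template_library(lib, template_dir)
  lib <- load_template_library(template_dir)

  ref <- sample_geometry_reference(n_ref, seed = derive_seed(seed, 17))
  ref_path <- file.path(dir, "geometry_reference.tsv")
  write_geometry_reference(ref, ref_path)

  paths <- character(0)
  truths <- list()
  for (i in seq_len(n_pos)) {
    sp <- plant_spec(
      triad_type = TRIAD_TYPES[1 + (i - 1) %% 3],
      topology = TOPOLOGIES[1 + (i - 1) %% 2],
      noise_sigma = noise_sigma, burial = "buried",
      seed = derive_seed(seed, i)
    )
    p <- make_positive(sp, id = sprintf("pos_%03d", i))
    f <- file.path(dir, "structures", sprintf("pos_%03d.pdb", i))
    write_structure_pdb(p$structure, f)
    paths <- c(paths, f)
    truths[[i]] <- p$truth
  }
  for (i in seq_len(n_neg)) {
    st <- make_negative(n_neg_residues, seed = derive_seed(seed, 1000 + i),
                        library = lib, id = sprintf("neg_%03d", i))
    f <- file.path(dir, "structures", sprintf("neg_%03d.pdb", i))
    write_structure_pdb(st, f)
    paths <- c(paths, f)
  }
  truth <- truth_to_output_schema(dplyr::bind_rows(truths))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  list(dir = dir, structure_paths = paths, truth = truth,
       template_dir = template_dir, geometry_reference = ref_path)
}
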