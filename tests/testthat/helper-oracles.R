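# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (closed form, brute-force
# dynamic programming, direct summation, or an unrelated library routine).

# Gotoh affine-gap global alignment score (gap of length k costs
# open + k * extend), scored with BLOSUM62 — dynamic-programming oracle for
# the optimal-alignment score behind flank_identity().
oracle_global_score <- function(a, b, open = 10, extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sm[sa[i - 1], sb[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# solvent-exposed area of one of two equal spheres of radius R at center
# distance d: full sphere minus the buried spherical cap (closed form)
spherical_cap_exposed <- function(R, d) {
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# direct kernel-sum log-density, independent of kde_loglik()'s vectorized
# path: plain double loop over augmented samples
oracle_kde_loglik <- function(kde, q) {
  total <- 0
  for (i in seq_len(nrow(kde$samples))) {
    z1 <- (q[1] - kde$samples[i, 1]) / kde$bandwidth[1]
    z2 <- (q[2] - kde$samples[i, 2]) / kde$bandwidth[2]
    total <- total + exp(-(z1^2 + z2^2) / 2) /
      (2 * pi * kde$bandwidth[1] * kde$bandwidth[2])
  }
  log(total / kde$n)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

transform_structure <- function(st, rot, shift) {
  m <- as.matrix(st[, c("x", "y", "z")]) %*% t(rot)
  st$x <- m[, 1] + shift[1]; st$y <- m[, 2] + shift[2]
  st$z <- m[, 3] + shift[3]
  st
}

# bare triad as a parseable structure (no decoy, no shell)
triad_structure <- function(triad_type = "Lys-Asn-Asp",
                            topology = "CnaA-like", bond_length = 1.33,
                            dihedrals = NULL, id = "triad") {
  tr <- isopeptider:::build_triad(triad_type, topology,
                                  bond_length = bond_length,
                                  dihedrals = dihedrals)
  at <- tibble::tibble(type = "ATOM", chain = "A",
                       resno = match(tr$role, isopeptider:::TRIAD_ROLES) + 20L,
                       resid = tr$resid, elety = tr$elety,
                       x = tr$x, y = tr$y, z = tr$z)
  as_structure(at, id = id)
}

triad_site <- function(acc_resid = "ASN", topology = "CnaA-like") {
  list(lys_chain = "A", lys_resno = 21L, lys_insert = "",
       cat_chain = "A", cat_resno = 22L, cat_insert = "",
       acc_chain = "A", acc_resno = 23L, acc_insert = "",
       acc_resid = acc_resid, topology = topology)
}

# hand-written three-residue PDB fixture with altlocs, a water and a ligand
write_mini_pdb <- function(path) {
  lines <- c(
    "HEADER    SYNTHETIC FIXTURE",
    "ATOM      1  N   LYS A  10      11.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  LYS A  10      12.458   2.000   3.000  1.00 10.00           C",
    "ATOM      3  NZ ALYS A  10      13.000   3.500   3.000  0.60 10.00           N",
    "ATOM      4  NZ BLYS A  10      13.900   3.900   3.900  0.40 12.00           N",
    "ATOM      5  N   ASN A  11      14.000   2.000   5.000  1.00 10.00           N",
    "ATOM      6  CA  ASN A  11      15.458   2.000   5.000  1.00 10.00           C",
    "ATOM      7  N   ASP A  12      17.000   2.000   7.000  1.00 10.00           N",
    "ATOM      8  CA  ASP A  12      18.458   2.000   7.000  1.00 10.00           C",
    "HETATM    9  C1  LIG A  13      20.000   5.000   9.000  1.00 20.00           C",
    "HETATM   10  O   HOH A  14      25.000   5.000   9.000  1.00 20.00           O",
    "END")
  writeLines(lines, path)
  path
}
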