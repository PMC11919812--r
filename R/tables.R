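#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Standard 20 amino acids, three-letter -> one-letter
AA_CODE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

TOPOLOGIES <- c("CnaA-like", "CnaB-like")
TRIAD_TYPES <- c("Lys-Asn-Asp", "Lys-Asp-Glu", "Lys-Asn-Glu")

# role order is fixed everywhere: bond-forming Lys, catalytic Asp/Glu,
# bond-accepting Asn/Asp
TRIAD_ROLES <- c("bond_lys", "catalytic", "bond_acceptor")

# residue names per role implied by each triad type (second element of the
# type string is the acceptor, third the catalytic residue)
triad_residues <- function(triad_type) {
  parts <- toupper(unlist(strsplit(triad_type, "-", fixed = TRUE)))
  long <- c(LYS = "LYS", ASN = "ASN", ASP = "ASP", GLU = "GLU")
  stopifnot(length(parts) == 3L, all(parts %in% names(long)))
  c(bond_lys = long[[parts[1]]],
    catalytic = long[[parts[3]]],
    bond_acceptor = long[[parts[2]]])
}

# side-chain atoms carried by templates, per residue type
TEMPLATE_ATOMS <- list(
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2")
)

# chemically indistinguishable atom-name pairs; deposited naming is arbitrary
SYMMETRIC_ATOMS <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2"))
)

.iso_cache <- new.env(parent = emptyenv())

iso_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "isopeptider", mustWork = TRUE)
  path
}

#' Van der Waals radius table used for solvent accessibility
#'
#' Element-wise van der Waals radii (Angstrom) shipped as a plain-text
#' resource, used by [compute_sasa()]. Elements absent from the table fall
#' back to 1.70 Angstrom (carbon).
#'
#' @return A tibble with columns `element` and `radius`.
#' @export
vdw_radii <- function() {
  if (is.null(.iso_cache$vdw)) {
    .iso_cache$vdw <- readr::read_tsv(iso_extdata("vdw_radii.tsv"),
                                      show_col_types = FALSE)
  }
  .iso_cache$vdw
}

#' Rost-Sander maximum accessible surface areas
#'
#' Per-residue-type maximum accessible surface area (Angstrom^2) used to
#' normalise absolute SASA into relative accessibility (rASA).
#'
#' @return A tibble with columns `resid` (three-letter code) and `max_asa`.
#' @export
max_asa_table <- function() {
  if (is.null(.iso_cache$max_asa)) {
    .iso_cache$max_asa <- readr::read_tsv(iso_extdata("max_asa_rost_sander.tsv"),
                                          show_col_types = FALSE)
  }
  .iso_cache$max_asa
}

vdw_radius_of <- function(element) {
  tab <- vdw_radii()
  r <- tab$radius[match(toupper(element), tab$element)]
  r[is.na(r)] <- 1.70
  r
}
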