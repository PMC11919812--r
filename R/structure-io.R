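#' Read a protein structure into an atom tibble
#'
#' Parses a PDB or mmCIF file into a flat atom table, one row per atom.
#' Only the first model is retained. For atoms deposited with alternate
#' locations, the highest-occupancy altloc is kept (ties broken by file
#' order). Waters are removed; other heteroatoms are kept and flagged
#' `nonstandard`. Hydrogens are retained but nothing downstream requires
#' them.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format Optional format hint, `"pdb"` or `"cif"`; by default the
#'   file extension decides.
#' @param id Structure identifier stored in the `structure_id` column;
#'   defaults to the file name without extension.
#' @return A tibble of class `iso_structure` with columns `structure_id`,
#'   `record`, `chain`, `resno`, `insert`, `resid`, `elety`, `elesy`,
#'   `x`, `y`, `z`, `o`, `b`, `het`, `nonstandard`, in file order, and an
#'   attribute `source_format`.
#' @export
#' @examples
#' pdb <- make_positive(plant_spec(seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' write_structure_pdb(pdb$structure, f)
#' s <- read_structure(f)
#' dplyr::count(s, chain)
read_structure <- function(path, format = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format %||% guess_format(path)
  raw <- switch(fmt,
    pdb = tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                   error = function(e) stop("PDB parse error in '", path, "': ",
                                            conditionMessage(e), call. = FALSE)),
    cif = tryCatch(
      withCallingHandlers(
        bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
        # advisory notes from the parser, not data problems
        warning = function(w) {
          if (grepl("beta version|helix/sheet", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) stop("mmCIF parse error in '", path,
                               "' (atom_site): ",
                               conditionMessage(e), call. = FALSE)),
    stop("unknown structure format: ", fmt)
  )
  at <- tibble::as_tibble(raw$atom)
  id <- id %||% sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                    basename(path), ignore.case = TRUE)
  as_structure(at, id = id, source_format = fmt)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an `iso_structure` from a bio3d-style atom table
#'
#' Applies the standard cleanup contract: single model, altloc resolution by
#' highest occupancy (file order breaks ties), water removal, heteroatom and
#' nonstandard-residue flagging.
#'
#' @param atoms A data frame with bio3d `$atom` columns (`type`, `elety`,
#'   `alt`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`,
#'   `elesy`).
#' @param id Structure identifier.
#' @param source_format Stored as an attribute (`"pdb"`, `"cif"` or
#'   `"generated"`).
#' @return An `iso_structure` tibble.
#' @export
as_structure <- function(atoms, id = "structure", source_format = "generated") {
  at <- tibble::as_tibble(atoms)
  needed <- c("type", "elety", "resid", "chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(at))
  if (length(missing)) stop("atom table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!"alt" %in% names(at)) at$alt <- NA_character_
  if (!"insert" %in% names(at)) at$insert <- NA_character_
  if (!"o" %in% names(at)) at$o <- 1
  if (!"b" %in% names(at)) at$b <- 0
  if (!"elesy" %in% names(at)) at$elesy <- guess_element(at$elety)
  at$o[is.na(at$o)] <- 1
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) stop("non-finite coordinates for ", sum(bad), " atom(s)")

  at <- dplyr::filter(at, !(toupper(.data$resid) %in% WATER_NAMES))
  if (nrow(at) == 0L) stop("empty structure: no non-water atoms in '", id, "'")

  # altloc resolution: keep the highest-occupancy record per atom slot
  at$.ord <- seq_len(nrow(at))
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid,
                    .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  out <- tibble::tibble(
    structure_id = id,
    record = at$type,
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = toupper(at$resid),
    elety = at$elety,
    elesy = toupper(ifelse(is.na(at$elesy), guess_element(at$elety), at$elesy)),
    x = at$x, y = at$y, z = at$z,
    o = at$o, b = at$b
  )
  out$het <- out$record == "HETATM"
  out$nonstandard <- out$het | !(out$resid %in% names(AA_CODE))
  if (!any(!out$nonstandard)) stop("empty structure: no standard protein ",
                                   "residues in '", id, "'")
  structure(out, class = c("iso_structure", class(tibble::tibble())),
            source_format = source_format)
}

guess_element <- function(elety) {
  e <- toupper(sub("^[0-9]*", "", elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA"), two, one)
}

residue_key <- function(chain, resno, insert) {
  paste0(chain, ":", resno, ifelse(insert == "" | is.na(insert), "",
                                   paste0(":", insert)))
}

# per-residue summary of an iso_structure
structure_residues <- function(structure) {
  structure |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert, .data$resid,
                    .data$het, .data$nonstandard) |>
    dplyr::mutate(key = residue_key(.data$chain, .data$resno, .data$insert))
}

# coordinates of named atoms of one residue; NULL if any is absent
residue_atom_coords <- function(structure, chain, resno, insert, atom_names) {
  rows <- structure[structure$chain == chain & structure$resno == resno &
                      structure$insert == (insert %||% ""), , drop = FALSE]
  idx <- match(atom_names, rows$elety)
  if (anyNA(idx)) return(NULL)
  as.matrix(rows[idx, c("x", "y", "z")])
}

#' Extract a chain's one-letter sequence with a residue-number map
#'
#' Nonstandard residues (including heteroatom ligands kept in the structure)
#' are emitted as `X`. The returned map is invertible onto modeled residues:
#' row `pos` holds the chain, residue number and insertion code of the
#' residue whose letter sits at that position.
#'
#' @param structure An `iso_structure`.
#' @param chain_id Chain identifier.
#' @return A tibble with columns `pos`, `chain`, `resno`, `insert`, `resid`,
#'   `letter`, in modeled order. Collapse `letter` for the plain string.
#' @export
extract_sequence <- function(structure, chain_id) {
  res <- structure_residues(structure)
  if (!chain_id %in% res$chain) stop("unknown chain: ", chain_id)
  res <- res[res$chain == chain_id, , drop = FALSE]
  letter <- unname(AA_CODE[res$resid])
  letter[is.na(letter) | res$nonstandard] <- "X"
  tibble::tibble(
    pos = seq_len(nrow(res)),
    chain = res$chain, resno = res$resno, insert = res$insert,
    resid = res$resid, letter = letter
  )
}

sequence_string <- function(seq_map) paste(seq_map$letter, collapse = "")

#' Write an `iso_structure` as a PDB file
#'
#' @param structure An `iso_structure` (or compatible atom tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  s <- structure
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    type = if ("record" %in% names(s)) s$record else "ATOM",
    resno = s$resno, resid = s$resid, chain = s$chain,
    elety = s$elety, insert = ifelse(s$insert == "", NA, s$insert),
    o = if ("o" %in% names(s)) s$o else 1,
    b = if ("b" %in% names(s)) s$b else 0, elesy = s$elesy
  )
  invisible(path)
}

#' Write an `iso_structure` as a minimal mmCIF file
#'
#' Emits a single `atom_site` loop (author numbering mirrored into the label
#' fields), sufficient for round-tripping through [read_structure()].
#'
#' @inheritParams write_structure_pdb
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(structure, path) {
  s <- structure
  hdr <- c(
    paste0("data_", s$structure_id[1] %||% "structure"),
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"))
  )
  rows <- sprintf(
    "%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    if ("record" %in% names(s)) s$record else "ATOM",
    seq_len(nrow(s)), s$elesy, s$elety, s$resid, s$chain, s$resno,
    ifelse(s$insert == "" | is.na(s$insert), "?", s$insert),
    s$x, s$y, s$z, if ("o" %in% names(s)) s$o else 1,
    if ("b" %in% names(s)) s$b else 0,
    s$resno, s$resid, s$chain, s$elety
  )
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
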