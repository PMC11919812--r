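#' Load a triad template library from a directory
#'
#' A template library is a directory holding one PDB-fragment file per
#' template: ATOM records for the labeled side-chain atoms of the three triad
#' residues (residue 1 = bond-forming Lys, residue 2 = catalytic Asp/Glu,
#' residue 3 = bond-accepting Asn/Asp), preceded by a metadata line
#'
#'     REMARK ISOPEPTIDE id=... topology=... triad_type=... flank=...
#'
#' Fragments remain viewable in molecular graphics programs. An optional
#' `LIBRARY` file with a `version=` line sets the library version.
#' Malformed templates make the whole load fail, with every offending file
#' named — a library is never silently truncated.
#'
#' @param dir_path Directory of template files.
#' @return A tibble of class `iso_template_library` with one row per
#'   template: `id`, `topology`, `triad_type`, `flank_sequence` and an
#'   `atoms` list-column of tibbles (`role`, `resid`, `elety`, `x`, `y`,
#'   `z`), plus a `version` attribute.
#' @export
load_template_library <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("template directory not found: ", dir_path)
  files <- sort(list.files(dir_path, pattern = "\\.pdb$", full.names = TRUE))
  if (length(files) == 0L) stop("empty template directory: ", dir_path)
  parsed <- lapply(files, function(f) {
    tryCatch(list(ok = read_template_file(f)),
             error = function(e) list(err = paste0(basename(f), ": ",
                                                   conditionMessage(e))))
  })
  errs <- unlist(lapply(parsed, `[[`, "err"))
  if (length(errs)) stop("invalid template file(s):\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  lib <- dplyr::bind_rows(lapply(parsed, `[[`, "ok"))
  if (anyDuplicated(lib$id)) stop("duplicate template ids: ",
                                  paste(unique(lib$id[duplicated(lib$id)]),
                                        collapse = ", "))
  version <- "unversioned"
  vf <- file.path(dir_path, "LIBRARY")
  if (file.exists(vf)) {
    ln <- grep("^version=", readLines(vf, warn = FALSE), value = TRUE)
    if (length(ln)) version <- sub("^version=", "", ln[1])
  }
  structure(lib, class = c("iso_template_library", class(tibble::tibble())),
            version = version)
}

read_template_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_line <- grep("^REMARK ISOPEPTIDE", lines, value = TRUE)
  if (length(meta_line) != 1L) stop("expected exactly one 'REMARK ISOPEPTIDE' ",
                                    "metadata line")
  meta <- parse_kv(sub("^REMARK ISOPEPTIDE\\s+", "", meta_line))
  for (k in c("topology", "triad_type", "flank")) {
    if (is.null(meta[[k]])) stop("metadata line lacks '", k, "='")
  }
  if (!meta$topology %in% TOPOLOGIES)
    stop("unknown topology '", meta$topology, "'")
  if (!meta$triad_type %in% TRIAD_TYPES)
    stop("unknown triad_type '", meta$triad_type, "'")
  if (!nzchar(meta$flank)) stop("empty flank sequence")
  at <- tibble::as_tibble(bio3d::read.pdb(path, verbose = FALSE)$atom)
  if (!all(sort(unique(at$resno)) == 1:3))
    stop("template must contain residues numbered 1 (bond_lys), ",
         "2 (catalytic), 3 (bond_acceptor)")
  expected <- triad_residues(meta$triad_type)
  atoms <- tibble::tibble(
    role = TRIAD_ROLES[at$resno],
    resid = toupper(at$resid),
    elety = at$elety,
    x = at$x, y = at$y, z = at$z
  )
  for (i in 1:3) {
    got <- unique(atoms$resid[atoms$role == TRIAD_ROLES[i]])
    if (!identical(got, unname(expected[[TRIAD_ROLES[i]]])))
      stop("residue ", i, " is ", paste(got, collapse = "/"),
           " but triad_type '", meta$triad_type, "' requires ",
           expected[[TRIAD_ROLES[i]]])
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite template coordinates")
  tibble::tibble(
    id = meta$id %||% sub("\\.pdb$", "", basename(path)),
    topology = meta$topology,
    triad_type = meta$triad_type,
    flank_sequence = meta$flank,
    atoms = list(atoms)
  )
}

parse_kv <- function(s) {
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) paste(p[-1], collapse = "="))
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

#' Save a template library to a directory
#'
#' Inverse of [load_template_library()]; coordinates are written at 0.001
#' Angstrom precision (the PDB coordinate field), so save/load round-trips
#' the on-disk representation exactly.
#'
#' @param library An `iso_template_library`.
#' @param dir_path Output directory (created if needed).
#' @param version Version string written to the `LIBRARY` file.
#' @return `dir_path`, invisibly.
#' @export
save_template_library <- function(library, dir_path,
                                  version = attr(library, "version") %||%
                                    "unversioned") {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(library))) {
    at <- library$atoms[[i]]
    resno <- match(at$role, TRIAD_ROLES)
    lines <- c(
      sprintf("REMARK ISOPEPTIDE id=%s topology=%s triad_type=%s flank=%s",
              library$id[i], library$topology[i], library$triad_type[i],
              library$flank_sequence[i]),
      sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              seq_len(nrow(at)),
              ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
              at$resid, "T", resno, at$x, at$y, at$z, 1, 0,
              guess_element(at$elety)),
      "END"
    )
    writeLines(lines, file.path(dir_path, paste0(library$id[i], ".pdb")))
  }
  writeLines(paste0("version=", version), file.path(dir_path, "LIBRARY"))
  invisible(dir_path)
}

#' Percent identity between two flank sequences
#'
#' Optimal global alignment (BLOSUM62, affine gaps: open 10, extend 1) of
#' the two flank strings; identity is the number of identical aligned
#' positions over the alignment length, as a percentage. Used to exclude
#' template matches onto sites the template was derived from (or close
#' homologs) in training/evaluation mode.
#'
#' @param a,b Amino-acid strings (one-letter codes; `X` allowed).
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' flank_identity("KND", "KNE") # 66.67
flank_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty flank sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1, type = "global"
  )
  # PID1: identical positions / alignment length (gaps included)
  Biostrings::pid(aln, type = "PID1")
}

# flank of a matched site: 20 residues upstream of the first triad residue
# through 20 downstream of the last, in modeled-sequence space, truncated at
# chain ends. For the rare cross-chain site the per-chain windows are
# concatenated in chain order.
site_flank <- function(structure, site) {
  res <- tibble::tibble(
    chain = c(site$lys_chain, site$cat_chain, site$acc_chain),
    resno = c(site$lys_resno, site$cat_resno, site$acc_resno),
    insert = c(site$lys_insert %||% "", site$cat_insert %||% "",
               site$acc_insert %||% "")
  )
  out <- character(0)
  for (ch in sort(unique(res$chain))) {
    map <- extract_sequence(structure, ch)
    here <- res[res$chain == ch, , drop = FALSE]
    pos <- map$pos[match(residue_key(here$chain, here$resno, here$insert),
                         residue_key(map$chain, map$resno, map$insert))]
    if (anyNA(pos)) stop("site residue not found in chain ", ch)
    lo <- max(1L, min(pos) - 20L)
    hi <- min(nrow(map), max(pos) + 20L)
    out <- c(out, paste(map$letter[lo:hi], collapse = ""))
  }
  paste(out, collapse = "")
}
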