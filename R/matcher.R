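#' Search configuration for template matching
#'
#' @param rmsd_cutoff Maximum superposition RMSD (Angstrom) for a reported
#'   hit.
#' @param distance_tolerance Maximum allowed deviation (Angstrom) of any
#'   target pairwise inter-atom distance from the template's, used both as
#'   the match definition and for search pruning.
#' @param max_hits_per_site Cap on reported hits per residue triple (lowest
#'   RMSD first); `Inf` keeps all.
#' @return A list of class `iso_search_config`.
#' @export
search_config <- function(rmsd_cutoff = 2.0, distance_tolerance = 1.5,
                          max_hits_per_site = Inf) {
  stopifnot(rmsd_cutoff > 0, distance_tolerance > 0, max_hits_per_site > 0)
  structure(list(rmsd_cutoff = rmsd_cutoff,
                 distance_tolerance = distance_tolerance,
                 max_hits_per_site = max_hits_per_site),
            class = "iso_search_config")
}

# Candidate residues for one triad role of one template: standard (non-het)
# residues of the required type carrying every labeled atom name. Returns a
# list of candidates, each with the residue identity and one coordinate
# matrix per admissible atom-naming variant (chemically symmetric carboxylate
# oxygens may be swapped; deposited naming is arbitrary).
role_candidates <- function(structure, resid_needed, atom_names) {
  res <- structure_residues(structure)
  res <- res[res$resid == resid_needed & !res$het, , drop = FALSE]
  if (nrow(res) == 0L) return(list())
  namings <- atom_namings(resid_needed, atom_names)
  out <- vector("list", nrow(res))
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    mats <- list()
    for (nm in namings) {
      m <- residue_atom_coords(structure, res$chain[i], res$resno[i],
                               res$insert[i], nm)
      if (!is.null(m)) mats[[length(mats) + 1L]] <- m
    }
    if (length(mats)) {
      out[[i]] <- list(chain = res$chain[i], resno = res$resno[i],
                       insert = res$insert[i], resid = res$resid[i],
                       key = res$key[i], coords = mats)
      keep[i] <- TRUE
    }
  }
  out[keep]
}

# all admissible orderings of target atom names for the template's atom list
atom_namings <- function(resid, atom_names) {
  namings <- list(atom_names)
  for (pair in SYMMETRIC_ATOMS[[resid]] %||% list()) {
    if (all(pair %in% atom_names)) {
      swapped <- lapply(namings, function(nm) {
        i <- match(pair, nm)
        nm[i] <- nm[rev(i)]
        nm
      })
      namings <- c(namings, swapped)
    }
  }
  namings
}

all_pair_dists_ok <- function(d_target, d_template, tol) {
  max(abs(d_target - d_template)) <= tol
}

cross_dists <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
}

#' Find template matches in a structure
#'
#' For every template, searches for assignments of three distinct target
#' residues (types matched strictly to the template's triad; the three
#' residues may lie on different chains) whose labeled atoms reproduce every
#' template pairwise inter-atom distance within `distance_tolerance`. Each
#' surviving assignment is scored by optimal least-squares superposition
#' RMSD ([kabsch_rmsd()]); hits with RMSD at most `rmsd_cutoff` are
#' returned. The search proceeds residue-role by residue-role with pairwise
#' distance pruning; symmetric carboxylate oxygen namings are tried both
#' ways and the lower-RMSD assignment kept.
#'
#' @param structure An `iso_structure`.
#' @param library An `iso_template_library`.
#' @param config An [search_config()].
#' @return A tibble with one row per (template, residue-triple) hit:
#'   structure/template identity, topology, triad type, RMSD, and the
#'   chain/resno/insert/resid of the three roles (`lys_*`, `cat_*`,
#'   `acc_*`), plus `site_key` identifying the unordered residue triple.
#' @export
find_matches <- function(structure, library, config = search_config()) {
  stopifnot(inherits(config, "iso_search_config"), nrow(library) > 0)
  tol <- config$distance_tolerance
  hits <- list()
  for (ti in seq_len(nrow(library))) {
    tmpl <- library[ti, ]
    at <- tmpl$atoms[[1]]
    tmat <- as.matrix(at[, c("x", "y", "z")])
    d_t <- as.matrix(stats::dist(tmat))
    idx <- split(seq_len(nrow(at)), at$role)[TRIAD_ROLES]
    need <- triad_residues(tmpl$triad_type)
    cand <- lapply(TRIAD_ROLES, function(ro)
      role_candidates(structure, need[[ro]], at$elety[idx[[ro]]]))
    names(cand) <- TRIAD_ROLES
    if (any(vapply(cand, length, 1L) == 0L)) next

    il <- idx$bond_lys; ic <- idx$catalytic; ia <- idx$bond_acceptor
    ord <- order(c(il, ic, ia))
    for (L in cand$bond_lys) {
      lm <- L$coords[[1]]
      if (!all_pair_dists_ok(as.matrix(stats::dist(lm)), d_t[il, il], tol)) next
      for (C in cand$catalytic) {
        if (C$key == L$key) next
        cms <- Filter(function(cm) {
          all_pair_dists_ok(cross_dists(lm, cm), d_t[il, ic], tol) &&
            all_pair_dists_ok(as.matrix(stats::dist(cm)), d_t[ic, ic], tol)
        }, C$coords)
        if (!length(cms)) next
        for (A in cand$bond_acceptor) {
          if (A$key == L$key || A$key == C$key) next
          best <- Inf
          for (am in A$coords) {
            if (!all_pair_dists_ok(cross_dists(lm, am), d_t[il, ia], tol)) next
            if (!all_pair_dists_ok(as.matrix(stats::dist(am)), d_t[ia, ia],
                                   tol)) next
            for (cm in cms) {
              if (!all_pair_dists_ok(cross_dists(cm, am), d_t[ic, ia],
                                     tol)) next
              r <- kabsch_rmsd(tmat, rbind(lm, cm, am)[ord, , drop = FALSE])
              if (r < best) best <- r
            }
          }
          if (best <= config$rmsd_cutoff) {
            hits[[length(hits) + 1L]] <- hit_row(structure, tmpl, L, C, A,
                                                 best)
          }
        }
      }
    }
  }
  finish_hits(hits, config)
}

hit_row <- function(structure, tmpl, L, C, A, rmsd) {
  tibble::tibble(
    structure_id = structure$structure_id[1],
    template_id = tmpl$id, topology = tmpl$topology,
    triad_type = tmpl$triad_type, rmsd = rmsd,
    lys_chain = L$chain, lys_resno = L$resno, lys_insert = L$insert,
    lys_resid = L$resid,
    cat_chain = C$chain, cat_resno = C$resno, cat_insert = C$insert,
    cat_resid = C$resid,
    acc_chain = A$chain, acc_resno = A$resno, acc_insert = A$insert,
    acc_resid = A$resid,
    site_key = paste(sort(c(L$key, C$key, A$key)), collapse = "|")
  )
}

empty_hits <- function() {
  tibble::tibble(
    structure_id = character(), template_id = character(),
    topology = character(), triad_type = character(), rmsd = double(),
    lys_chain = character(), lys_resno = integer(), lys_insert = character(),
    lys_resid = character(),
    cat_chain = character(), cat_resno = integer(), cat_insert = character(),
    cat_resid = character(),
    acc_chain = character(), acc_resno = integer(), acc_insert = character(),
    acc_resid = character(),
    site_key = character()
  )
}

finish_hits <- function(hits, config) {
  if (!length(hits)) return(empty_hits())
  out <- dplyr::bind_rows(hits) |>
    dplyr::arrange(.data$site_key, .data$rmsd, .data$template_id)
  if (is.finite(config$max_hits_per_site)) {
    out <- out |>
      dplyr::group_by(.data$site_key) |>
      dplyr::slice_head(n = config$max_hits_per_site) |>
      dplyr::ungroup()
  }
  out
}

#' Exhaustive reference matcher
#'
#' Enumerates every type-compatible residue triple and every admissible
#' atom naming, applies the full pairwise-distance criterion directly on the
#' complete correspondence, and scores by superposition RMSD. No pruning or
#' search ordering is involved, so this serves as the independent reference
#' implementation for [find_matches()]; it is practical only for small
#' structures.
#'
#' @inheritParams find_matches
#' @return Same schema as [find_matches()].
#' @export
find_matches_brute <- function(structure, library, config = search_config()) {
  stopifnot(inherits(config, "iso_search_config"))
  hits <- list()
  for (ti in seq_len(nrow(library))) {
    tmpl <- library[ti, ]
    at <- tmpl$atoms[[1]]
    tmat <- as.matrix(at[, c("x", "y", "z")])
    d_t <- as.matrix(stats::dist(tmat))
    need <- triad_residues(tmpl$triad_type)
    idx <- split(seq_len(nrow(at)), at$role)[TRIAD_ROLES]
    cand <- lapply(TRIAD_ROLES, function(ro)
      role_candidates(structure, need[[ro]], at$elety[idx[[ro]]]))
    names(cand) <- TRIAD_ROLES
    ord <- order(c(idx$bond_lys, idx$catalytic, idx$bond_acceptor))
    for (L in cand$bond_lys) for (C in cand$catalytic)
      for (A in cand$bond_acceptor) {
        if (length(unique(c(L$key, C$key, A$key))) < 3L) next
        best <- Inf
        for (lm in L$coords) for (cm in C$coords) for (am in A$coords) {
          m <- rbind(lm, cm, am)[ord, , drop = FALSE]
          if (max(abs(as.matrix(stats::dist(m)) - d_t)) >
                config$distance_tolerance) next
          r <- kabsch_rmsd(tmat, m)
          if (r < best) best <- r
        }
        if (best <= config$rmsd_cutoff) {
          hits[[length(hits) + 1L]] <- hit_row(structure, tmpl, L, C, A, best)
        }
      }
  }
  finish_hits(hits, config)
}

#' Keep only the lowest-RMSD template match per site
#'
#' Hits are grouped by unordered residue triple (within a structure);
#' exactly one hit per group is retained — the minimum-RMSD one, with RMSD
#' ties broken by lexicographic template id.
#'
#' @param hits A hit tibble from [find_matches()].
#' @return A tibble with one row per distinct site.
#' @export
reduce_to_best <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    dplyr::group_by(.data$structure_id, .data$site_key) |>
    dplyr::arrange(.data$rmsd, .data$template_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Remove matches onto sites homologous to their template
#'
#' Training/evaluation-mode filter: a hit is dropped when the template's
#' flank sequence aligns to the target site's flank (20 residues up- and
#' downstream of the triad) with identity strictly above the threshold.
#' Identity exactly at the threshold is retained.
#'
#' @param hits A hit tibble.
#' @param structure The `iso_structure` the hits refer to.
#' @param library The template library the hits came from.
#' @param threshold_pct Percent-identity threshold (default 30).
#' @return The filtered hit tibble.
#' @export
exclude_by_identity <- function(hits, structure, library, threshold_pct = 30) {
  if (nrow(hits) == 0L) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    tmpl <- library[library$id == h$template_id, ]
    if (nrow(tmpl) == 0L) stop("hit references unknown template: ",
                               h$template_id)
    target_flank <- site_flank(structure, as.list(h))
    flank_identity(tmpl$flank_sequence[1], target_flank) <= threshold_pct
  }, logical(1))
  hits[keep, , drop = FALSE]
}
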