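#' Detect isopeptide bonds in structure files
#'
#' End-to-end pipeline over one or many PDB/mmCIF files: parse, template
#' scan, keep the lowest-RMSD template per site, compute features (RMSD and
#' triad rASA), classify with the logistic model, and (optionally) score
#' bond geometry for sites predicted positive. Files that fail to parse
#' are skipped with a warning; the call errors only when every input
#' fails. Output is deterministic for fixed inputs.
#'
#' @param paths Character vector of structure files.
#' @param templates An `iso_template_library` or a template directory path.
#' @param model An `iso_model` or a model-file path.
#' @param geometry_ref An `iso_geometry_ref`, a reference TSV path, or
#'   `NULL` for the bundled synthetic reference.
#' @param threshold Decision threshold; default: the model's.
#' @param rmsd_cutoff,distance_tolerance Search parameters, see
#'   [search_config()].
#' @param sasa_points SASA test points per atom (default 500).
#' @param qc Assess geometry of predicted bonds (default `TRUE`).
#' @param identity_exclusion If not `NULL`, training/evaluation mode:
#'   exclude template-site matches with flank identity strictly above this
#'   percentage before site reduction.
#' @return A tibble, one row per detected site, sorted by (structure, chain,
#'   Lys position): `structure_id`, `chain`, `r1_bond`, `r_cat`, `r2_bond`
#'   (author residue numbers of Lys, catalytic and acceptor residues),
#'   residue names, `probability`, `is_bond`, features, closest `template`,
#'   `type` (topology), and geometry-QC columns.
#' @export
#' @examples
#' corpus <- make_corpus(tempfile(), n_pos = 1, n_neg = 1, seed = 7)
#' detect_bonds(corpus$structure_paths,
#'              templates = corpus$template_dir,
#'              geometry_ref = corpus$geometry_reference)
detect_bonds <- function(paths,
                         templates = default_template_library(),
                         model = default_model(),
                         geometry_ref = NULL,
                         threshold = NULL,
                         rmsd_cutoff = 2.0, distance_tolerance = 1.5,
                         sasa_points = 500, qc = TRUE,
                         identity_exclusion = NULL) {
  if (!length(paths)) stop("no input structure files given")
  if (is.character(templates)) templates <- load_template_library(templates)
  if (is.character(model)) model <- read_model(model)
  if (!is.null(threshold)) model$threshold <- threshold
  if (qc) {
    ref <- if (is.null(geometry_ref)) default_geometry_reference()
           else if (is.character(geometry_ref))
             fit_geometry_reference(read_geometry_reference(geometry_ref))
           else geometry_ref
  }
  config <- search_config(rmsd_cutoff = rmsd_cutoff,
                          distance_tolerance = distance_tolerance)

  results <- list()
  n_failed <- 0L
  for (path in paths) {
    st <- tryCatch(read_structure(path), error = function(e) {
      warning("skipping '", path, "': ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(st)) { n_failed <- n_failed + 1L; next }
    hits <- find_matches(st, templates, config)
    if (!is.null(identity_exclusion) && nrow(hits))
      hits <- exclude_by_identity(hits, st, templates, identity_exclusion)
    best <- reduce_to_best(hits)
    if (!nrow(best)) next
    rows <- lapply(seq_len(nrow(best)), function(i) {
      h <- as.list(best[i, ])
      h$topology <- best$topology[i]
      r_asa <- compute_rasa(st, h, n_points = sasa_points)
      feat <- tibble::tibble(rmsd = h$rmsd, r_asa = r_asa)
      pred <- predict_bonds(feat, model)
      out <- tibble::tibble(
        structure_id = h$structure_id, chain = h$lys_chain,
        r1_bond = h$lys_resno, r_cat = h$cat_resno, r2_bond = h$acc_resno,
        r1_bond_name = h$lys_resid, r_cat_name = h$cat_resid,
        r2_bond_name = h$acc_resid,
        probability = pred$probability, is_bond = pred$is_bond,
        rmsd = h$rmsd, r_asa = r_asa,
        template = h$template_id, type = h$topology
      )
      qc_cols <- tibble::tibble(
        bond_length = NA_real_, zscore = NA_real_, zscore_flag = NA,
        phi_psi_likelihood = NA_real_, omega_psi_likelihood = NA_real_,
        omega_phi_likelihood = NA_real_, geometry_flag = NA_character_
      )
      if (qc && pred$is_bond) {
        g <- assess_geometry(st, h, ref)
        qc_cols <- g[, names(qc_cols)]
      }
      dplyr::bind_cols(out, qc_cols)
    })
    results[[length(results) + 1L]] <- dplyr::bind_rows(rows)
  }
  if (n_failed == length(paths)) stop("all ", n_failed,
                                      " input file(s) failed to parse")
  out <- if (length(results)) dplyr::bind_rows(results) else empty_predictions()
  dplyr::arrange(out, .data$structure_id, .data$chain, .data$r1_bond)
}

empty_predictions <- function() {
  tibble::tibble(
    structure_id = character(), chain = character(),
    r1_bond = integer(), r_cat = integer(), r2_bond = integer(),
    r1_bond_name = character(), r_cat_name = character(),
    r2_bond_name = character(),
    probability = double(), is_bond = logical(),
    rmsd = double(), r_asa = double(),
    template = character(), type = character(),
    bond_length = double(), zscore = double(), zscore_flag = logical(),
    phi_psi_likelihood = double(), omega_psi_likelihood = double(),
    omega_phi_likelihood = double(), geometry_flag = character()
  )
}

TSV_COLUMNS <- c(
  "structure_id", "chain", "r1_bond", "r_cat", "r2_bond",
  "r1_bond_name", "r_cat_name", "r2_bond_name", "probability", "rmsd",
  "r_asa", "template", "type", "bond_length", "zscore", "zscore_flag",
  "phi_psi_likelihood", "omega_psi_likelihood", "omega_phi_likelihood",
  "geometry_flag"
)

#' Write predictions as a tab-separated table
#'
#' Fixed, documented column order (`structure_id`, `chain`, `r1_bond`,
#' `r_cat`, `r2_bond`, residue names, `probability`, `rmsd`, `r_asa`,
#' `template`, `type`, then the geometry-QC columns); rows sorted by
#' (structure, chain, Lys position). Rerunning on the same inputs
#' overwrites with byte-identical output.
#'
#' @param predictions A prediction tibble from [detect_bonds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  missing <- setdiff(TSV_COLUMNS, names(predictions))
  if (length(missing)) stop("prediction table lacks column(s): ",
                            paste(missing, collapse = ", "))
  out <- predictions[, TSV_COLUMNS]
  out <- dplyr::arrange(out, .data$structure_id, .data$chain, .data$r1_bond)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Site-level precision and recall against a ground-truth table
#'
#' Predictions and truth are matched on (structure, unordered residue
#' triple). A prediction counts when `is_bond` is `TRUE` (all rows count if
#' the column is absent). Precision is `NA` when nothing was predicted.
#'
#' @param predictions Prediction tibble ([detect_bonds()] output schema).
#' @param truth Truth tibble with columns `structure_id`, `r1_bond`,
#'   `r_cat`, `r2_bond` (the schema written by [make_corpus()]).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  need <- c("structure_id", "r1_bond", "r_cat", "r2_bond")
  if (!all(need %in% names(truth)))
    stop("truth table schema mismatch; need columns: ",
         paste(need, collapse = ", "))
  if (!all(need %in% names(predictions)))
    stop("prediction table schema mismatch; need columns: ",
         paste(need, collapse = ", "))
  site_id <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    trip <- mapply(function(a, b, c) paste(sort(c(a, b, c)), collapse = "-"),
                   d$r1_bond, d$r_cat, d$r2_bond)
    paste0(d$structure_id, "|", trip)
  }
  pos <- predictions
  if ("is_bond" %in% names(pos)) pos <- pos[pos$is_bond %in% TRUE, ,
                                            drop = FALSE]
  p_sites <- unique(site_id(pos))
  t_sites <- unique(site_id(truth))
  tp <- length(intersect(p_sites, t_sites))
  fp <- length(setdiff(p_sites, t_sites))
  fn <- length(setdiff(t_sites, p_sites))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
}

# truth in the prediction-output schema (used for the corpus truth.tsv)
truth_to_output_schema <- function(truth) {
  tibble::tibble(
    structure_id = truth$structure_id, chain = truth$chain,
    r1_bond = truth$lys_resno, r_cat = truth$cat_resno,
    r2_bond = truth$acc_resno,
    r1_bond_name = truth$lys_resid, r_cat_name = truth$cat_resid,
    r2_bond_name = truth$acc_resid,
    type = truth$topology, triad_type = truth$triad_type,
    planted_bond_length = truth$bond_length,
    planted_phi = truth$phi, planted_psi = truth$psi,
    planted_omega = truth$omega,
    burial = truth$burial, noise_sigma = truth$noise_sigma,
    seed = truth$seed
  )
}
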