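#' Train the logistic site classifier
#'
#' Fits a two-feature logistic regression (template RMSD, triad rASA) by
#' maximizing the L2-penalized log-likelihood with penalty `1/(2C) * ||w||^2`
#' on the weights (intercept unpenalized), the convention of the common
#' default `C = 1`. Features are not standardized before fitting; this is
#' recorded in the model metadata so training and prediction can never
#' silently disagree. The fit is deterministic given the data.
#'
#' @param features A data frame with numeric columns `rmsd` and `r_asa` and
#'   a logical (or 0/1) column `label` — `TRUE` for isopeptide-bond sites.
#' @param C Inverse regularization strength (default 1).
#' @param threshold Decision threshold on the probability (default 0.5;
#'   classification is strict: `p > threshold`).
#' @param seed Accepted for interface symmetry with stochastic trainers;
#'   the fit itself is deterministic.
#' @return An object of class `iso_model`: weights, intercept, threshold,
#'   feature names and training metadata.
#' @export
#' @examples
#' set.seed(7)
#' feats <- dplyr::bind_rows(
#'   tibble::tibble(rmsd = rnorm(200, 0.3, 0.1), r_asa = rnorm(200, 0.1, 0.05),
#'                  label = TRUE),
#'   tibble::tibble(rmsd = rnorm(200, 1.5, 0.2), r_asa = rnorm(200, 0.5, 0.1),
#'                  label = FALSE))
#' m <- train_classifier(feats)
#' generics::tidy(m)
train_classifier <- function(features, C = 1, threshold = 0.5, seed = NULL) {
  stopifnot(all(c("rmsd", "r_asa", "label") %in% names(features)))
  x <- as.matrix(features[, c("rmsd", "r_asa")])
  y <- as.numeric(features$label)
  if (anyNA(x) || anyNA(y)) stop("NA in training features/labels")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")

  obj <- function(p) {
    eta <- drop(x %*% p[1:2] + p[3])
    # log(1+exp(eta)) in overflow-safe form
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -sum(y * eta - lse) + sum(p[1:2]^2) / (2 * C)
  }
  grad <- function(p) {
    eta <- drop(x %*% p[1:2] + p[3])
    pr <- 1 / (1 + exp(-eta))
    g <- crossprod(x, pr - y)
    c(g + p[1:2] / C, sum(pr - y))
  }
  fit <- stats::optim(c(0, 0, 0), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  new_iso_model(
    weights = c(rmsd = fit$par[1], r_asa = fit$par[2]),
    intercept = fit$par[3], threshold = threshold,
    training_meta = list(
      n_pos = sum(y == 1), n_neg = sum(y == 0), C = C,
      standardize = FALSE, converged = fit$convergence == 0,
      date = format(Sys.Date()),
      data_hash = feature_hash(x, y)
    )
  )
}

feature_hash <- function(x, y) {
  v <- c(as.numeric(x), y)
  sprintf("%08x", sum(as.integer((abs(v) * 1e4) %% 2147483647)) %%
            .Machine$integer.max)
}

new_iso_model <- function(weights, intercept, threshold = 0.5,
                          training_meta = list()) {
  stopifnot(length(weights) == 2, threshold > 0, threshold < 1)
  structure(list(weights = weights, intercept = intercept,
                 threshold = threshold,
                 feature_names = c("rmsd", "r_asa"),
                 training_meta = training_meta),
            class = "iso_model")
}

#' @export
print.iso_model <- function(x, ...) {
  cat("<iso_model> logistic isopeptide-bond classifier\n")
  cat(sprintf("  p = sigmoid(%+.4f * rmsd %+.4f * r_asa %+.4f)\n",
              x$weights[["rmsd"]], x$weights[["r_asa"]], x$intercept))
  cat(sprintf("  decision threshold: p > %g\n", x$threshold))
  if (length(x$training_meta))
    cat("  trained on", x$training_meta$n_pos %||% "?", "positives /",
        x$training_meta$n_neg %||% "?", "negatives\n")
  invisible(x)
}

#' Classify sites with a fitted model
#'
#' Computes the closed-form sigmoid probability for each row and applies
#' the strict decision rule `is_bond = probability > threshold` (a
#' probability exactly at the threshold classifies negative).
#'
#' @param features A data frame with numeric columns `rmsd` and `r_asa`
#'   (other columns pass through).
#' @param model An `iso_model`.
#' @return The input tibble with `probability` and `is_bond` appended.
#' @export
predict_bonds <- function(features, model) {
  stopifnot(inherits(model, "iso_model"))
  x <- as.matrix(features[, model$feature_names])
  if (nrow(x) && (anyNA(x) || !all(is.finite(x))))
    stop("non-finite feature value passed to predict_bonds")
  eta <- drop(x %*% model$weights + model$intercept)
  out <- tibble::as_tibble(features)
  out$probability <- 1 / (1 + exp(-eta))
  out$is_bond <- out$probability > model$threshold
  out
}

#' @export
predict.iso_model <- function(object, newdata, ...) {
  predict_bonds(newdata, object)$probability
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted classifier coefficients
#'
#' @param x An `iso_model`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.iso_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$feature_names),
                 estimate = unname(c(x$intercept, x$weights)))
}

#' One-row model summary
#'
#' @param x An `iso_model`.
#' @param ... Unused.
#' @return A one-row tibble: threshold, regularization, class counts.
#' @export
glance.iso_model <- function(x, ...) {
  tm <- x$training_meta
  tibble::tibble(threshold = x$threshold, C = tm$C %||% NA_real_,
                 n_pos = tm$n_pos %||% NA_integer_,
                 n_neg = tm$n_neg %||% NA_integer_,
                 converged = tm$converged %||% NA)
}

#' Write a classifier to a plain-text parameter file
#'
#' The model is persisted as `key=value` text at full precision, so
#' predictions are reproducible independently of any fitting library.
#'
#' @param model An `iso_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  tm <- model$training_meta
  lines <- c(
    "format=isopeptider-logistic-1",
    paste0("feature_names=", paste(model$feature_names, collapse = ",")),
    paste0("weights=", paste(sprintf("%.17g", model$weights), collapse = ",")),
    sprintf("intercept=%.17g", model$intercept),
    sprintf("threshold=%.17g", model$threshold),
    paste0("training_meta=", paste(names(tm), vapply(tm, format, ""),
                                   sep = ":", collapse = ";"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a classifier parameter file
#'
#' @param path Path to a file written by [write_model()].
#' @return An `iso_model`.
#' @export
read_model <- function(path) {
  kv <- parse_kv_lines(readLines(path, warn = FALSE))
  if (!identical(kv$format, "isopeptider-logistic-1"))
    stop("unrecognized model file format in ", path)
  w <- as.numeric(strsplit(kv$weights, ",")[[1]])
  fn <- strsplit(kv$feature_names, ",")[[1]]
  meta <- list()
  if (!is.null(kv$training_meta) && nzchar(kv$training_meta)) {
    pairs <- strsplit(strsplit(kv$training_meta, ";")[[1]], ":")
    meta <- lapply(pairs, function(p) paste(p[-1], collapse = ":"))
    names(meta) <- vapply(pairs, `[[`, "", 1L)
  }
  m <- new_iso_model(weights = stats::setNames(w, fn),
                     intercept = as.numeric(kv$intercept),
                     threshold = as.numeric(kv$threshold),
                     training_meta = meta)
  m
}

parse_kv_lines <- function(lines) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, `[[`, 2L)
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

#' Default bundled classifier
#'
#' The synthetic-fixture-trained model shipped with the package (the
#' original tool's fitted coefficients are not published). Trained on the
#' package's documented Gaussian fixture distributions; replace with your
#' own model via [train_classifier()] + [write_model()] for production use.
#'
#' @return An `iso_model`.
#' @export
default_model <- function() read_model(iso_extdata("model_synthetic.txt"))
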