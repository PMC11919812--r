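#' Plot the classifier's decision landscape
#'
#' Probability surface of the fitted logistic model over the (RMSD, rASA)
#' feature plane, with the decision boundary drawn at the model's
#' threshold. Optionally overlays feature points (e.g. training data or
#' pipeline output).
#'
#' @param object An `iso_model`.
#' @param features Optional data frame with `rmsd` and `r_asa` columns
#'   (and, if present, a logical `label` or `is_bond` used for shape).
#' @param rmsd_range,r_asa_range Plot ranges.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iso_model <- function(object, features = NULL,
                               rmsd_range = c(0, 2.5),
                               r_asa_range = c(0, 1), ...) {
  grid <- tidyr::expand_grid(
    rmsd = seq(rmsd_range[1], rmsd_range[2], length.out = 120),
    r_asa = seq(r_asa_range[1], r_asa_range[2], length.out = 120)
  )
  grid$probability <- predict(object, grid)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$rmsd, .data$r_asa)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$probability)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$probability),
                          breaks = object$threshold, colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "RMSD to closest template (Å)",
                  y = "relative accessible surface area",
                  fill = "P(bond)") +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    lab <- features$label %||% features$is_bond
    if (!is.null(lab)) {
      features$class <- ifelse(lab, "bond", "no bond")
      p <- p + ggplot2::geom_point(
        data = features,
        ggplot2::aes(shape = .data$class), colour = "black")
    } else {
      p <- p + ggplot2::geom_point(data = features, colour = "black")
    }
  }
  p
}

#' Plot a fitted dihedral-pair density
#'
#' Density raster of one angular KDE model with its 5th-percentile outlier
#' cutoff contour and the training samples.
#'
#' @param object An `iso_kde` from [fit_kde()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iso_kde <- function(object, ...) {
  grid <- tidyr::expand_grid(a1 = seq(-180, 180, by = 3),
                             a2 = seq(-180, 180, by = 3))
  grid$loglik <- kde_loglik(object, as.matrix(grid))
  samples <- tibble::tibble(a1 = object$samples[seq_len(object$n), 1],
                            a2 = object$samples[seq_len(object$n), 2])
  ggplot2::ggplot(grid, ggplot2::aes(.data$a1, .data$a2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$loglik)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$loglik),
                          breaks = object$cutoff, colour = "red") +
    ggplot2::geom_point(data = samples, size = 0.3, alpha = 0.5,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "angle 1 (deg)", y = "angle 2 (deg)",
                  fill = "log density") +
    ggplot2::theme_minimal()
}

#' Feature-space view of pipeline predictions
#'
#' Scatters detected sites in the (RMSD, rASA) plane, coloured by bond
#' probability; the classifier's decision boundary is drawn when the model
#' is supplied.
#'
#' @param predictions Output of [detect_bonds()].
#' @param model Optional `iso_model` used to draw the decision boundary.
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions, model = NULL) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(.data$rmsd, .data$r_asa,
                                    colour = .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "RMSD to closest template (Å)",
                  y = "relative accessible surface area",
                  colour = "P(bond)") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    w <- model$weights; b <- model$intercept
    thr_eta <- log(model$threshold / (1 - model$threshold))
    # boundary line w1*rmsd + w2*r_asa + b = logit(threshold)
    if (abs(w[["r_asa"]]) > 1e-12) {
      xs <- seq(0, max(c(predictions$rmsd, 1)) * 1.1, length.out = 50)
      line <- tibble::tibble(
        rmsd = xs,
        r_asa = (thr_eta - b - w[["rmsd"]] * xs) / w[["r_asa"]]
      )
      p <- p + ggplot2::geom_line(data = line,
                                  ggplot2::aes(.data$rmsd, .data$r_asa),
                                  inherit.aes = FALSE, linetype = 2)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
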