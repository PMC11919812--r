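#' Optimal superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation between two corresponded coordinate sets after
#' optimal least-squares rigid-body superposition (rotation restricted to
#' proper rotations; reflections are never applied).
#'
#' @param a,b Numeric n x 3 matrices with rows in correspondence.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 3, ncol(b) == 3,
            nrow(a) == nrow(b), nrow(a) >= 3)
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ca, cb))
  d <- sign(det(s$v %*% t(s$u)))
  # E = sum of squared deviations at the optimum, via singular values
  e <- sum(ca^2) + sum(cb^2) - 2 * (s$d[1] + s$d[2] + d * s$d[3])
  sqrt(max(e, 0) / nrow(a))
}

# rotation+translation mapping b onto a (least squares), for completeness
kabsch_fit <- function(a, b) {
  ma <- colMeans(a); mb <- colMeans(b)
  ca <- sweep(a, 2, ma); cb <- sweep(b, 2, mb)
  s <- svd(crossprod(cb, ca))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = t(rot), shift_from = mb, shift_to = ma)
}
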