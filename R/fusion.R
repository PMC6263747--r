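#' Stack synchronized axis segments into one instance row
#'
#' Concatenates equal-length x, y and z segments as `[x | y | z]`. Downstream
#' discretization runs on each third independently with the same window size,
#' and the instance histogram is the sum of the three axis-tagged histograms
#' — so no classifier needs to change to handle three axes.
#'
#' @param x,y,z Numeric segments of equal length.
#' @return Numeric vector of length `3 * length(x)`.
#' @export
stack_axes <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop_parameter("axis segments must have equal length")
  }
  c(x, y, z)
}

#' Euclidean-magnitude fusion
#'
#' Collapses the three axes to the rotation-invariant signal magnitude
#' `sqrt(x^2 + y^2 + z^2)`. Static postures whose gravity vectors share the
#' same norm become indistinguishable under this fusion — orientation is
#' deliberately discarded.
#'
#' @param x,y,z Aligned numeric vectors.
#' @return Nonnegative numeric vector.
#' @export
fuse_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop_parameter("axis vectors must have equal length")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' First-principal-component fusion
#'
#' Fits a 3x3 covariance eigendecomposition on the *training* samples
#' (mean-centered x, y, z), then projects any frame onto the leading
#' eigenvector. The loading with the largest magnitude is forced nonnegative
#' so the projection sign is deterministic. Fit on training folds only to
#' avoid test-set leakage.
#'
#' @param train Data frame with columns `x`, `y`, `z` (training samples).
#' @return An object of class `pca_fusion`: `center`, `rotation` (leading
#'   eigenvector), `eigenvalues`.
#' @export
fit_pca_fusion <- function(train) {
  M <- as.matrix(train[, c("x", "y", "z")])
  if (nrow(M) < 2) stop_parameter("need at least 2 training samples")
  C <- stats::cov(M)
  if (!all(is.finite(C)) || max(diag(C)) <= 0) {
    stop_parameter("zero-variance training data: PCA fusion undefined")
  }
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  structure(list(center = colMeans(M), rotation = v, eigenvalues = e$values),
            class = "pca_fusion")
}

#' @rdname fit_pca_fusion
#' @param object A fitted `pca_fusion`.
#' @param frame Data frame with columns `x`, `y`, `z` to project.
#' @return Numeric vector: the centered samples projected on the leading
#'   eigenvector.
#' @export
fuse_pca <- function(object, frame) {
  M <- as.matrix(frame[, c("x", "y", "z")])
  as.numeric(sweep(M, 2, object$center) %*% object$rotation)
}
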