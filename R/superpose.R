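#' Least-squares (Kabsch) superposition
#'
#' Finds the rigid transform (proper rotation + translation) minimizing the
#' RMSD between corresponding atom sets, via SVD of the cross-covariance
#' matrix with the usual determinant correction against reflections.
#'
#' @param mobile,target numeric matrices (n x 3) of corresponding atoms,
#'   n >= 3, not collinear.
#' @return list with `rotation` (3x3, applied on the right), `translation`
#'   (length 3), `rmsd` (Angstrom) and `transform(coords)`, a function
#'   applying the fit to arbitrary coordinates.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L)
  if (nrow(mobile) != nrow(target)) stop("correspondence mismatch")
  if (nrow(mobile) < 3L) stop("need at least 3 corresponding atom pairs")
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2L, cm); Y <- sweep(target, 2L, ct)
  sx <- svd(X)$d
  if (sx[2L] < 1e-8 * max(sx[1L], 1))
    stop("degenerate geometry: mobile atoms are (nearly) collinear")
  s <- svd(crossprod(X, Y))  # X^T Y = U D V^T
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  translation <- ct - as.numeric(cm %*% R)
  transform <- function(coords) {
    coords <- as.matrix(coords)
    sweep(coords %*% R, 2L, translation, "+")
  }
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = transform)
}

#' Apply a superposition to a structure model
#' @param model a [structure_model].
#' @param fit result of [kabsch_superpose()].
#' @return the model with transformed coordinates.
#' @export
transform_structure <- function(model, fit) {
  xyz <- fit$transform(as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}
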