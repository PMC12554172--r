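#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' deviation of `mobile` onto `reference`, via the singular value
#' decomposition of the cross-covariance of the centered point sets, with
#' the usual reflection correction so the returned rotation has
#' determinant +1.
#'
#' @param mobile,reference Numeric n x 3 matrices of matching points,
#'   n >= 3, not all collinear.
#'
#' @return A list with `rotation` (3 x 3, det +1), `translation` (length-3
#'   vector such that `mobile %*% t(rotation) + translation` best matches
#'   `reference`), and `rmsd`, the root-mean-square deviation after
#'   superposition (same units as the coordinates).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("`mobile` and `reference` must be n x 3 matrices of equal size.",
      class = "degronmap_error_coords"
    )
  }
  n <- nrow(mobile)
  if (n < 3) {
    abort("Superposition needs at least 3 points.",
      class = "degronmap_error_coords"
    )
  }
  if (any(!is.finite(mobile)) || any(!is.finite(reference))) {
    abort("Coordinates must be finite.", class = "degronmap_error_coords")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  # collinear (or coincident) point sets leave the rotation underdetermined
  if (qr(p)$rank < 2 || qr(q)$rank < 2) {
    abort("Degenerate (collinear) point configuration; cannot superpose.",
      class = "degronmap_error_degenerate"
    )
  }
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  list(
    rotation = rot,
    translation = as.numeric(cr - cm %*% t(rot)),
    rmsd = rmsd
  )
}

# RMSD-only fast path used per frame. The residuals are formed explicitly
# after rotation (rather than via the singular-value identity), which
# avoids catastrophic cancellation for widely spread coordinates.
kabsch_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((p %*% t(rot) - q)^2)))
}
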