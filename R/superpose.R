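#' Kabsch least-squares superposition
#'
#' Optimal rigid-body fit (rotation + translation, reflections excluded) of
#' paired coordinate sets by SVD of the covariance matrix. The returned
#' transform maps `a` onto `b`: `a %*% rotation + translation` (row-vector
#' convention).
#'
#' @param a,b n x 3 matrices of paired CA coordinates (n >= 3).
#' @return list with `rotation` (3 x 3, orthonormal, det +1), `translation`
#'   (length-3), `rmsd` (Angstrom, after transform).
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets must be paired")
  if (nrow(a) < 3) stop("need at least 3 paired points")
  if (anyNA(a) || anyNA(b)) stop("NA coordinates in superposition input")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  H <- crossprod(ac, bc)                # t(ac) %*% bc
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  tr <- as.numeric(cb - ca %*% R)
  fit <- sweep(ac %*% R, 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fit - b)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

# apply a superposition to a full coordinate matrix (NA rows pass through)
apply_superposition <- function(xyz, sup) {
  out <- xyz %*% sup$rotation
  sweep(out, 2, sup$translation, "+")
}

# trimmed superposition: iteratively discard pairs that fit worse than
# max(trim_dist, median residual) and refit, so a conserved core dominates
# the frame even when flexible regions are mispaired
robust_superpose <- function(a, b, rounds = 8, trim_dist = 1.5) {
  sup <- kabsch_superpose(a, b)
  for (r in seq_len(rounds)) {
    d <- sqrt(rowSums((apply_superposition(a, sup) - b)^2))
    keep <- which(d <= max(trim_dist, stats::median(d)))
    if (length(keep) < 3 || length(keep) == nrow(a)) break
    a <- a[keep, , drop = FALSE]
    b <- b[keep, , drop = FALSE]
    sup <- kabsch_superpose(a, b)
  }
  sup
}
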