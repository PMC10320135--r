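# Low-level coordinate geometry shared by the scoring metrics.
# Row-vector convention throughout: a point set is an n x 3 matrix and a
# rigid transform acts as  x %*% rotation + translation.

# Squared Euclidean distances between the rows of a (n x 3) and b (m x 3).
dist_sq <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

dist_mat <- function(a, b) sqrt(dist_sq(a, b))

# Per-row distance between two conformations of the same points.
row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the least-squares rigid transform (proper rotation + translation,
#' reflections disallowed) taking the point set `coords_a` onto `coords_b`,
#' where the two n x 3 matrices are in row correspondence.
#'
#' The returned transform follows the row-vector convention:
#' `coords_a %*% rotation + rep(translation, each = n)` best approximates
#' `coords_b`, and `rmsd` is the residual root-mean-square deviation at the
#' optimum.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices, n >= 3, rows in
#'   correspondence.
#' @return An object of class `superposition`: a list with elements
#'   `rotation` (3 x 3 orthonormal, det +1), `translation` (length-3),
#'   `rmsd` (Angstrom) and `n_points`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' sp <- kabsch_superpose(a, a)
#' sp$rmsd # 0
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!is.numeric(coords_a) || !is.numeric(coords_b) ||
      ncol(coords_a) != 3L || ncol(coords_b) != 3L) {
    abort("coordinate sets must be numeric n x 3 matrices")
  }
  n <- nrow(coords_a)
  if (nrow(coords_b) != n) abort("point sets must have equal size")
  if (n < 3L) abort("superposition requires at least 3 points")
  if (anyNA(coords_a) || anyNA(coords_b)) abort("coordinates contain NA")

  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  ac <- sweep(coords_a, 2, ca)
  bc <- sweep(coords_b, 2, cb)

  h <- crossprod(ac, bc)
  sv <- svd(h)
  # Collinear/degenerate sets leave the rotation about the point axis free.
  scale0 <- max(sqrt(sum(ac^2)), sqrt(sum(bc^2)), .Machine$double.eps)
  if (sv$d[2] / scale0^2 < 1e-10 && sv$d[1] / scale0^2 > 1e-10) {
    abort("ill-conditioned superposition: points are (near-)collinear")
  }
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rmsd <- sqrt(max(0, mean(rowSums((ac %*% rot - bc)^2))))

  structure(
    list(rotation = rot, translation = as.numeric(cb - ca %*% rot),
         rmsd = rmsd, n_points = n),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param coords An n x 3 coordinate matrix.
#' @return The transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d points, rmsd = %.4f A\n", x$n_points, x$rmsd))
  invisible(x)
}

# Rotation matrix (row-vector convention) about a unit axis, angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) * c_ + s_ * k + (1 - c_) * tcrossprod(u)
  t(r) # column convention -> row convention
}

# A uniformly random proper rotation (row-vector convention), seeded by caller.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  r <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  t(r)
}
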