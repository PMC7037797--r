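# Low-level 3D geometry: all angles in degrees, all lengths in Angstrom.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped to the principal interval `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  low <- which(w <= -180)
  w[low] <- w[low] + 360
  w
}

#' Bond angle at three points
#'
#' Angle a-b-c in degrees, in `(0, 180)` for non-degenerate input.
#' @param a,b,c numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Torsion angle of four points
#'
#' Signed dihedral a-b-c-d using the IUPAC convention (cis = 0, trans = 180),
#' wrapped to `(-180, 180]`.
#' @param a,b,c,d numeric 3-vectors (Angstrom).
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) / DEG)
}

# Place atom D given reference atoms a-b-c, bond length c-D, angle b-c-D and
# dihedral a-b-c-D (NeRF-style sequential extension).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * DEG
  ph <- -dihedral * DEG
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               bond * sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d_local + c)
}

# Rotation matrix for a right-handed rotation by `angle` degrees about unit
# axis `u` (Rodrigues form).
rotation_matrix <- function(u, angle) {
  u <- unitv(u)
  th <- angle * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate rows of an n x 3 matrix about the axis through `origin` along `u`.
rotate_about_axis <- function(xyz, origin, u, angle) {
  R <- rotation_matrix(u, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation between two equally sized coordinate sets,
#' optionally after the optimal least-squares rigid superposition (Kabsch
#' algorithm, proper rotations only).
#'
#' @param a,b n x 3 numeric matrices of matched coordinates (Angstrom).
#' @param superpose superpose `b` onto `a` before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    abort(sprintf("coordinate sets differ in size (%d vs %d atoms)",
                  nrow(a), nrow(b)))
  }
  if (nrow(a) < 3 && superpose) {
    abort("superposition needs at least 3 atoms")
  }
  if (superpose) b <- kabsch_fit(a, b)$xyz
  sqrt(mean(rowSums((a - b)^2)))
}

# Superpose b onto a; returns transformed coordinates plus rotation/centroids.
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(t(b0) %*% a0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(xyz = sweep(b0 %*% t(R), 2, ca, `+`), rotation = R,
       center_a = ca, center_b = cb)
}

# Signed angle from vector x to vector y in the plane perpendicular to unit
# axis u, right-handed about u, in degrees.
azimuth_about <- function(u, x, y) {
  u <- unitv(u)
  px <- x - sum(x * u) * u
  py <- y - sum(y * u) * u
  if (vnorm(px) < 1e-9 || vnorm(py) < 1e-9) return(NA_real_)
  px <- unitv(px); py <- unitv(py)
  wrap_angle(atan2(sum(cross3(px, py) * u), sum(px * py)) / DEG)
}
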