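# Geometric primitives shared by the builders and the analysis layer.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle
#'
#' Right-handed (IUPAC) convention: cis = 0 deg, trans = 180 deg, result in
#' (-180, 180]. No unwrapping is applied.
#'
#' @param xyz n x 3 coordinate matrix (A) or a `conformation`.
#' @param idx integer vector of four 1-based atom indices.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(xyz, idx) {
  xyz <- as_xyz(xyz)
  stopifnot(length(idx) == 4)
  phi <- cpp_dihedral(xyz, idx[1] - 1L, idx[2] - 1L, idx[3] - 1L, idx[4] - 1L)$phi
  a <- rad2deg(phi)
  if (a <= -180) a <- a + 360
  a
}

as_xyz <- function(x) {
  if (inherits(x, "conformation")) x <- x$xyz
  stopifnot(is.matrix(x), ncol(x) == 3)
  x
}

# NeRF placement: position a new atom bonded to c, with angle(b, c, new) and
# dihedral(a, b, c, new). bond in A, angle/dihedral in degrees.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  angle <- deg2rad(angle); dihedral <- deg2rad(dihedral)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference atoms in place_atom")
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Rodrigues rotation of points about an axis through `origin`.
rotate_about_axis <- function(xyz, origin, axis, angle_deg) {
  th <- deg2rad(angle_deg)
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# von Mises sampler (Best & Fisher 1979); mu in degrees, returns degrees.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        th <- sign(u[3] - 0.5) * acos(f)
        out[i] <- th
        break
      }
    }
  }
  ang <- rad2deg(out) + mu
  ((ang + 180) %% 360) - 180
}
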