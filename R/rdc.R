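# Dipolar-coupling tensors and their tanh-capped orientational pseudo-forces.

new_dipolar_tensor <- function(m, frame) {
  structure(m, frame = frame, class = "dipolar_tensor")
}

#' Principal-axis dipolar tensor
#'
#' In the principal axis system (z along the internuclear vector) the
#' dipolar tensor is diagonal with principal values (-D/2, -D/2, D) where
#' `D = s_am * d_stat`: the static splitting scaled into the residual
#' regime by the alignment-medium order parameter.
#'
#' @param d_stat static splitting, Hz (e.g. 47960 for one-bond sp3 C-H).
#' @param s_am alignment-medium order parameter in (0, 1].
#' @return 3 x 3 `dipolar_tensor` (Hz) in the PAS frame.
#' @export
#' @examples
#' pas_tensor(47960, 0.004)[3, 3]  # maximum attainable splitting, 191.84 Hz
pas_tensor <- function(d_stat, s_am) {
  stopifnot(d_stat != 0, s_am > 0, s_am <= 1)
  D <- s_am * d_stat
  new_dipolar_tensor(diag(c(-D / 2, -D / 2, D)), "pas")
}

#' Laboratory-frame dipolar tensor of one internuclear vector
#'
#' Rotates the PAS tensor into the laboratory frame with a transformation
#' matrix built from the unit internuclear vector (z axis) completed by two
#' orthonormal axes; the completion starts from the Cartesian axis with the
#' smallest vector component (any completion gives the same tensor). The
#' result is symmetric, traceless, and keeps the PAS eigenvalues.
#'
#' @param conf `conformation` or n x 3 coordinate matrix.
#' @param pair two 1-based atom indices.
#' @param pas the PAS tensor from [pas_tensor()].
#' @return 3 x 3 `dipolar_tensor` (Hz) in the lab frame.
#' @export
lab_tensor <- function(conf, pair, pas) {
  xyz <- as_xyz(conf)
  d <- xyz[pair[1], ] - xyz[pair[2], ]
  r <- sqrt(sum(d^2))
  if (r < 1e-8) stop("zero-length internuclear vector")
  u <- d / r
  e <- diag(3)[, which.min(abs(u))]
  x1 <- e - sum(e * u) * u
  x1 <- x1 / sqrt(sum(x1^2))
  x2 <- pracma_cross(u, x1)
  Tm <- cbind(x1, x2, u)          # columns: PAS axes in lab coordinates
  new_dipolar_tensor(Tm %*% unclass(pas) %*% t(Tm), "lab")
}

#' Experimental target tensor
#'
#' A measured RDC is the z component of a diagonal traceless lab-frame
#' tensor; the off-diagonal targets are zero because rapid reorientation
#' about the director averages them away.
#'
#' @param d_exp measured residual dipolar coupling, Hz.
#' @return 3 x 3 `dipolar_tensor` (Hz) in the lab frame.
#' @export
exp_tensor <- function(d_exp) {
  new_dipolar_tensor(diag(c(-d_exp / 2, -d_exp / 2, d_exp)), "lab")
}

#' Saturating tanh scale of a constraint deviation
#'
#' `tanh(delta/width)`: linear for small deviations, saturating at +-1 so
#' a badly violated constraint exerts a bounded force instead of the
#' unbounded harmonic one.
#'
#' @param delta deviation (mean minus experimental value), any units.
#' @param width tanh width in the same units (> 0).
#' @return dimensionless factor in (-1, 1).
#' @export
tanh_scale <- function(delta, width) {
  stopifnot(width > 0)
  tanh(delta / width)
}

#' RDC tensorial pseudo-force
#'
#' Forces on the two coupled atoms from the mismatch between the
#' memory-averaged lab-frame tensor and the experimental target tensor.
#' All nine tensor components contribute through the tanh scale; only the
#' orientational derivative of the theoretical tensor is used (the
#' internuclear distance is held fixed), so the forces on i and j are equal
#' and opposite and perpendicular to the internuclear vector.
#'
#' @param conf `conformation` or coordinate matrix.
#' @param pair two 1-based atom indices (i, j).
#' @param mem_mean 3 x 3 memory-averaged lab tensor (Hz).
#' @param d_exp experimental RDC, Hz.
#' @param d_max scaled static splitting `s_am * d_stat`, Hz.
#' @param width tanh width Delta D, Hz.
#' @param k force constant (kJ mol^-1 Hz^-1).
#' @param t,rho time and ramp constant, ps (ramp multiplies the force).
#' @return n x 3 force matrix (kJ mol^-1 A^-1), nonzero on rows i and j.
#' @export
rdc_pseudo_force <- function(conf, pair, mem_mean, d_exp, d_max, width, k,
                             t = Inf, rho = 1) {
  xyz <- as_xyz(conf)
  cons <- empty_cons()
  cons$rdc_idx <- matrix(as.integer(c(pair[1], pair[2], -1, -1, -1, -1)) - c(1L, 1L, 0L, 0L, 0L, 0L), 1, 6)
  cons$rdc_np <- 1L
  cons$rdc_dmax <- d_max; cons$rdc_dexp <- d_exp; cons$rdc_dD <- width
  ramp <- if (is.finite(t)) ramp_factor(t, rho) else 1
  cpp_pseudo_forces(xyz, cons,
                    matrix(as.numeric(t(unclass(mem_mean))), 1, 9), 1,
                    numeric(0), numeric(0), numeric(0), numeric(0),
                    ramp * k, 0, 0)
}

#' Methyl-averaged RDC observable
#'
#' The rapidly rotating CH3 group is treated as one constraint: the
#' observable is the arithmetic mean of the three lab-frame C-H bond
#' tensors, and the pseudo-forces are distributed over the three protons
#' with weight 1/3 each.
#'
#' @param conf `conformation` or coordinate matrix.
#' @param pairs 3 x 2 matrix of (C, H) index pairs sharing the carbon.
#' @param pas PAS tensor of a single C-H bond.
#' @return 3 x 3 `dipolar_tensor` (lab frame).
#' @export
methyl_rdc_observable <- function(conf, pairs, pas) {
  stopifnot(is.matrix(pairs), nrow(pairs) == 3)
  if (length(unique(pairs[, 1])) != 1) {
    stop("methyl RDC pairs must share the carbon atom")
  }
  m <- matrix(0, 3, 3)
  for (h in 1:3) m <- m + unclass(lab_tensor(conf, pairs[h, ], pas)) / 3
  new_dipolar_tensor(m, "lab")
}

#' @export
print.dipolar_tensor <- function(x, ...) {
  cat("<dipolar_tensor> frame:", attr(x, "frame"), "\n")
  print(unclass(x), ...)
  invisible(x)
}

# empty compiled-constraint structure (fields as consumed by the C++ core)
empty_cons <- function() {
  list(
    rdc_idx = matrix(integer(0), 0, 6), rdc_np = integer(0),
    rdc_dmax = numeric(0), rdc_dexp = numeric(0), rdc_dD = numeric(0),
    noe_idx = matrix(integer(0), 0, 2),
    noe_rexp = numeric(0), noe_dr = numeric(0),
    j_idx = matrix(integer(0), 0, 4),
    j_jexp = numeric(0), j_dD = numeric(0),
    j_P = matrix(numeric(0), 0, 6),
    j_chi = matrix(numeric(0), 0, 4), j_xi = matrix(numeric(0), 0, 4),
    j_ns = integer(0)
  )
}
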