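# NOE distance and 3J Karplus constraints with tanh-capped pseudo-forces.

#' NOE mean distance from an r^-6 memory
#'
#' NOE distances average as `rbar = <r^-6>^(-1/6)` (valid for rigid
#' molecules undergoing isotropic reorientation); the memory accumulator is
#' fed the instantaneous r^-6 each step.
#'
#' @param mem a `memory_state` fed with r^-6 values (A^-6).
#' @return rbar in A.
#' @export
noe_mean_distance <- function(mem) {
  memory_mean(mem)^(-1 / 6)
}

#' NOE pseudo-force
#'
#' Central force along the interproton vector with magnitude
#' `ramp * k * tanh((rbar - r_exp)/width)`: attractive when the averaged
#' distance exceeds the target, repulsive when it falls short. For a methyl
#' partner the identical constraint applies to each of the three protons
#' with the full force on each.
#'
#' @param conf `conformation` or coordinate matrix.
#' @param pair two 1-based proton indices.
#' @param rbar memory-averaged distance, A.
#' @param r_exp target distance, A.
#' @param width tanh width, A.
#' @param k force constant, kJ mol^-1 A^-1 at saturation.
#' @param t,rho ramp time arguments (ps); `t = Inf` disables the ramp.
#' @return n x 3 force matrix.
#' @export
noe_pseudo_force <- function(conf, pair, rbar, r_exp, width, k,
                             t = Inf, rho = 1) {
  xyz <- as_xyz(conf)
  cons <- empty_cons()
  cons$noe_idx <- matrix(as.integer(pair) - 1L, 1, 2)
  cons$noe_rexp <- r_exp; cons$noe_dr <- width
  ramp <- if (is.finite(t)) ramp_factor(t, rho) else 1
  cpp_pseudo_forces(xyz, cons,
                    matrix(numeric(0), 0, 9), numeric(0),
                    rbar^-6, 1, numeric(0), numeric(0),
                    0, ramp * k, 0)
}

#' Substituent-corrected Karplus equation for vicinal couplings
#'
#' Evaluates
#' `J = P1 cos^2(phi) + P2 cos(phi) + P3 +
#'    sum_i dchi_i (P4 + P5 cos^2(xi_i phi + P6 |dchi_i|))`
#' with phi the H-C-C-H torsion, dchi_i the substituent electronegativity
#' differences and xi_i = +-1 their orientation signs.
#'
#' @param phi torsion angle(s), degrees.
#' @param chi numeric vector of substituent electronegativity differences
#'   (empty for the plain Karplus curve).
#' @param xi orientation signs, one per substituent, each +-1.
#' @param params named `P1..P6` vector (P6 in degrees), e.g.
#'   [haasnoot_params()].
#' @return 3J in Hz, same length as `phi`.
#' @export
#' @examples
#' karplus_haasnoot(180) > karplus_haasnoot(60)
karplus_haasnoot <- function(phi, chi = numeric(0), xi = numeric(0),
                             params = haasnoot_params("hla2")) {
  if (length(chi) != length(xi)) stop("chi and xi must pair up")
  if (length(xi) && any(abs(xi) != 1)) stop("xi entries must be +1 or -1")
  P <- as.numeric(params)
  P[6] <- deg2rad(P[6])
  cpp_karplus(deg2rad(phi), P, as.numeric(chi), as.numeric(xi))
}

#' 3J pseudo-force
#'
#' Chain rule through the torsion angle: the scalar
#' `ramp * k * tanh((<J> - J_exp)/width) * dJ/dphi` is distributed over the
#' four path atoms with the analytic gradient of the dihedral angle, so the
#' net force and net torque of the four-atom set vanish.
#'
#' @param conf `conformation` or coordinate matrix.
#' @param path four 1-based atom indices H-C-C-H.
#' @param j_mean memory-averaged 3J, Hz.
#' @param j_exp experimental 3J, Hz.
#' @param width tanh width, Hz.
#' @param k force constant, kJ mol^-1 Hz^-1.
#' @param chi,xi,params Karplus substituent descriptors, see
#'   [karplus_haasnoot()].
#' @param t,rho ramp arguments (ps); `t = Inf` disables the ramp.
#' @return n x 3 force matrix.
#' @export
j_pseudo_force <- function(conf, path, j_mean, j_exp, width, k,
                           chi = numeric(0), xi = numeric(0),
                           params = haasnoot_params("hla2"),
                           t = Inf, rho = 1) {
  xyz <- as_xyz(conf)
  cons <- empty_cons()
  cons$j_idx <- matrix(as.integer(path) - 1L, 1, 4)
  cons$j_jexp <- j_exp; cons$j_dD <- width
  P <- as.numeric(params); P[6] <- deg2rad(P[6])
  cons$j_P <- matrix(P, 1, 6)
  ns <- length(chi)
  if (ns > 4) stop("at most 4 substituents supported")
  cons$j_chi <- matrix(c(chi, rep(0, 4 - ns)), 1, 4)
  cons$j_xi <- matrix(c(xi, rep(1, 4 - ns)), 1, 4)
  cons$j_ns <- as.integer(ns)
  ramp <- if (is.finite(t)) ramp_factor(t, rho) else 1
  cpp_pseudo_forces(xyz, cons,
                    matrix(numeric(0), 0, 9), numeric(0),
                    numeric(0), numeric(0), j_mean, 1,
                    0, 0, ramp * k)
}
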