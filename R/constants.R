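#' Physical constants and unit conventions
#'
#' The package works throughout in angstrom (length), picosecond (time),
#' unified atomic mass unit (mass) and kJ/mol (energy). In these units one
#' u A^2 ps^-2 equals 0.01 kJ/mol, so accelerations are
#' `100 * force / mass` A ps^-2.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ mol^-1 K^-1.}
#'   \item{coulomb}{Coulomb prefactor, kJ mol^-1 A e^-2.}
#' }
#' @name mdoc-units
NULL

.kB <- 0.008314462618
.coulomb_const <- 1389.35458

#' Static dipolar splitting defaults
#'
#' Static (rigid-limit) dipolar splittings used to build the principal-axis
#' dipolar tensor before scaling by the alignment-medium order parameter
#' `s_am`. The one-bond C(sp3)-H value is the conventional 47.96 kHz
#' splitting; the sp2 variant is configurable and defaults to the same
#' number (a documented placeholder). Long-range H-H splittings are
#' computed from the interproton distance as `hh_prefactor / r^3` (kHz,
#' r in A) at configuration time and then frozen.
#'
#' @param class one of `"ch_sp3"`, `"ch_sp2"`.
#' @return splitting in Hz.
#' @export
d_stat_default <- function(class = c("ch_sp3", "ch_sp2")) {
  class <- match.arg(class)
  switch(class, ch_sp3 = 47960, ch_sp2 = 47960)
}

# kHz A^3; |D_HH| splitting = .hh_dipolar_prefactor / r^3
.hh_dipolar_prefactor <- 240.2

#' Karplus (Haasnoot) parameter sets
#'
#' Published parameter sets for the substituent-corrected Karplus relation
#' used for vicinal proton couplings,
#' `J = P1 cos^2(phi) + P2 cos(phi) + P3 +
#'    sum_i dchi_i (P4 + P5 cos^2(xi_i phi + P6 |dchi_i|))`.
#' `"hla2"` is the generally used set for H-C-C-H fragments with two
#' non-hydrogen substituents, `"hla3"` the three-substituent set. P6 is in
#' degrees. These are shipped as data defaults, not hard-wired into the
#' force code.
#'
#' @param set parameter set name.
#' @return named numeric vector `P1..P6`.
#' @export
#' @examples
#' haasnoot_params("hla2")
haasnoot_params <- function(set = c("hla2", "hla3")) {
  set <- match.arg(set)
  switch(set,
    hla2 = c(P1 = 13.70, P2 = -0.73, P3 = 0.00, P4 = 0.56, P5 = -2.47, P6 = 16.9),
    hla3 = c(P1 = 13.22, P2 = -0.99, P3 = 0.00, P4 = 0.87, P5 = -2.46, P6 = 19.9)
  )
}
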