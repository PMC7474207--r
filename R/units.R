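#' Reduced-unit conversions
#'
#' The coarse-grained model works in reduced units: length in Angstrom,
#' energy in units of the uniform contact well depth \eqn{\epsilon}, time in
#' \eqn{\tau} (of the order of 1 ns). Calibration against unfolding
#' experiments fixes \eqn{\epsilon \approx 110} pN A, i.e. about
#' 6.62 kJ/mol, which these helpers use to report in physical units.
#'
#' @name units
#' @examples
#' eps_to_kJ_per_mol(1)      # ~6.62 kJ/mol
#' umbrella_k_to_reduced(2000)  # kJ/mol/nm^2 -> eps/A^2
NULL

# 110 pN*A = 1.1e-20 J; times Avogadro -> J/mol
.EPS_KJ_PER_MOL <- 110e-12 * 1e-10 * 6.02214076e23 / 1000

#' @rdname units
#' @param e energy in \eqn{\epsilon}
#' @export
eps_to_kJ_per_mol <- function(e) e * .EPS_KJ_PER_MOL

#' @rdname units
#' @param kj energy in kJ/mol
#' @export
kJ_per_mol_to_eps <- function(kj) kj / .EPS_KJ_PER_MOL

#' @rdname units
#' @param e_pnA energy in pN A
#' @export
pN_A_to_eps <- function(e_pnA) e_pnA / 110

#' Convert an umbrella spring constant from kJ/(mol nm^2) to eps/A^2
#' @rdname units
#' @param k spring constant in kJ/(mol nm^2)
#' @export
umbrella_k_to_reduced <- function(k) kJ_per_mol_to_eps(k) / 100
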