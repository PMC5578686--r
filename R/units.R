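#' Unit conversion constants and helpers
#'
#' Internal mechanical units are angstrom (length), piconewton (force),
#' pN/A^2 (stress) and pN*A (energy). Interaction energies are handled in
#' kcal/mol and converted at the force level.
#'
#' Conversions:
#' * 1 kcal/mol/A  = 69.48 pN
#' * 1 pN/A^2      = 100 MPa
#'
#' @name msclrod-units
NULL

#' Force conversion factor: kcal/mol/A per pN
#' @keywords internal
.KCALMOL_PER_A_IN_PN <- 69.48

#' Stress conversion factor: MPa per pN/A^2
#' @keywords internal
.PN_A2_IN_MPA <- 100

#' Convert a force gradient in kcal/mol/A to piconewtons
#'
#' @param x numeric vector, kcal/mol/A.
#' @return numeric vector, pN.
#' @export
#' @examples
#' kcalmol_per_A_to_pN(1) # 69.48
kcalmol_per_A_to_pN <- function(x) x * .KCALMOL_PER_A_IN_PN

#' Convert piconewtons to kcal/mol/A
#' @param x numeric vector, pN.
#' @return numeric vector, kcal/mol/A.
#' @export
pN_to_kcalmol_per_A <- function(x) x / .KCALMOL_PER_A_IN_PN

#' Convert stress in pN/A^2 to MPa
#' @param x numeric vector, pN/A^2.
#' @return numeric vector, MPa.
#' @export
#' @examples
#' pN_A2_to_MPa(10) # 1000 MPa = 1 GPa
pN_A2_to_MPa <- function(x) x * .PN_A2_IN_MPA

#' Convert stress in MPa to pN/A^2
#' @param x numeric vector, MPa.
#' @return numeric vector, pN/A^2.
#' @export
MPa_to_pN_A2 <- function(x) x / .PN_A2_IN_MPA
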