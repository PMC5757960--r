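#' Physical constants and package-wide conventions
#'
#' Gas constant in kJ/mol/K and derived RT at the simulation temperature,
#' the Coulomb prefactor in kJ mol^-1 nm e^-2, and the handedness constant
#' that fixes what a "positive" helical rotation means.
#'
#' @name helixpack-constants
#' @keywords internal
NULL

#' Gas constant, kJ/mol/K.
#' @export
GAS_CONSTANT_KJ <- 0.0083145

#' Default simulation temperature, K.
#' @export
DEFAULT_TEMPERATURE_K <- 300

#' RT at 300 K, kJ/mol.
#' @export
RT_300K <- GAS_CONSTANT_KJ * DEFAULT_TEMPERATURE_K

#' Coulomb prefactor 1/(4 pi eps0) in kJ mol^-1 nm e^-2.
#' @export
COULOMB_KJ_NM <- 138.935485

# Sign convention for helical rotation: a positive angle is a clockwise
# displacement about the helix long axis as viewed from the N-terminus
# looking toward the C-terminus. With a right-handed rotation matrix about
# the N->C unit axis, "clockwise from N looking toward C" is a rotation by
# minus the angle; this constant carries that mapping. The whole pipeline
# (application and measurement) is self-consistent under either value.
#' Handedness of positive helical rotation (-1: clockwise viewed N toward C).
#' @export
ROTATION_HANDEDNESS <- -1

#' Threshold for flagging residue-pair energy changes, kJ/mol.
#' @export
PAIR_ENERGY_FLAG_KJ <- 1.0

#' Van der Waals radii by element, nm
#'
#' Bondi-type radii used for surface-area and steric-clash calculations.
#' The radii source is a package convention (documented in the methods
#' vignette); area results carry the corresponding ambiguity.
#'
#' @return named numeric vector of radii in nm
#' @export
vdw_radii <- function() {
  c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
    P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
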