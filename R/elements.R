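#' Monoisotopic element masses and physical constants
#'
#' Monoisotopic masses (most abundant isotope, Da) of the elements accepted
#' in formulas, from the standard IUPAC/NIST atomic mass evaluation, plus the
#' constants used for charge bookkeeping.
#'
#' @format A named numeric vector, element symbol to mass in Da.
#' @name element-masses
NULL

# Most-abundant-isotope masses, Da (IUPAC/NIST). Immutable during a run.
.ELEMENT_MASSES <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.9897692809,
  Mg = 23.9850417,
  Si = 27.9769265327,
  P  = 30.97376151,
  S  = 31.97207069,
  Cl = 34.96885271,
  K  = 38.9637064864,
  Ca = 39.9625909,
  F  = 18.9984031627,
  Br = 78.9183376,
  I  = 126.904468,
  Fe = 55.9349421,
  Zn = 63.9291466,
  Se = 79.9165218
)

.ELECTRON_MASS <- 0.00054857990
# Proton = H minus one electron; 1.007276 Da.
.PROTON_MASS <- .ELEMENT_MASSES[["H"]] - .ELECTRON_MASS
# 13C - 12C spacing used for z = 1 deisotoping.
.C13_SPACING <- 1.003355

#' Element mass table and constants
#'
#' @return `element_masses()` returns the named vector of monoisotopic
#'   element masses (Da). `proton_mass()`, `electron_mass()` and
#'   `isotope_spacing()` return the corresponding constants in Da.
#' @examples
#' element_masses()[["Na"]] - element_masses()[["H"]] # 21.9819, the Na-H delta
#' @export
element_masses <- function() .ELEMENT_MASSES

#' @rdname element_masses
#' @export
proton_mass <- function() .PROTON_MASS

#' @rdname element_masses
#' @export
electron_mass <- function() .ELECTRON_MASS

#' @rdname element_masses
#' @export
isotope_spacing <- function() .C13_SPACING
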