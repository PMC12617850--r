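#' Physical constants for mass-spectrometric arithmetic
#'
#' Monoisotopic atomic masses (Da) for the supported element alphabet,
#' proton and electron masses, and the iron isotope masses and abundances
#' used by the ferric-complex screen. Values are hard-coded from the
#' AME2020 atomic-mass evaluation and the IUPAC isotopic-abundance tables
#' so that the package has no runtime dependency for constants.
#'
#' The proton (not the hydrogen atom) mass is used for protonation
#' arithmetic; the electron mass is carried along for completeness but the
#' [M+H]+ calculation ignores it (the error is below 1 ppm for m/z > 100).
#'
#' @return A list with components:
#'   \describe{
#'     \item{masses}{named numeric vector of monoisotopic atomic masses for
#'       C, H, N, O, S and Fe (56Fe), in Da}
#'     \item{proton}{proton mass (Da)}
#'     \item{electron}{electron mass (Da)}
#'     \item{fe56, fe54}{monoisotopic masses of 56Fe and 54Fe (Da)}
#'     \item{fe_spacing}{fe56 - fe54, about 1.99533 Da}
#'     \item{fe_ratio}{natural 54Fe/56Fe abundance ratio, about 0.0637}
#'     \item{c13_abundance}{natural 13C fractional abundance}
#'     \item{ch2, o}{monoisotopic masses of a CH2 and an O increment (Da)}
#'     \item{holo_shift}{fe56 - 3 H, the constant m/z offset between the
#'       protonated ferric complex [M - 3H + Fe + H]+ and the protonated
#'       apo species [M + H]+, about 52.9115 Da}
#'   }
#' @examples
#' mass_constants()$fe_spacing  # ~1.99533
#' @export
mass_constants <- function() {
  ## AME2020 atomic masses; IUPAC 2021 abundances
  fe56 <- 55.93493633
  fe54 <- 53.93960899
  masses <- c(
    C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    S = 31.97207100,
    Fe = fe56
  )
  list(
    masses        = masses,
    proton        = 1.007276466879,
    electron      = 0.000548579909,
    fe56          = fe56,
    fe54          = fe54,
    fe_spacing    = fe56 - fe54,
    fe_ratio      = 0.05845 / 0.91754,
    c13_abundance = 0.0107,
    ch2           = masses[["C"]] + 2 * masses[["H"]],
    o             = masses[["O"]],
    holo_shift    = fe56 - 3 * masses[["H"]]
  )
}
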