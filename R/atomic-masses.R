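#' Monoisotopic atomic masses
#'
#' CODATA/NIST monoisotopic masses (Da) of the principal isotopes of the
#' elements handled by the package, plus the heavy isotopes used for
#' stable-isotope labels and the proton mass used for ion m/z.
#'
#' @format Named numeric vector of masses in Da.
#' @keywords internal
#' @name atomic-masses
NULL

# single authoritative constants table; everything mass-related reads these
.MONOISOTOPIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

.ISOTOPE_MASS <- c(
  `13C` = 13.0033548378,
  `15N` = 15.0001088982,
  `2H`  = 2.0141017778
)

# proton (not bare H): electron mass is accounted for in [M-H]-/[M+H]+
.PROTON_MASS <- 1.00727646688

.KNOWN_ELEMENTS <- names(.MONOISOTOPIC_MASS)

#' Mass shift per label substitution
#'
#' Mass difference introduced by a single isotope substitution.
#'
#' @keywords internal
.LABEL_SHIFT <- c(
  `13C` = .ISOTOPE_MASS[["13C"]] - .MONOISOTOPIC_MASS[["C"]],
  `15N` = .ISOTOPE_MASS[["15N"]] - .MONOISOTOPIC_MASS[["N"]],
  `2H`  = .ISOTOPE_MASS[["2H"]]  - .MONOISOTOPIC_MASS[["H"]]
)

#' Round half-up to a fixed number of decimals
#'
#' `base::round()` rounds half to even; reported m/z follow the
#' round-half-up convention used on instrument output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
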