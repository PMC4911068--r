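# Closed-form physics of the string model of vocal fold vibration.
#
# External units follow the conventions of the comparative literature:
# lengths in millimetres, stresses in kilopascals, density in kg/m^3,
# frequencies in hertz. The frequency formula is dimensionally consistent
# only in SI, so conversions happen here and nowhere else.

MM_PER_M <- 1000
PA_PER_KPA <- 1000

#' Default vocal fold tissue density
#'
#' Soft tissue density, about 1.04 g/cm^3, expressed in kg/m^3.
#' @export
DEFAULT_TISSUE_DENSITY <- 1040

#' Exponential tissue stress-strain law
#'
#' The fiber stress of vocal fold tissue rises exponentially with strain:
#' `mu = A * exp(B * strain)`, with strain measured relative to the
#' cadaveric reference length `L0`. `A` sets the stress at the reference
#' length; the dimensionless exponent `B` quantifies tissue nonlinearity
#' and is the key determinant of achievable frequency range.
#'
#' @param A stress amplitude at zero strain, kPa; must be > 0.
#' @param B dimensionless stiffness exponent; must be >= 0.
#' @param L0 cadaveric reference length, mm; must be > 0.
#' @return An object of class `stress_law`.
#' @examples
#' stress_law(A = 4.0, B = 9.4, L0 = 16)  # adult human male vocal fold
#' @export
stress_law <- function(A, B, L0) {
  check_positive(A, "A")
  check_scalar(B, "B")
  if (B < 0) abort_domain(sprintf("`B` must be >= 0 (got %g)", B))
  check_positive(L0, "L0")
  structure(list(A = A, B = B, L0 = L0), class = "stress_law")
}

#' @export
print.stress_law <- function(x, ...) {
  cat(sprintf("<stress_law> mu' = %g kPa * exp(%g * strain), L0 = %g mm\n",
              x$A, x$B, x$L0))
  invisible(x)
}

#' Ideal string under tension
#'
#' State of a string fixed at both ends: vibrating length, effective fiber
#' stress (combined shear and tensile stress for transverse displacement,
#' treated as a single effective stress), and tissue density.
#'
#' @param L vibrating length, mm; > 0.
#' @param mu effective fiber stress, kPa; > 0.
#' @param rho tissue density, kg/m^3; > 0. Default [DEFAULT_TISSUE_DENSITY].
#' @return An object of class `vibrating_string`.
#' @export
vibrating_string <- function(L, mu, rho = DEFAULT_TISSUE_DENSITY) {
  check_positive(L, "L")
  check_positive(mu, "mu")
  check_positive(rho, "rho")
  structure(list(L = L, mu = mu, rho = rho), class = "vibrating_string")
}

#' Elongation geometry of a vocal fold
#'
#' Holds the cadaveric reference length `L0` together with the shortest
#' (`L1`) and longest (`L2`) lengths used in phonation. Phonatory lengths
#' typically span roughly +/- 30-50 % around `L0`, so `L1/L0` is required
#' to lie in (0, 1.5].
#'
#' @param L0 reference (cadaveric) length, mm.
#' @param L1 shortest phonatory length, mm.
#' @param L2 longest phonatory length, mm; `L1 <= L2`.
#' @return An object of class `elongation` with derived `l1_fraction`
#'   (`L1/L0`) and `length_ratio` (`L2/L1`).
#' @export
elongation <- function(L0, L1, L2) {
  check_positive(L0, "L0")
  check_positive(L1, "L1")
  check_positive(L2, "L2")
  if (L1 > L2) abort_domain(sprintf("`L1` (%g) must not exceed `L2` (%g)", L1, L2))
  l1_fraction <- L1 / L0
  if (l1_fraction > 1.5) {
    abort_domain(sprintf("`L1/L0` = %g exceeds the physiological bound 1.5", l1_fraction))
  }
  structure(list(L0 = L0, L1 = L1, L2 = L2,
                 l1_fraction = l1_fraction, length_ratio = L2 / L1),
            class = "elongation")
}

#' Fundamental frequency range
#'
#' A pair of f0 bounds with ratio and octave views (`octaves = log2(fo2/fo1)`).
#'
#' @param fo1 lowest fundamental frequency, Hz.
#' @param fo2 highest fundamental frequency, Hz; `fo1 <= fo2`.
#' @return An object of class `frequency_range` with derived `ratio` and
#'   `octaves`.
#' @export
frequency_range <- function(fo1, fo2) {
  check_positive(fo1, "fo1")
  check_positive(fo2, "fo2")
  if (fo1 > fo2) abort_domain(sprintf("`fo1` (%g) must not exceed `fo2` (%g)", fo1, fo2))
  structure(list(fo1 = fo1, fo2 = fo2, ratio = fo2 / fo1,
                 octaves = log2(fo2 / fo1)),
            class = "frequency_range")
}

#' Fundamental frequency of an ideal string
#'
#' For a string fixed at both ends, `fo = 1/(2L) * sqrt(mu/rho)`. The
#' frequency falls as 1/L and rises as the square root of fiber stress,
#' which is why stress — not length — is the critical variable for f0
#' control once all tissue layers share one elongation.
#'
#' @param string a [vibrating_string()] (length in mm, stress in kPa).
#' @return Fundamental frequency in Hz.
#' @examples
#' string_fo(vibrating_string(L = 16, mu = 4))  # ~61 Hz
#' @export
string_fo <- function(string) {
  stopifnot(inherits(string, "vibrating_string"))
  L_m <- string$L / MM_PER_M
  mu_pa <- string$mu * PA_PER_KPA
  1 / (2 * L_m) * sqrt(mu_pa / string$rho)
}

#' Fiber stress at a given strain
#'
#' Evaluates the exponential stress-strain law `A * exp(B * strain)`.
#' Strain is `(L - L0)/L0` and must exceed -1 (length stays positive).
#'
#' @param strain dimensionless fractional elongation; > -1.
#' @param law a [stress_law()].
#' @return Fiber stress in kPa.
#' @export
fiber_stress <- function(strain, law) {
  stopifnot(inherits(law, "stress_law"))
  check_scalar(strain, "strain")
  if (strain <= -1) {
    abort_domain(sprintf("`strain` must be > -1 (got %g): length must stay positive", strain))
  }
  law$A * exp(law$B * strain)
}

#' First-order f0 change under combined length and stress perturbation
#'
#' Differentiating the string formula gives
#' `dfo = fo * (-dL/L + 1/2 * dmu/mu)`: a positive stress change must
#' overcome twice its share of the (negative) length change for f0 to
#' rise. This is the first-order Taylor expansion of [string_fo()].
#'
#' @param fo operating fundamental frequency, Hz; > 0.
#' @param rel_length_change relative length change `dL/L`.
#' @param rel_stress_change relative stress change `dmu/mu`.
#' @return Frequency change in Hz.
#' @export
delta_fo <- function(fo, rel_length_change, rel_stress_change) {
  check_positive(fo, "fo")
  check_scalar(rel_length_change, "rel_length_change")
  check_scalar(rel_stress_change, "rel_stress_change")
  fo * (-rel_length_change + 0.5 * rel_stress_change)
}

#' Predicted f0 ratio across an elongation range
#'
#' Combining the string formula with the exponential stress law, the ratio
#' of the highest to the lowest fundamental frequency over an elongation
#' from `L1` to `L2` is
#' `fo2/fo1 = (L2/L1)^-1 * exp(1/2 * B * (L2 - L1)/L0)`.
#' The amplitude `A` cancels: only the exponent `B` and the geometry
#' matter. For `B = 0` (constant stress) the ratio is simply `L1/L2` —
#' longer means lower, the general size principle.
#'
#' @param elong an [elongation()].
#' @param B dimensionless stiffness exponent; >= 0.
#' @return The dimensionless ratio `fo2/fo1`.
#' @examples
#' # four-octave range: B = 10 with elongation from 0.7*L0 to 1.4*L0
#' fo_ratio(elongation(L0 = 10, L1 = 7, L2 = 14), B = 10)  # ~16
#' @export
fo_ratio <- function(elong, B) {
  stopifnot(inherits(elong, "elongation"))
  check_scalar(B, "B")
  if (B < 0) abort_domain(sprintf("`B` must be >= 0 (got %g)", B))
  (elong$L2 / elong$L1)^-1 * exp(0.5 * B * (elong$L2 - elong$L1) / elong$L0)
}

#' Convert a frequency ratio to octaves
#'
#' @param ratio a positive frequency ratio.
#' @return `log2(ratio)`.
#' @export
octaves <- function(ratio) {
  check_positive(ratio, "ratio")
  log2(ratio)
}
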