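# Physicochemical constants used across the package.

# Monoisotopic residue masses (Da) for the 20 canonical amino acids,
# standard IUPAC/Unimod values (residue = amino acid minus water).
AA_MONO_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

WATER_MASS <- 18.0105646837
PROTON_MASS <- 1.007276466

# Kyte-Doolittle hydropathy scale (dimensionless).
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Cross-linker bridge masses
#'
#' Monoisotopic mass added by common amine-reactive cross-linkers once both
#' ends have reacted (the intact bridge between two peptide chains).
#' DSS and BS3 share the C8H10O2 suberate bridge (138.06808 Da); DSSO
#' contributes its C6H6O3S thioether bridge (158.00376 Da).
#'
#' @return Named numeric vector of bridge masses in Da.
#' @export
#' @examples
#' crosslinker_masses()[["DSS"]]
crosslinker_masses <- function() {
  c(DSS = 138.06807956, BS3 = 138.06807956, DSSO = 158.00376026)
}
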