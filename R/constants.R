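# Physical constants and unit conversions, fixed in one place.
# Internal length unit is the angstrom, charge the elementary charge e,
# energy kcal/mol, potential mV.

# Boltzmann constant, kcal mol^-1 K^-1
kB_KCAL <- 1.987204259e-3

# 1 e * mV in kcal/mol (1 eV = 23.060548 kcal/mol)
E_MV_TO_KCAL <- 23.060548e-3

# Coulomb potential of 1 e at 1 A, in mV (332.06371 kcal A / (mol e^2)
# divided by E_MV_TO_KCAL)
POT_E_PER_A_MV <- 332.06371 / E_MV_TO_KCAL / 1000 * 1000  # = 14399.65 mV*A/e

# conductance: N events of charge q e over T ns under V mV, in pS:
# g = N*q*1.602176634e-19 C / (T*1e-9 s * V*1e-3 V) * 1e12 pS/S
COND_PS_FACTOR <- 1.602176634e5

# gas constant alias used for free-energy surfaces (kcal mol^-1 K^-1)
R_KCAL <- kB_KCAL

# atomic masses for mass-weighted centres of mass (g/mol)
ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, K = 39.098, CL = 35.45, NA. = 22.990, X = 1.0
)

element_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- ELEMENT_MASS[el]
  m[is.na(m)] <- 12.0  # unknown heavy atom: carbon-like default
  unname(m)
}

is_hydrogen <- function(element, name) {
  he <- !is.na(element) & toupper(element) == "H"
  # fall back on atom-name convention when the element column is empty
  hn <- (is.na(element) | element == "") & grepl("^[0-9]*H", name)
  he | hn
}
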