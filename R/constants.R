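# Physical constants pinned in one place so vibrational golden tests are
# bit-stable. Energies are kcal/mol, lengths Angstrom, masses amu throughout.

.KCAL_PER_MOL_J <- 4184                # J per kcal
.AVOGADRO <- 6.02214076e23             # 1/mol (exact, SI 2019)
.AMU_KG <- 1.66053906660e-27           # kg
.C_CM_S <- 2.99792458e10               # speed of light, cm/s

# sqrt(kcal/(mol A^2 amu)) -> wavenumber (cm^-1)
.FREQ_FACTOR <- sqrt(.KCAL_PER_MOL_J / (.AVOGADRO * .AMU_KG * 1e-20)) /
  (2 * pi * .C_CM_S)

# Average atomic masses (amu) for the elements a truncated protein + small
# substrate model can contain.
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, "NA" = 22.990, MG = 24.305, P = 30.974, S = 32.06,
  CL = 35.45, K = 39.098, CA = 40.078, FE = 55.845, ZN = 65.38,
  BR = 79.904, I = 126.904
)

#' Look up atomic masses
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @keywords internal
atomic_mass <- function(elements) {
  m <- .ATOMIC_MASSES[toupper(trimws(elements))]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

.WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP", "TIP3")

# Backbone atom names (amide H and alpha H included): everything else in a
# residue counts as side chain for freeze-list purposes.
.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HN", "HA", "HA2", "HA3")
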