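# Physical constants and residue-level coefficient tables used across the
# package. All tables are plain named vectors so they can be inspected,
# subset and overridden by users.

# Average (isotope-abundance weighted) residue masses, Da. Standard values;
# a peptide of length L has mass sum(residues) + one water.
.residue_avg_mass <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.water_mass <- 18.01528

# Molar absorptivities at 214 nm, 1/(M*cm), after Kuipers & Gruppen
# (J Agric Food Chem 2007): one peptide-bond term per bond plus per-residue
# side-chain contributions. Proline in a peptide bond has its own bond-aware
# value; an N-terminal proline contributes only 30.
.eps214_bond <- 923
.eps214_side <- c(
  G = 21,    A = 32,    S = 34,    P = 2675,  V = 43,
  T = 41,    C = 225,   L = 45,    I = 45,    N = 136,
  D = 58,    Q = 142,   K = 41,    E = 78,    M = 980,
  H = 5125,  F = 5200,  R = 102,   Y = 5375,  W = 29050
)
.eps214_pro_nterm <- 30

# Amino acid partial specific volumes, cm^3/g (Cohn & Edsall consensus
# values as tabulated for protein vbar estimation).
.residue_vbar <- c(
  G = 0.64, A = 0.74, S = 0.63, P = 0.76, V = 0.86,
  T = 0.70, C = 0.63, L = 0.90, I = 0.90, N = 0.62,
  D = 0.60, Q = 0.67, K = 0.82, E = 0.66, M = 0.75,
  H = 0.67, F = 0.77, R = 0.70, Y = 0.71, W = 0.74
)

.proton_mass <- 1.00728                 # Da, for m/z -> neutral mass
.fwhm_factor <- 2 * sqrt(2 * log(2))    # Gaussian FWHM / SD
.R_erg <- 8.31446e7                     # gas constant, erg/(mol K)
.avogadro <- 6.02214076e23
.cscl_beta0 <- 1.17e9                   # CsCl gradient coefficient, cm^5/(g s^2), ~25 C
.dna_residue_mass <- 309                # Da per ssDNA nucleotide, average

#' Molar extinction coefficient table at 214 nm
#'
#' Per-residue side-chain molar absorptivities at 214 nm plus the peptide-bond
#' term, used by [molar_extinction_214()]. Values follow the sequence-based
#' prediction scheme of Kuipers & Gruppen (2007): each peptide bond absorbs
#' 923 M^-1 cm^-1; proline engaged in a peptide bond carries a distinct
#' bond-aware coefficient (2675), while an N-terminal proline contributes 30.
#'
#' @return A list with elements `peptide_bond` (scalar), `side_chain`
#'   (named vector over the 20 standard residues) and `proline_n_terminal`.
#' @export
epsilon214_coefficients <- function() {
  list(peptide_bond = .eps214_bond,
       side_chain = .eps214_side,
       proline_n_terminal = .eps214_pro_nterm)
}

#' Amino acid partial specific volumes
#'
#' Cohn-Edsall style residue partial specific volumes (cm^3/g) used by
#' [composition_vbar()] for the mass-weighted protein vbar estimate.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
residue_partial_specific_volumes <- function() .residue_vbar
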