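# Fixed model constants: ideal geometry, residue tables, steric radii, masses.
# All builder geometry lives here so the coarse-grained model is editable in
# one place. Distances in Angstrom, angles in degrees, energies in kcal/mol.

#' Ideal-geometry table used by the internal-coordinate builder
#'
#' The structure builder places atoms from fixed bond lengths and angles; only
#' the backbone phi/psi torsions are variable. Amide omega torsions are fixed
#' trans (180 degrees) and the 1,2,3-triazole ring is a rigid planar pentagon.
#' These are standard peptide values, not force-field parameters: the model is
#' intended for torsion-space analysis, not for geometry optimisation.
#'
#' @return Named list of bond lengths (`bonds`, Angstrom) and angles
#'   (`angles`, degrees).
#' @export
ideal_geometry <- function() {
  list(
    bonds = c(
      C_N_amide = 1.33,   # C(=O)-N amide bond
      N_CA      = 1.46,
      CA_C      = 1.52,
      C_O       = 1.23,   # carbonyl C=O
      C_OXT     = 1.34,   # ester C-O
      CA_C4     = 1.50,   # CA to triazole ring C4 (4n residue)
      N1_CA     = 1.46,   # triazole ring N1 to CA (4c residue)
      ring      = 1.35,   # all five triazole ring bonds
      N_H       = 1.01,
      CA_H      = 1.09,
      CA_CB     = 1.53,
      C5_H5     = 1.08,
      OXT_CM    = 2.00    # ester O to allyl/benzyl centroid
    ),
    angles = c(
      CA_C_N    = 116.0,  # around carbonyl C
      CA_C_O    = 121.0,
      CA_C_OXT  = 111.0,
      C_N_CA    = 122.0,  # around amide N
      C_N_H     = 119.0,
      N_CA_C    = 111.0,  # around CA
      N_CA_CB   = 110.5,
      N_CA_H    = 108.0,
      N_CA_C4   = 111.0,
      N1_CA_C   = 111.0,
      N1_CA_CB  = 110.5,
      N1_CA_H   = 108.0,
      CA_C4_C5  = 126.0,  # exocyclic at ring C4
      ring      = 108.0,  # interior pentagon angle
      C4_C5_H5  = 126.0,
      C5_N1_CA  = 126.0,  # exocyclic at ring N1
      CA_CB_SC  = 114.0,
      O_C_N     = 122.0,  # cap carbonyl
      H_N_CA    = 118.0,  # free-amine cap
      C_OXT_CM  = 117.0
    )
  )
}

# chirality sign convention for the two CA substituents (degrees):
# dihedral(CB-CA-N-C_ref) for an L residue; D mirrors the signs.
.CHI <- list(L = c(CB = -122.0, H_A = 118.0),
             D = c(CB = 122.0, H_A = -118.0),
             achiral = c(H_A = 118.0))

# residue table: one/three letter code, side-chain centroid bond length from CB
# (0 = CB only, NA = no side chain) and summed heavy-atom side-chain mass.
.RESIDUES <- data.frame(
  code3 = c("Gly", "Ala", "Val", "Leu", "Ile", "Phe", "Ser", "Thr", "Tyr",
            "Trp", "Met", "Cys", "Asn", "Gln", "Asp", "Glu", "Lys", "Arg",
            "His", "Pro"),
  code1 = c("G", "A", "V", "L", "I", "F", "S", "T", "Y", "W", "M", "C", "N",
            "Q", "D", "E", "K", "R", "H", "P"),
  sc_dist = c(NA, 0, 1.2, 1.7, 1.7, 2.4, 1.2, 1.2, 2.9, 3.0, 2.2, 1.5, 1.6,
              2.1, 1.6, 2.1, 2.7, 3.2, 2.2, 1.2),
  sc_mass = c(0, 15.035, 43.089, 57.116, 57.116, 91.13, 31.034, 45.061,
              107.129, 130.166, 75.15, 47.1, 58.06, 72.086, 59.044, 73.071,
              73.137, 101.151, 81.096, 42.08),
  stringsAsFactors = FALSE
)

# per-role hard-sphere radii for the stand-in steric term (Angstrom);
# sigma_ij = (radius_i + radius_j) / 2 (arithmetic mean). Declared
# non-physical: exists only to keep the chain from self-intersecting during
# torsional Monte Carlo.
.ROLE_RADIUS <- c(
  N = 1.5, CA = 1.5, C_O = 1.5, O = 1.4, OXT = 1.4,
  ring_N1 = 1.5, ring_N2 = 1.5, ring_N3 = 1.5, ring_C4 = 1.5, ring_C5 = 1.5,
  CB = 1.7, SC_centroid = 2.2,
  H_N = 1.0, H_A = 1.0, ring_H5 = 1.0,
  cap_C = 1.5, cap_O = 1.4, cap_CT = 2.2, cap_H = 1.0, cap_CM = 2.0
)

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

# bulk number density of water, molecules per cubic Angstrom (RDF default)
.WATER_DENSITY <- 0.033456

# AMBER-style NOE restraint force constant, kcal mol^-1 A^-2 (default)
.DEFAULT_K_RESTRAINT <- 32

# restraint-pruning penalty ceiling, kcal/mol (default)
.DEFAULT_PENALTY_CEILING <- 5

#' Gas constant in kcal per mol per Kelvin
#' @export
R_KCAL <- 1.98720425864e-3
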