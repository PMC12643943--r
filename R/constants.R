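# Ideal backbone geometry (Engh-Huber-style values). All lengths in
# Angstrom, all angles in degrees. Kept in one place so that the builder,
# the ring-closure routine and the closure validator agree by construction.
.bb_geom <- list(
  b_n_ca  = 1.458,  # N-CA bond
  b_ca_c  = 1.525,  # CA-C bond
  b_c_n   = 1.329,  # C-N peptide bond (the closing bond of a macrocycle)
  b_c_o   = 1.231,  # C=O carbonyl
  a_n_ca_c = 111.2, # N-CA-C
  a_ca_c_n = 116.2, # CA-C-N
  a_c_n_ca = 121.7, # C-N-CA
  a_ca_c_o = 120.8  # CA-C-O
)

# Heavy-atom van der Waals radii (Bondi set), Angstrom. Hydrogens are
# ignored throughout (heavy-atom SASA).
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, H = 1.20
)

# Black-Mould residue hydrophobicity (normalized 0..1 scale), shifted so
# that glycine sits at zero, as used by the spatial aggregation
# propensity score.
.bm_hydrophobicity_raw <- c(
  ALA = 0.616, ARG = 0.000, ASN = 0.236, ASP = 0.028, CYS = 0.680,
  GLN = 0.251, GLU = 0.043, GLY = 0.501, HIS = 0.165, ILE = 0.943,
  LEU = 0.943, LYS = 0.283, MET = 0.738, PHE = 1.000, PRO = 0.711,
  SER = 0.359, THR = 0.450, TRP = 0.878, TYR = 0.880, VAL = 0.825
)
.bm_hydrophobicity <- .bm_hydrophobicity_raw - .bm_hydrophobicity_raw[["GLY"]]

.backbone_atom_names <- c("N", "CA", "C", "O", "OXT")

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1to3 <- setNames(names(.aa3to1), .aa3to1)

#' Ideal backbone geometry constants
#'
#' Returns the table of ideal bond lengths (Angstrom) and bond angles
#' (degrees) used by [build_from_torsions()], [ccd_close()] and
#' [closure_check()].
#'
#' @return Named list of geometry constants.
#' @export
backbone_geometry <- function() .bb_geom
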