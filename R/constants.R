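# Residue-level chemistry tables used by selection and the fixture builder.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

STANDARD_AA <- unname(AA3)

NUCLEI <- c("CA", "CB", "C", "HN", "N", "HA")

# Ring atom names in bond order around each ring.
RING_DEFS <- list(
  PHE  = list(res = "PHE", atoms = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR  = list(res = "TYR", atoms = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS  = list(res = "HIS", atoms = c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP5 = list(res = "TRP", atoms = c("CG", "CD1", "NE1", "CE2", "CD2")),
  TRP6 = list(res = "TRP", atoms = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# Side-chain anisotropy groups: (A, center, B) atom names per residue.
SIDECHAIN_ANI <- list(
  ASN = list(kind = "OCN", atoms = c("OD1", "CG", "ND2")),
  GLN = list(kind = "OCN", atoms = c("OE1", "CD", "NE2")),
  ASP = list(kind = "OCO", atoms = c("OD1", "CG", "OD2")),
  GLU = list(kind = "OCO", atoms = c("OE1", "CD", "OE2")),
  ARG = list(kind = "NCN", atoms = c("NH1", "CZ", "NH2"))
)

# PDB hydrogen-name dialects mapped onto the names selection expects.
# Amide proton: "H" (wwPDB v3) and "HN" (older/CHARMM-style) are the same
# atom; glycine alpha protons drift between HA1/HA2, HA2/HA3 and 1HA/2HA.
H_SYNONYMS <- c(
  "H"   = "HN",
  "HN"  = "HN",
  "1H"  = "HN",
  "HA"  = "HA",
  "HA1" = "HA2",
  "HA2" = "HA2",
  "HA3" = "HA3",
  "1HA" = "HA2",
  "2HA" = "HA3"
)

normalize_h_name <- function(name) {
  out <- unname(H_SYNONYMS[name])
  ifelse(is.na(out), name, out)
}
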